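# The synthetic-data generator: haplotype frequencies from MAF/LD, the
# scenario effect vectors, intercept calibration and distributional checks.

test_that("haplotype frequencies from MAF and LD match the construction", {
  f <- haplotype_freqs_from_maf_ld(0.3, 0.4, 0.02)
  expect_equal(as.numeric(f), c(0.44, 0.26, 0.16, 0.14), tolerance = 1e-12)
  # linkage equilibrium: products of allele frequencies
  f0 <- haplotype_freqs_from_maf_ld(0.3, 0.4, 0)
  expect_equal(as.numeric(f0), c(0.7 * 0.6, 0.7 * 0.4, 0.3 * 0.6, 0.3 * 0.4))
  # D beyond its bound names the violated haplotype
  expect_error(haplotype_freqs_from_maf_ld(0.3, 0.4, 0.3), "bound")
  expect_error(haplotype_freqs_from_maf_ld(0.3, 0.4, -0.2), "bound")
})

test_that("scenario effect vectors match the design table", {
  expect_equal(unname(scenario_effects("S0")), rep(0, 8))
  expect_equal(unname(scenario_effects("S1")), rep(0.8, 8))
  expect_equal(unname(scenario_effects("S2")), c(0.8, 0.8, rep(0, 6)))
  expect_equal(unname(scenario_effects("S3")), c(rep(0.8, 4), rep(0, 4)))
  expect_equal(unname(scenario_effects("S4")),
               c(0.8, 0, 0.8, 0, 0.8, 0.8, 0.8, 0.8))
  expect_equal(unname(scenario_effects("S2", effect_size = 0.5))[1], 0.5)
  expect_error(scenario_effects("S9"), "unknown")
})

test_that("intercept calibration balances the case fraction", {
  f <- haplotype_freqs_from_maf_ld(0.3, 0.4, 0.02)
  # null scenario: symmetric, mu = 0
  expect_equal(calibrate_intercept(scenario_effects("S0"), f, f), 0,
               tolerance = 1e-9)
  # S2: the bisection solution must agree with brute-force enumeration of
  # the nine composite-diplotype cells
  eff <- scenario_effects("S2")
  mu <- calibrate_intercept(eff, f, f)
  pH <- f[1]
  wb <- c(pH^2, 2 * pH * (1 - pH), (1 - pH)^2)
  cells <- expand.grid(ks = 2:0, kt = 2:0)
  w9 <- wb[3 - cells$ks] * wb[3 - cells$kt]
  pfun <- function(m) sum(w9 * plogis(m + design_matrix(cells$ks, cells$kt) %*% eff))
  expect_equal(pfun(mu), 0.5, tolerance = 1e-6)
  grid <- seq(-2, 2, by = 1e-4)
  brute <- grid[which.min(abs(vapply(grid, pfun, numeric(1)) - 0.5))]
  expect_lt(abs(mu - brute), 1e-4)
  # calibrated intercepts hold in simulation
  dat <- simulate_epistasis_data(1e5, "S4", seed = 105)
  expect_lt(abs(mean(dat$phenotype) - 0.5), 0.01)
})

test_that("simulated genotypes follow the implied HWE cell distribution", {
  dat <- simulate_epistasis_data(1e5, "S0", seed = 106)
  f <- haplotype_freqs_from_maf_ld(0.3, 0.4, 0.02)
  gs <- dat$genotypes[, 1:2]
  counts <- tabulate(gs[, 1] * 3 + gs[, 2] + 1, nbins = 9)
  probs <- hapepi:::two_locus_genotype_probs(f)
  expect_gt(stats::chisq.test(counts, p = probs)$p.value, 0.001)
  # double-heterozygote frequency matches 2(p11 p22 + p12 p21) per block
  p_dh <- 2 * (f[1] * f[4] + f[2] * f[3])
  expect_lt(abs(mean(gs[, 1] == 1 & gs[, 2] == 1) - p_dh),
            3 * sqrt(p_dh * (1 - p_dh) / 1e5))
})

test_that("phenotypes follow the logistic model on the true codes", {
  dat <- simulate_epistasis_data(1e5, "S2", seed = 107)
  X <- design_matrix(dat$truth$copies[, "copies_s"],
                     dat$truth$copies[, "copies_t"])
  fit <- stats::glm(dat$phenotype ~ X[, "a_s"] + X[, "a_t"],
                    family = stats::binomial())
  se <- summary(fit)$coefficients[2:3, 2]
  expect_true(all(abs(stats::coef(fit)[2:3] - 0.8) < 3 * se))
  # S0: phenotype independent of genotype
  dat0 <- simulate_epistasis_data(2e4, "S0", seed = 108)
  expect_lt(abs(mean(dat0$phenotype) - 0.5), 0.015)
  tab <- table(dat0$genotypes[, 1], dat0$phenotype)
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
})

test_that("simulation is exactly reproducible from its seed", {
  d1 <- simulate_epistasis_data(200, "S4", seed = 109)
  d2 <- simulate_epistasis_data(200, "S4", seed = 109)
  expect_identical(d1$genotypes, d2$genotypes)
  expect_identical(d1$phenotype, d2$phenotype)
  expect_identical(d1$truth$phase, d2$truth$phase)
})

test_that("oracle phase information is at least as accurate as the EM fit", {
  # oracle mode supplies the hidden true phase to the likelihood by making
  # each ambiguous subject's true mixture cell the only one with prior mass;
  # the full penalized pipeline then runs identically in both modes and the
  # oracle estimates should be no worse in MSE across replicates
  truth <- scenario_effects("S2")
  err_oracle <- err_em <- matrix(NA_real_, 12, 8)
  for (r in 1:12) {
    dat <- simulate_epistasis_data(500, "S2", seed = 400 + r)
    fs <- estimate_haplotype_frequencies(dat$genotypes[, 1:2])
    ft <- estimate_haplotype_frequencies(dat$genotypes[, 3:4])
    mf <- build_model_frame(dat$genotypes[, 1:2], dat$genotypes[, 3:4],
                            dat$phenotype, risk_s = "[11]", risk_t = "[11]",
                            freqs_s = fs, freqs_t = ft)
    w <- suppressWarnings(adaptive_weights(mf))
    fit <- select_lambda(mf, w, nlambda = 10)$fit
    err_em[r, ] <- fit$beta - truth
    # degenerate priors at the true phase configuration
    mfo <- mf
    ok_s <- is.na(mfo$cind_s) |
      mfo$cind_s == (dat$truth$copies[mfo$subject, "copies_s"] == 1)
    ok_t <- is.na(mfo$cind_t) |
      mfo$cind_t == (dat$truth$copies[mfo$subject, "copies_t"] == 1)
    mfo$prior <- as.numeric(ok_s & ok_t)
    wo <- suppressWarnings(adaptive_weights(mfo))
    fito <- select_lambda(mfo, wo, nlambda = 10)$fit
    err_oracle[r, ] <- fito$beta - truth
  }
  expect_lte(mean(err_oracle^2), mean(err_em^2) * 1.1)
})

test_that("the scenario study tabulates selection proportions reproducibly", {
  r1 <- suppressWarnings(run_scenario_study("S2", 200, n_reps = 3, seed = 5,
                                            risk = "fixed", nlambda = 8))
  r2 <- suppressWarnings(run_scenario_study("S2", 200, n_reps = 3, seed = 5,
                                            risk = "fixed", nlambda = 8))
  expect_identical(r1$proportions, r2$proportions)
  expect_true(all(r1$proportions >= 0 & r1$proportions <= 1))
  expect_equal(dim(r1$estimates), c(1, 1, 3, 8))
})
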