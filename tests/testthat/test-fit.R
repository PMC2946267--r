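# The estimation engine: adaptive weights, Gauss-Seidel solver, E-step,
# EM outer loop and BIC-based lambda selection.

freqs_sim <- haplotype_freqs_from_maf_ld(0.3, 0.4, 0.02)

frame_from_sim <- function(n, scenario, seed, ...) {
  dat <- simulate_epistasis_data(n, scenario, seed = seed, ...)
  build_model_frame(dat$genotypes[, 1:2], dat$genotypes[, 3:4], dat$phenotype,
                    risk_s = "[11]", risk_t = "[11]",
                    freqs_s = estimate_haplotype_frequencies(dat$genotypes[, 1:2]),
                    freqs_t = estimate_haplotype_frequencies(dat$genotypes[, 3:4]))
}

test_that("a penalty above lambda_max returns the all-zero genetic solution", {
  mf <- frame_from_sim(200, "S2", seed = 12)
  w <- rep(1, 8)
  null_fit <- em_fit(mf, lambda = Inf, pen_weights = w)
  lam_max <- max(abs(score_vector(mf, null_fit$theta, null_fit$weights)[1:8]))
  sol <- gauss_seidel_solve(mf, lambda = lam_max * 1.01, pen_weights = w,
                            weights = null_fit$weights)
  expect_true(all(sol$theta[1:8] == 0))
  expect_lt(sol$max_violation, 1e-5)
})

test_that("at lambda = 0 on phase-known data the solver matches the logistic MLE", {
  pk <- make_phase_known_data(300, seed = 41)
  mf <- build_model_frame(pk$gs, pk$gt, pk$y, risk_s = "[11]", risk_t = "[11]",
                          freqs_s = freqs_sim, freqs_t = freqs_sim)
  sol <- gauss_seidel_solve(mf, lambda = 0, pen_weights = rep(1, 8))
  glm_fit <- suppressWarnings(
    stats::glm(mf$y_row ~ mf$X - 1, family = stats::binomial()))
  expect_equal(unname(sol$theta), unname(stats::coef(glm_fit)),
               tolerance = 1e-5)
})

test_that("at lambda > 0 the solver reaches the proximal-gradient optimum", {
  pk <- make_phase_known_data(250, seed = 51)
  mf <- build_model_frame(pk$gs, pk$gt, pk$y, risk_s = "[11]", risk_t = "[11]",
                          freqs_s = freqs_sim, freqs_t = freqs_sim)
  pen_w <- c(1.2, 0.8, 2, 1, 1.5, 1, 3, 0.7)
  for (lambda in c(2, 10)) {
    sol <- gauss_seidel_solve(mf, lambda = lambda, pen_weights = pen_w)
    obj_gs <- penalized_objective(mf, sol$theta, lambda, pen_w)
    oracle <- fista_l1_logistic(mf$X, mf$y_row, rep(1, nrow(mf$X)),
                                lambda, pen_w, pen_idx = 1:8)
    expect_lt(abs(obj_gs - oracle$objective), 1e-6 * (1 + abs(oracle$objective)))
    expect_lte(obj_gs, oracle$objective + 1e-6)
  }
})

test_that("E-step posteriors follow Bayes' rule", {
  mf <- frame_from_sim(400, "S4", seed = 13)
  # all genetic effects zero: the likelihood cancels and E(c) = phi
  es0 <- e_step(mf, numeric(ncol(mf$X)))
  expect_equal(unname(es0$E_cs[mf$amb_s]),
               rep(mf$phi_s, sum(mf$amb_s)), tolerance = 1e-12)
  expect_equal(unname(es0$E_ct[mf$amb_t]),
               rep(mf$phi_t, sum(mf$amb_t)), tolerance = 1e-12)
  # nonzero coefficients: M4 posteriors match brute-force enumeration
  set.seed(14)
  theta <- c(rnorm(8, 0, 0.6), 0.3)
  es <- e_step(mf, theta)
  m4 <- which(mf$group == "M4")
  expect_gt(length(m4), 0)
  for (i in m4) {
    oracle <- brute_force_m4_posterior(theta, mf$y[i],
                                       phi_s = mf$phi_s, phi_t = mf$phi_t)
    expect_equal(unname(es$E_cs[i]), oracle$E_cs, tolerance = 1e-12)
    expect_equal(unname(es$E_ct[i]), oracle$E_ct, tolerance = 1e-12)
    expect_equal(unname(es$weights[mf$subject == i]), unname(oracle$post),
                 tolerance = 1e-12)
  }
})

test_that("a prior of 1 forces E(c) = 1 regardless of coefficients", {
  gs <- rbind(c(1, 1), c(0, 0)); gt <- rbind(c(0, 1), c(2, 2))
  f_det <- c(0.6, 0, 0.1, 0.3)   # p12 = 0: only [11][22] possible, phi = 1
  mf <- build_model_frame(gs, gt, y = c(1L, 0L), risk_s = "[11]",
                          risk_t = "[11]", freqs_s = f_det, freqs_t = freqs_sim)
  set.seed(15)
  es <- e_step(mf, c(rnorm(8), 0.5))
  expect_equal(unname(es$E_cs[1]), 1, tolerance = 1e-12)
})

test_that("EM without ambiguous subjects reduces to a single M-step", {
  pk <- make_phase_known_data(200, seed = 61)
  mf <- build_model_frame(pk$gs, pk$gt, pk$y, risk_s = "[11]", risk_t = "[11]",
                          freqs_s = freqs_sim, freqs_t = freqs_sim)
  fit <- em_fit(mf, lambda = 3, pen_weights = rep(1, 8))
  sol <- gauss_seidel_solve(mf, lambda = 3, pen_weights = rep(1, 8))
  expect_equal(fit$theta, sol$theta, tolerance = 1e-10)
  expect_lte(fit$em_iterations, 2)
})

test_that("the observed-data penalized objective never increases across EM iterations", {
  for (seed in c(16, 17, 18)) {
    mf <- frame_from_sim(300, "S4", seed = seed)
    fit <- em_fit(mf, lambda = 2, pen_weights = rep(1, 8))
    expect_true(fit$converged)
    expect_true(all(diff(fit$objective) <= 1e-8))
  }
})

test_that("adaptive weights are reciprocal reference estimates with the cap", {
  mf <- frame_from_sim(500, "S2", seed = 19)
  w <- adaptive_weights(mf)
  b <- attr(w, "beta_ref")
  expect_equal(as.numeric(w), as.numeric(1 / pmax(abs(b), 1e-3)))
  expect_true(all(w <= 1000 + 1e-9))
  # a raised floor binds: |reference estimates| below it are capped at 1/floor
  w2 <- adaptive_weights(mf, floor = 10)
  expect_true(all(abs(w2 - 0.1) < 1e-12 | abs(b) > 10))
  # the reference fit matches the Gauss-Seidel solution at lambda = 0 on a
  # well-conditioned dataset
  mf2 <- frame_from_sim(300, "S2", seed = 24)
  w3 <- adaptive_weights(mf2)
  gs0 <- em_fit(mf2, lambda = 0, pen_weights = rep(1, 8))
  expect_equal(as.numeric(attr(w3, "beta_ref")), as.numeric(gs0$beta),
               tolerance = 1e-4)
})

test_that("BIC of the intercept-only null model matches the closed form", {
  # 100 balanced subjects, no genetic effect selected: the intercept MLE is 0
  gs <- matrix(0L, 100, 2); gt <- matrix(0L, 100, 2)
  y <- rep(c(0L, 1L), 50)
  mf <- build_model_frame(gs, gt, y, risk_s = "[11]", risk_t = "[11]",
                          freqs_s = freqs_sim, freqs_t = freqs_sim)
  fit <- em_fit(mf, lambda = Inf, pen_weights = rep(1, 8))
  expect_equal(fit$bic, -2 * 100 * log(0.5) + log(100), tolerance = 1e-6)
  expect_equal(fit$df, 1)
})

test_that("select_lambda picks the minimum-BIC fit, sparser on ties", {
  mf <- frame_from_sim(400, "S2", seed = 20)
  w <- adaptive_weights(mf)
  path <- select_lambda(mf, w, nlambda = 20)
  expect_equal(path$bic[path$best], min(path$bic))
  # descending grid + which.min: any earlier (larger-lambda) tie would win
  expect_true(all(path$bic[seq_len(path$best - 1)] > path$bic[path$best]))
  # the largest lambda keeps all genetic effects at zero
  expect_true(all(path$coefficients[1, 1:8] == 0))
  expect_equal(path$df[1], 1)
})

test_that("the number of selected effects is non-increasing in lambda (phase-known)", {
  pk <- make_phase_known_data(400, seed = 71,
                              effects = c(0.8, 0.8, 0.5, 0, 0.6, 0, 0, 0))
  mf <- build_model_frame(pk$gs, pk$gt, pk$y, risk_s = "[11]", risk_t = "[11]",
                          freqs_s = freqs_sim, freqs_t = freqs_sim)
  w <- adaptive_weights(mf)
  path <- select_lambda(mf, w, nlambda = 25)
  nnz <- rowSums(path$coefficients[, 1:8, drop = FALSE] != 0)
  # grid is descending in lambda, so nnz should be non-decreasing down it;
  # tolerate single-step wobble from the discrete grid
  expect_true(all(diff(nnz) >= -1))
  expect_gte(sum(diff(nnz) >= 0), length(nnz) - 2)
})

test_that("every converged fit passes the KKT audit", {
  for (seed in c(22, 23)) {
    mf <- frame_from_sim(250, "S4", seed = seed)
    w <- adaptive_weights(mf)
    path <- select_lambda(mf, w, nlambda = 15)
    expect_lt(kkt_audit(path$fit), 1e-5)
  }
})
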