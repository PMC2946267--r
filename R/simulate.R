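# Case-control simulator for two-block haplotype epistasis: HWE haplotype
# draws with specified MAFs and linkage disequilibrium, Bernoulli phenotypes
# under the Cockerham effect scenarios, and the Monte-Carlo scenario study.

#' Two-locus haplotype frequencies from allele frequencies and LD
#'
#' Allele "1" is the major allele and "2" the minor allele at each SNP; `D`
#' is the linkage-disequilibrium coefficient of the major-major haplotype:
#' `p11 = (1-maf1)(1-maf2) + D`, `p12 = (1-maf1) maf2 - D`,
#' `p21 = maf1 (1-maf2) - D`, `p22 = maf1 maf2 + D`.
#'
#' @param maf1,maf2 Minor allele frequencies of the two SNPs.
#' @param D Linkage-disequilibrium coefficient.
#' @return Object of class `hap_freqs` (named frequencies `[11],[12],[21],[22]`).
#' @examples
#' haplotype_freqs_from_maf_ld(0.3, 0.4, 0.02)  # 0.44 0.26 0.16 0.14
#' @export
haplotype_freqs_from_maf_ld <- function(maf1, maf2, D) {
  stopifnot(length(maf1) == 1L, length(maf2) == 1L, length(D) == 1L)
  if (!is.finite(maf1) || maf1 <= 0 || maf1 >= 1 ||
      !is.finite(maf2) || maf2 <= 0 || maf2 >= 1)
    stop("minor allele frequencies must lie strictly between 0 and 1")
  p <- c(
    p11 = (1 - maf1) * (1 - maf2) + D,
    p12 = (1 - maf1) * maf2 - D,
    p21 = maf1 * (1 - maf2) - D,
    p22 = maf1 * maf2 + D
  )
  bad <- which(p < 0 | p > 1)
  if (length(bad))
    stop("D = ", D, " violates the frequency bound for haplotype ",
         paste(c("[11]", "[12]", "[21]", "[22]")[bad], collapse = ", "),
         " (frequency ", paste(signif(p[bad], 4), collapse = ", "), ")")
  structure(as.numeric(p), names = paste0("p", haplotypes()),
            class = "hap_freqs", iterations = 0L, converged = TRUE,
            loglik = numeric(0), identifiable = TRUE)
}

#' Genetic-effect vectors of the simulation scenarios
#'
#' Five standard scenarios for the eight effects
#' `(a_s, a_t, d_s, d_t, i_aa, i_ad, i_da, i_dd)`: `S0` all zero (null);
#' `S1` all effects present; `S2` additive effects of both blocks only;
#' `S3` both blocks' main effects, no interaction; `S4` main effects of
#' block s plus all four interactions.
#'
#' @param scenario One of `"S0"`-`"S4"`.
#' @param effect_size Magnitude used for the active effects (default 0.8).
#' @return Named numeric vector of length 8.
#' @export
scenario_effects <- function(scenario, effect_size = 0.8) {
  patterns <- list(
    S0 = c(0, 0, 0, 0, 0, 0, 0, 0),
    S1 = c(1, 1, 1, 1, 1, 1, 1, 1),
    S2 = c(1, 1, 0, 0, 0, 0, 0, 0),
    S3 = c(1, 1, 1, 1, 0, 0, 0, 0),
    S4 = c(1, 0, 1, 0, 1, 1, 1, 1)
  )
  if (!scenario %in% names(patterns)) stop("unknown scenario: ", scenario)
  structure(patterns[[scenario]] * effect_size, names = effect_names())
}

#' Calibrate the intercept for a balanced case/control ratio
#'
#' Solves `E[logistic(mu + x beta)] = target` over the exact composite-
#' diplotype distribution (9 cells, HWE within block, blocks independent)
#' by root bracketing, so that simulated samples have the requested expected
#' case fraction.
#'
#' @param effects Length-8 genetic effect vector.
#' @param freqs_s,freqs_t Block haplotype frequencies.
#' @param risk_s,risk_t Risk haplotypes used to define the composite
#'   diplotypes.
#' @param target Desired expected case fraction (default 0.5).
#' @return The intercept `mu`.
#' @export
calibrate_intercept <- function(effects, freqs_s, freqs_t,
                                risk_s = "[11]", risk_t = "[11]",
                                target = 0.5) {
  rs <- normalize_hap(risk_s); rt <- normalize_hap(risk_t)
  ps <- check_freqs(freqs_s)[rs]; pt <- check_freqs(freqs_t)[rt]
  w_s <- c(ps^2, 2 * ps * (1 - ps), (1 - ps)^2)         # copies 2, 1, 0
  w_t <- c(pt^2, 2 * pt * (1 - pt), (1 - pt)^2)
  cells <- expand.grid(ks = c(2L, 1L, 0L), kt = c(2L, 1L, 0L))
  wt <- w_s[3L - cells$ks] * w_t[3L - cells$kt]
  eta_g <- drop(design_matrix(cells$ks, cells$kt) %*% effects)
  f <- function(mu) sum(wt * stats::plogis(mu + eta_g)) - target
  stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
}

#' Simulate a two-block case-control dataset
#'
#' Draws two haplotypes per block per subject i.i.d. from the block
#' frequencies (Hardy-Weinberg equilibrium), collapses them to unphased
#' 0/1/2 genotypes, computes the phase-known Cockerham design row relative
#' to the true risk-haplotype pair, and draws the phenotype from
#' `Bernoulli(logistic(mu + x beta))` with the intercept calibrated for a
#' balanced design. Phase is not part of the observable data but is kept in
#' the `truth` component for benchmarking.
#'
#' @param n Sample size.
#' @param scenario Scenario name passed to [scenario_effects()]; ignored if
#'   `effects` is given.
#' @param effects Optional explicit length-8 effect vector.
#' @param maf_s,maf_t Minor allele frequencies of the two SNPs in each block.
#' @param D_s,D_t Linkage disequilibrium within each block.
#' @param risk_s,risk_t True risk haplotypes (default `[11]`, major-major).
#' @param effect_size Effect magnitude for scenario patterns.
#' @param seed Optional RNG seed.
#' @return Object of class `hapepi_sim`: `genotypes` (n x 4 matrix, columns
#'   `s1,s2,t1,t2`), `phenotype`, and `truth` (effects, intercept, risk pair,
#'   frequencies, hidden phase and risk-copy counts).
#' @export
simulate_epistasis_data <- function(n, scenario = "S0", effects = NULL,
                                    maf_s = c(0.3, 0.4), maf_t = c(0.3, 0.4),
                                    D_s = 0.02, D_t = 0.02,
                                    risk_s = "[11]", risk_t = "[11]",
                                    effect_size = 0.8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(effects)) effects <- scenario_effects(scenario, effect_size)
  if (length(effects) != 8L) stop("effects must have length 8")
  effects <- structure(as.numeric(effects), names = effect_names())
  fs <- haplotype_freqs_from_maf_ld(maf_s[1L], maf_s[2L], D_s)
  ft <- haplotype_freqs_from_maf_ld(maf_t[1L], maf_t[2L], D_t)
  rs <- normalize_hap(risk_s); rt <- normalize_hap(risk_t)
  mu <- calibrate_intercept(effects, fs, ft, rs, rt)
  hs1 <- sample.int(4L, n, replace = TRUE, prob = fs)
  hs2 <- sample.int(4L, n, replace = TRUE, prob = fs)
  ht1 <- sample.int(4L, n, replace = TRUE, prob = ft)
  ht2 <- sample.int(4L, n, replace = TRUE, prob = ft)
  geno <- cbind(
    s1 = (hap_allele1(hs1) - 1L) + (hap_allele1(hs2) - 1L),
    s2 = (hap_allele2(hs1) - 1L) + (hap_allele2(hs2) - 1L),
    t1 = (hap_allele1(ht1) - 1L) + (hap_allele1(ht2) - 1L),
    t2 = (hap_allele2(ht1) - 1L) + (hap_allele2(ht2) - 1L)
  )
  copies_s <- (hs1 == rs) + (hs2 == rs)
  copies_t <- (ht1 == rt) + (ht2 == rt)
  eta <- mu + drop(design_matrix(copies_s, copies_t) %*% effects)
  y <- stats::rbinom(n, 1L, stats::plogis(eta))
  structure(list(
    genotypes = geno, phenotype = y,
    truth = list(effects = effects, intercept = mu,
                 risk_s = hap_label(rs), risk_t = hap_label(rt),
                 freqs_s = fs, freqs_t = ft,
                 phase = cbind(hs1 = hs1, hs2 = hs2, ht1 = ht1, ht2 = ht2),
                 copies = cbind(copies_s = copies_s, copies_t = copies_t))
  ), class = "hapepi_sim")
}

#' @export
print.hapepi_sim <- function(x, ...) {
  cat(sprintf("simulated two-block dataset: n = %d, case fraction %.3f\n",
              length(x$phenotype), mean(x$phenotype)))
  cat("true nonzero effects:",
      if (any(x$truth$effects != 0))
        paste(names(x$truth$effects)[x$truth$effects != 0], collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' Monte-Carlo scenario study of selection rates
#'
#' For each scenario and sample size, simulates `n_reps` datasets, runs the
#' analysis pipeline (haplotype frequency estimation, adaptive weights,
#' BIC-tuned penalty path, optionally the full risk-haplotype search) and
#' tabulates the proportion of replicates in which each genetic effect is
#' selected nonzero. Under the null scenario these proportions are the
#' per-parameter false selection rates; elsewhere they are selection power.
#'
#' @param scenarios Character vector of scenario names.
#' @param sample_sizes Integer vector of sample sizes.
#' @param n_reps Replicates per cell (the conventional study uses 200).
#' @param seed Base seed; per-replicate seeds are derived from it, so the
#'   study is reproducible and replicates are independent.
#' @param risk `"fixed"` fits with the true risk pair; `"search"` runs the
#'   full 16-candidate BIC search per replicate.
#' @param nlambda,lambda_min_ratio Penalty path settings.
#' @param effect_size,maf,D Generator settings (both blocks share them).
#' @param progress Print a line per completed cell.
#' @return Object of class `hapepi_scenarios` with the selection-proportion
#'   array `proportions` (scenario x size x effect), the estimate array
#'   `estimates` (scenario x size x rep x effect), failure counts and the
#'   study settings.
#' @export
run_scenario_study <- function(scenarios = c("S0", "S1", "S2", "S3", "S4"),
                               sample_sizes = c(200L, 500L, 1000L),
                               n_reps = 200L, seed = 1L,
                               risk = c("search", "fixed"),
                               nlambda = 50L, lambda_min_ratio = 0.001,
                               effect_size = 0.8,
                               maf = c(0.3, 0.4), D = 0.02,
                               progress = FALSE) {
  risk <- match.arg(risk)
  if (n_reps < 1L) stop("n_reps must be >= 1")
  set.seed(seed)
  nS <- length(scenarios); nN <- length(sample_sizes)
  rep_seeds <- array(sample.int(.Machine$integer.max - 1L, nS * nN * n_reps),
                     dim = c(nS, nN, n_reps))
  est <- array(NA_real_, dim = c(nS, nN, n_reps, 8L),
               dimnames = list(scenarios, sample_sizes, NULL, effect_names()))
  failures <- matrix(0L, nS, nN, dimnames = list(scenarios, sample_sizes))
  for (si in seq_len(nS)) for (ni in seq_len(nN)) {
    for (r in seq_len(n_reps)) {
      res <- tryCatch({
        dat <- simulate_epistasis_data(sample_sizes[ni], scenario = scenarios[si],
                                       maf_s = maf, maf_t = maf, D_s = D, D_t = D,
                                       effect_size = effect_size,
                                       seed = rep_seeds[si, ni, r])
        gs <- dat$genotypes[, 1:2]; gt <- dat$genotypes[, 3:4]
        if (risk == "fixed") {
          fs <- estimate_haplotype_frequencies(gs)
          ft <- estimate_haplotype_frequencies(gt)
          mf <- build_model_frame(gs, gt, dat$phenotype,
                                  risk_s = dat$truth$risk_s,
                                  risk_t = dat$truth$risk_t,
                                  freqs_s = fs, freqs_t = ft)
          w <- adaptive_weights(mf)
          select_lambda(mf, w, nlambda = nlambda,
                        lambda_min_ratio = lambda_min_ratio)$fit$beta
        } else {
          search_risk_haplotypes(gs, gt, dat$phenotype,
                                 nlambda = nlambda,
                                 lambda_min_ratio = lambda_min_ratio)$fit$beta
        }
      }, error = function(e) NULL)
      if (is.null(res)) failures[si, ni] <- failures[si, ni] + 1L
      else est[si, ni, r, ] <- res
    }
    if (progress)
      message(sprintf("scenario %s, n = %d done (%d failures)",
                      scenarios[si], sample_sizes[ni], failures[si, ni]))
  }
  sel <- est != 0
  proportions <- apply(sel, c(1, 2, 4), mean, na.rm = TRUE)
  structure(list(
    proportions = proportions, estimates = est, selected = sel,
    failures = failures, n_reps = n_reps, scenarios = scenarios,
    sample_sizes = sample_sizes, risk = risk, seed = seed,
    effect_size = effect_size, maf = maf, D = D
  ), class = "hapepi_scenarios")
}

#' @export
print.hapepi_scenarios <- function(x, ...) {
  cat(sprintf("scenario study: %d replicates per cell, risk %s\n",
              x$n_reps, x$risk))
  for (s in x$scenarios) {
    cat("\nselection proportions,", s, "\n")
    print(round(x$proportions[s, , , drop = TRUE], 3))
  }
  invisible(x)
}

#' Bar plot of per-effect selection proportions
#'
#' Grouped bars per genetic effect, one bar per sample size, one panel per
#' scenario, with a dashed line at the 0.05 nominal level.
#'
#' @param x A `hapepi_scenarios` object.
#' @param ... Unused.
#' @export
plot.hapepi_scenarios <- function(x, ...) {
  old <- graphics::par(mfrow = c(length(x$scenarios), 1),
                       mar = c(3, 4, 2, 1))
  on.exit(graphics::par(old))
  for (s in x$scenarios) {
    m <- x$proportions[s, , , drop = FALSE]
    m <- matrix(m, nrow = length(x$sample_sizes),
                dimnames = list(x$sample_sizes, effect_names()))
    graphics::barplot(m, beside = TRUE, ylim = c(0, 1),
                      legend.text = rownames(m),
                      args.legend = list(x = "topright", bty = "n", cex = 0.7),
                      main = paste("scenario", s), ylab = "proportion selected")
    graphics::abline(h = 0.05, lty = 2)
  }
  invisible(x)
}
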