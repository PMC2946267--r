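# Mixture likelihood for a block pair under a candidate risk-haplotype pair.
#
# Each subject is expanded into 1, 2 or 4 rows, one per compatible pair of
# composite diplotypes: group M1 subjects (no phase ambiguity) get a single
# row; M2/M3 (one block ambiguous) get two rows, c = 1 (one risk copy, HHbar)
# and c = 0 (HbarHbar); M4 (both ambiguous) get the 4-cell grid. Row priors
# are products of the per-block probabilities P(c = 1). The E-step replaces
# priors by posterior cell weights; the weighted complete-data log-likelihood,
# its gradient and the KKT violations all operate on this expanded frame.

PROB_CLIP <- 1e-12

clip_prob <- function(p) pmin(pmax(p, PROB_CLIP), 1 - PROB_CLIP)

#' Build the expanded model frame for one risk-haplotype pair
#'
#' @param gs,gt n x 2 genotype matrices (0/1/2 codes) for blocks s and t.
#' @param y Binary phenotype (0 = control, 1 = case).
#' @param covariates Optional numeric matrix of covariates (no intercept
#'   column; one is added automatically).
#' @param risk_s,risk_t Candidate risk haplotypes (index 1-4 or `"[11]"` etc).
#' @param freqs_s,freqs_t Haplotype frequencies for the two blocks.
#' @return A list of class `hapepi_frame` holding the expanded design matrix
#'   `X` (8 genetic columns then intercept and covariates), per-row phenotype,
#'   subject index, prior mixture weights, candidate phase indicators and
#'   block-level metadata. Used by the likelihood, score and fitting
#'   functions.
#' @export
build_model_frame <- function(gs, gt, y, covariates = NULL,
                              risk_s, risk_t, freqs_s, freqs_t) {
  gs <- as_geno_matrix(gs); gt <- as_geno_matrix(gt)
  n <- nrow(gs)
  if (nrow(gt) != n) stop("blocks must cover the same subjects")
  y <- as.integer(y)
  if (length(y) != n || any(is.na(y)) || any(!y %in% 0:1))
    stop("phenotype must be a 0/1 vector matching the genotypes")
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) stop("covariates must have one row per subject")
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
  }
  bs <- block_map(gs, risk_s, freqs_s)
  bt <- block_map(gt, risk_t, freqs_t)
  amb_s <- bs$ambiguous; amb_t <- bt$ambiguous
  # candidate (copies, c-indicator, prior) per subject and block
  ncell <- ifelse(amb_s, 2L, 1L) * ifelse(amb_t, 2L, 1L)
  subject <- rep.int(seq_len(n), ncell)
  # per-row candidate index within subject, expanded s-major
  cs <- ct <- integer(sum(ncell))
  prior <- numeric(sum(ncell))
  cind_s <- rep(NA_integer_, sum(ncell))
  cind_t <- rep(NA_integer_, sum(ncell))
  pos <- 1L
  for (i in seq_len(n)) {
    s_opts <- if (amb_s[i]) c(1L, 0L) else bs$copies[i]
    s_pri  <- if (amb_s[i]) c(bs$p_c1, 1 - bs$p_c1) else 1
    t_opts <- if (amb_t[i]) c(1L, 0L) else bt$copies[i]
    t_pri  <- if (amb_t[i]) c(bt$p_c1, 1 - bt$p_c1) else 1
    for (a in seq_along(s_opts)) for (b in seq_along(t_opts)) {
      cs[pos] <- s_opts[a]; ct[pos] <- t_opts[b]
      prior[pos] <- s_pri[a] * t_pri[b]
      if (amb_s[i]) cind_s[pos] <- s_opts[a]
      if (amb_t[i]) cind_t[pos] <- t_opts[b]
      pos <- pos + 1L
    }
  }
  Xg <- design_matrix(cs, ct)
  Xe <- cbind("(Intercept)" = rep(1, length(subject)))
  if (!is.null(covariates)) Xe <- cbind(Xe, covariates[subject, , drop = FALSE])
  X <- cbind(Xg, Xe)
  group <- classify_phase_groups(gs, gt)
  structure(list(
    X = X, y_row = y[subject], subject = subject, prior = prior,
    cind_s = cind_s, cind_t = cind_t,
    n = n, y = y, group = group,
    amb_s = amb_s, amb_t = amb_t,
    phi_s = bs$p_c1, phi_t = bt$p_c1,
    risk_s = bs$risk, risk_t = bt$risk,
    p_pen = 8L, q = ncol(Xe),
    coef_names = colnames(X)
  ), class = "hapepi_frame")
}

row_probs <- function(mf, theta) {
  clip_prob(stats::plogis(drop(mf$X %*% theta)))
}

#' Weighted complete-data log-likelihood
#'
#' The Bernoulli log-likelihood of the expanded frame with per-row weights:
#' group M1 rows have weight 1, mixture rows carry their E-step posterior
#' (or prior) weights. Probabilities are clipped to `[1e-12, 1 - 1e-12]`
#' before taking logs.
#'
#' @param mf A [build_model_frame()] object.
#' @param theta Coefficient vector: 8 genetic effects then intercept and
#'   covariates.
#' @param weights Per-row weights; defaults to the prior mixture weights.
#' @return The scalar weighted log-likelihood `L`.
#' @export
weighted_loglik <- function(mf, theta, weights = mf$prior) {
  p <- row_probs(mf, theta)
  sum(weights * ifelse(mf$y_row == 1L, log(p), log1p(-p)))
}

#' Observed-data log-likelihood
#'
#' Marginalizes the phase mixture: each subject contributes
#' `log(sum_cells prior * Bernoulli(pi_cell))`.
#' @inheritParams weighted_loglik
#' @export
observed_loglik <- function(mf, theta) {
  p <- row_probs(mf, theta)
  b <- ifelse(mf$y_row == 1L, p, 1 - p)
  sum(log(rowsum(mf$prior * b, mf$subject)[, 1L]))
}

penalty_term <- function(beta, lambda, pen_weights) {
  s <- sum(pen_weights * abs(beta))
  if (s == 0) 0 else lambda * s   # keeps lambda = Inf with beta = 0 finite
}

#' Adaptive-L1 penalized objective
#'
#' `L' = -2 L + lambda * sum_j w_j |beta_j|`, penalizing only the 8 genetic
#' effects; the intercept and covariates are never penalized.
#'
#' @inheritParams weighted_loglik
#' @param lambda Penalty tuning parameter (>= 0).
#' @param pen_weights Positive weights for the 8 genetic effects.
#' @export
penalized_objective <- function(mf, theta, lambda, pen_weights, weights = mf$prior) {
  -2 * weighted_loglik(mf, theta, weights) +
    penalty_term(theta[seq_len(mf$p_pen)], lambda, pen_weights)
}

# Observed-data penalized objective (the quantity EM decreases).
observed_objective <- function(mf, theta, lambda, pen_weights) {
  -2 * observed_loglik(mf, theta) +
    penalty_term(theta[seq_len(mf$p_pen)], lambda, pen_weights)
}

#' Score of the doubled log-likelihood
#'
#' `F_j = d(2L)/d theta_j` of the weighted complete-data log-likelihood:
#' `F_j = 2 * sum_rows w x_j (y - pi)`. The first-order optimality conditions
#' of the penalized objective are `F_j = 0` for unpenalized coordinates and
#' `F_j = sign(beta_j) w_j lambda` (or `|F_j| <= w_j lambda` at zero) for the
#' penalized ones.
#'
#' @inheritParams weighted_loglik
#' @return `score_vector()` returns the full named gradient;
#'   `score_component()` the single coordinate `j`.
#' @export
score_vector <- function(mf, theta, weights = mf$prior) {
  p <- row_probs(mf, theta)
  drop(2 * crossprod(mf$X, weights * (mf$y_row - p)))
}

#' @rdname score_vector
#' @param j Coordinate index into `theta`.
#' @export
score_component <- function(mf, theta, weights = mf$prior, j) {
  score_vector(mf, theta, weights)[[j]]
}

#' First-order optimality violation of a coordinate
#'
#' The four-case violation used by the maximum-violator Gauss-Seidel solver:
#' unpenalized coordinates use `|F_j|`; for penalized coordinates it is
#' `|w_j lambda - F_j|` when `beta_j > 0`, `|w_j lambda + F_j|` when
#' `beta_j < 0`, and `max(F_j - w_j lambda, -F_j - w_j lambda, 0)` at zero.
#' All are zero exactly at a solution.
#'
#' @param F_j Score component(s) `d(2L)/d beta_j`.
#' @param beta_j Current coefficient value(s).
#' @param w_j Penalty weight(s).
#' @param lambda Penalty tuning parameter.
#' @param unpenalized Logical (recycled): treat the coordinate as unpenalized.
#' @return Violation value(s), >= 0.
#' @export
kkt_violation <- function(F_j, beta_j, w_j, lambda, unpenalized = FALSE) {
  m <- max(length(F_j), length(beta_j), length(w_j))
  F_j <- rep_len(F_j, m); beta_j <- rep_len(beta_j, m)
  thr <- rep_len(w_j * lambda, m); unpenalized <- rep_len(unpenalized, m)
  v <- ifelse(unpenalized, abs(F_j),
       ifelse(beta_j > 0, abs(thr - F_j),
       ifelse(beta_j < 0, abs(thr + F_j),
              pmax(F_j - thr, -F_j - thr, 0))))
  as.numeric(v)
}

# All-coordinate violations at a given state. ridge is the optional
# ridge-stabilization coefficient applied to the genetic effects.
violations <- function(mf, theta, weights, lambda, pen_weights, ridge = 0) {
  Fv <- score_vector(mf, theta, weights)
  if (ridge > 0) {
    idx <- seq_len(mf$p_pen)
    Fv[idx] <- Fv[idx] - 2 * ridge * theta[idx]
  }
  pen <- seq_len(mf$p_pen)
  v <- numeric(length(theta))
  v[pen] <- kkt_violation(Fv[pen], theta[pen], pen_weights, lambda)
  v[-pen] <- abs(Fv[-pen])
  v
}

#' KKT audit of a fitted model
#'
#' Recomputes all first-order violations at the fitted coefficients with the
#' final E-step weights and returns the maximum. A converged fit should be
#' below `1e-5`.
#'
#' @param fit An `hapepi_emfit` object (see [em_fit()]).
#' @return The maximum violation across coordinates.
#' @export
kkt_audit <- function(fit) {
  max(violations(fit$frame, fit$theta, fit$weights, fit$lambda,
                 fit$pen_weights, ridge = fit$ridge))
}
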