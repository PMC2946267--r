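# Estimation engine: maximum-violator Gauss-Seidel coordinate solver for the
# adaptive-L1 penalized logistic objective, the E-step posterior update, the
# EM outer loop, BIC-based lambda selection, and adaptive penalty weights.

# Exact one-dimensional coordinate solve. Finds the root of
#   f(b) = 2 sum(w x (y - pi(eta_minus + x b))) - 2 ridge b - target
# which is strictly decreasing in b, by bracketed Newton on the rows where
# x != 0 (zero-code rows are invariant in b). Returns the root, or +-bmax
# with a separation flag when the root lies beyond the bracket cap.
solve_coordinate <- function(x, eta_minus, y, w, target, b_init,
                             ridge = 0, bmax = 100, tol_f = 1e-6) {
  wx <- w * x
  wyx <- sum(wx * y)
  feval <- function(b) {
    p <- 1 / (1 + exp(-(eta_minus + x * b)))
    list(f = 2 * (wyx - sum(wx * p)) - 2 * ridge * b - target,
         h = 2 * sum(wx * x * p * (1 - p)) + 2 * ridge)
  }
  b <- b_init
  ev <- feval(b)
  if (abs(ev$f) <= tol_f) return(list(b = b, separation = FALSE))
  # expand a bracket [lo, hi] with f(lo) > 0 > f(hi)
  if (ev$f > 0) {
    lo <- b
    step <- max(1, abs(ev$f) / max(ev$h, 1e-8))
    hi <- NA_real_
    while (is.na(hi)) {
      cand <- lo + step
      if (cand > bmax) return(list(b = bmax, separation = TRUE))
      if (feval(cand)$f <= 0) hi <- cand else { lo <- cand; step <- 2 * step }
    }
  } else {
    hi <- b
    step <- max(1, abs(ev$f) / max(ev$h, 1e-8))
    lo <- NA_real_
    while (is.na(lo)) {
      cand <- hi - step
      if (cand < -bmax) return(list(b = -bmax, separation = TRUE))
      if (feval(cand)$f >= 0) lo <- cand else { hi <- cand; step <- 2 * step }
    }
  }
  b <- (lo + hi) / 2
  for (k in seq_len(100L)) {
    ev <- feval(b)
    if (abs(ev$f) <= tol_f) break
    if (ev$f > 0) lo <- b else hi <- b
    bn <- b + ev$f / ev$h
    if (!is.finite(bn) || bn <= lo || bn >= hi) bn <- (lo + hi) / 2
    if (abs(bn - b) < 1e-14) { b <- bn; break }
    b <- bn
  }
  list(b = b, separation = FALSE)
}

#' Gauss-Seidel maximum-violator solver for the penalized objective
#'
#' Minimizes `-2L + lambda sum_j w_j |beta_j|` (for fixed mixture weights) one
#' coordinate at a time: coefficients start at zero, the worst violator among
#' the zero penalized coordinates is brought into the active set, then the
#' active set (which always contains the unpenalized intercept/covariates) is
#' cycled over its own maximum violators until clean, and the outer loop
#' repeats until no coordinate violates the first-order conditions by more
#' than `tol`. Each single-coordinate update is an exact scalar solve of the
#' piecewise-smooth objective (bracketed Newton on the score equation, with
#' the subgradient test deciding whether the coordinate stays at the kink).
#'
#' @param mf A [build_model_frame()] object.
#' @param lambda Penalty tuning parameter; `Inf` freezes all genetic effects
#'   at zero (used for the null fit).
#' @param pen_weights Positive penalty weights for the 8 genetic effects.
#' @param weights Per-row mixture weights (defaults to the priors).
#' @param init Optional warm-start coefficient vector.
#' @param ridge Optional ridge stabilization added to the genetic effects
#'   (used by the separation fallback of [adaptive_weights()]).
#' @param tol Violation threshold for convergence (default `1e-5`).
#' @param max_updates Cap on coordinate updates before aborting.
#' @return List with `theta` (named coefficients), `updates`, `max_violation`
#'   and `separation`.
#' @export
gauss_seidel_solve <- function(mf, lambda, pen_weights, weights = mf$prior,
                               init = NULL, ridge = 0, tol = 1e-5,
                               max_updates = 10000L) {
  p_tot <- ncol(mf$X)
  pen <- seq_len(mf$p_pen)
  if (length(pen_weights) != mf$p_pen || any(!is.finite(pen_weights)) ||
      any(pen_weights <= 0))
    stop("pen_weights must be ", mf$p_pen, " finite positive values")
  theta0 <- if (is.null(init)) numeric(p_tot) else as.numeric(init)
  if (length(theta0) != p_tot) stop("init has the wrong length")

  # internal column standardization: solve in X_j / s_j with beta_j * s_j,
  # an exact reparameterization that equalizes coordinate curvatures (the
  # raw additive/dominance/interaction codes differ several-fold in scale,
  # which slows one-coordinate descent badly). Mapped back on exit.
  wsum <- sum(weights)
  s <- sqrt(colSums(weights * mf$X^2) / wsum)
  s <- pmax(s, 1e-6)
  X <- sweep(mf$X, 2L, s, "/")
  pw <- pen_weights / s[pen]              # lambda * w |beta| is unchanged
  ridge_j <- ridge / s[pen]^2             # ridge * beta^2 is unchanged
  theta <- theta0 * s
  tol_s <- tol / max(1, max(s))
  eta <- drop(X %*% theta)
  separation <- FALSE
  updates <- 0L

  # per-column nonzero support: rows with x_j = 0 are invariant in theta_j
  supp <- lapply(seq_len(p_tot), function(j) which(X[, j] != 0))
  xval <- lapply(seq_len(p_tot), function(j) X[supp[[j]], j])

  sweep_violations <- function() {
    p <- 1 / (1 + exp(-eta))
    Fv <- drop(2 * crossprod(X, weights * (mf$y_row - p)))
    if (ridge > 0) Fv[pen] <- Fv[pen] - 2 * ridge_j * theta[pen]
    v <- abs(Fv)
    thr <- pw * lambda
    bp <- theta[pen]
    pos <- bp > 0; neg <- bp < 0; zer <- !(pos | neg)
    v[pen][pos] <- abs(thr[pos] - Fv[pen][pos])
    v[pen][neg] <- abs(thr[neg] + Fv[pen][neg])
    v[pen][zer] <- pmax(Fv[pen][zer] - thr[zer], -Fv[pen][zer] - thr[zer], 0)
    v
  }

  update_coord <- function(j) {
    idx <- supp[[j]]
    xj <- xval[[j]]
    em <- eta[idx] - xj * theta[j]
    yj <- mf$y_row[idx]
    wj <- weights[idx]
    rj <- if (j <= mf$p_pen) ridge_j[j] else 0
    if (j <= mf$p_pen && is.finite(lambda)) {
      F0 <- 2 * sum(wj * xj * (yj - 1 / (1 + exp(-em))))
      thr <- pw[j] * lambda
      if (abs(F0) <= thr) {
        b <- 0
      } else {
        sol <- solve_coordinate(xj, em, yj, wj,
                                target = sign(F0) * thr, b_init = theta[j],
                                ridge = rj, tol_f = tol_s / 10)
        b <- sol$b
        if (sol$separation) separation <<- TRUE
      }
    } else if (j <= mf$p_pen) {      # lambda = Inf: frozen at zero
      b <- 0
    } else {
      sol <- solve_coordinate(xj, em, yj, wj,
                              target = 0, b_init = theta[j],
                              ridge = rj, tol_f = tol_s / 10)
      b <- sol$b
      if (sol$separation) separation <<- TRUE
    }
    eta[idx] <<- em + xj * b
    theta[j] <<- b
    updates <<- updates + 1L
    if (updates > max_updates)
      stop("coordinate solver failed to converge within ", max_updates,
           " updates (max violation ",
           format(max(violations(mf, theta / s, weights, lambda, pen_weights,
                                 ridge))),
           ")")
  }

  repeat {
    # inner loop: active set I_nz = unpenalized + nonzero penalized
    repeat {
      v <- sweep_violations()
      inz <- c(pen[theta[pen] != 0], (mf$p_pen + 1L):p_tot)
      j <- inz[which.max(v[inz])]
      if (v[j] <= tol_s) break
      update_coord(j)
    }
    # outer: worst violator among the zero penalized coordinates I_z
    v <- sweep_violations()
    iz <- pen[theta[pen] == 0]
    if (length(iz) == 0L) break
    j <- iz[which.max(v[iz])]
    if (v[j] <= tol_s) break
    update_coord(j)
  }
  theta <- theta / s
  names(theta) <- mf$coef_names
  list(theta = theta, updates = updates,
       max_violation = max(violations(mf, theta, weights, lambda, pen_weights,
                                      ridge)),
       separation = separation || any(abs(eta) > 30))
}

#' E-step: posterior phase weights
#'
#' Computes the posterior probability of each mixture cell given the current
#' coefficients: `w_cell = prior_cell * Bern(pi_cell) / sum_cells(...)` per
#' subject. For subjects with one ambiguous block this is the printed
#' two-component posterior with prior `phi`; for doubly ambiguous subjects it
#' is the 4-cell joint posterior, whose margins are the conditional
#' expectations `E(c_s)` and `E(c_t)`.
#'
#' @inheritParams gauss_seidel_solve
#' @param theta Current coefficients.
#' @return List with per-row `weights` and per-subject `E_cs`, `E_ct`
#'   (NA where the corresponding block is phase-known).
#' @export
e_step <- function(mf, theta) {
  p <- row_probs(mf, theta)
  b <- ifelse(mf$y_row == 1L, p, 1 - p)
  t_ <- mf$prior * b
  denom <- rowsum(t_, mf$subject)[, 1L]
  if (any(denom <= 0)) stop("degenerate posterior: a subject has total mixture mass 0")
  w <- t_ / denom[mf$subject]
  cs <- ifelse(is.na(mf$cind_s), 0, mf$cind_s)
  ct <- ifelse(is.na(mf$cind_t), 0, mf$cind_t)
  E_cs <- rowsum(w * cs, mf$subject)[, 1L]
  E_ct <- rowsum(w * ct, mf$subject)[, 1L]
  E_cs[!mf$amb_s] <- NA_real_
  E_ct[!mf$amb_t] <- NA_real_
  list(weights = w, E_cs = E_cs, E_ct = E_ct)
}

#' EM fit of the penalized model at a fixed lambda
#'
#' Alternates the posterior phase update ([e_step()]) with the penalized
#' M-step ([gauss_seidel_solve()], warm-started from the previous
#' coefficients) until the maximum absolute coefficient change falls below
#' `tol`. The observed-data penalized objective is recorded per iteration;
#' EM guarantees it never increases.
#'
#' @inheritParams gauss_seidel_solve
#' @param tol EM convergence tolerance on coefficients.
#' @param max_iter EM iteration cap; exceeding it returns the last iterate
#'   flagged `converged = FALSE`.
#' @return Object of class `hapepi_emfit`: coefficients (`beta`, `gamma`,
#'   `theta`), final E-step weights and `E_cs`/`E_ct`, weighted and observed
#'   log-likelihoods, `objective` trace, `df`, `bic`, convergence flags.
#' @export
em_fit <- function(mf, lambda, pen_weights, init = NULL, ridge = 0,
                   tol = 1e-6, max_iter = 200L, gs_tol = 1e-5) {
  theta <- if (is.null(init)) numeric(ncol(mf$X)) else as.numeric(init)
  trace <- numeric(0)
  converged <- FALSE
  separation <- FALSE
  es <- NULL
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    es <- e_step(mf, theta)
    sol <- gauss_seidel_solve(mf, lambda, pen_weights, weights = es$weights,
                              init = theta, ridge = ridge, tol = gs_tol)
    separation <- separation || sol$separation
    delta <- max(abs(sol$theta - theta))
    theta <- sol$theta
    trace[it] <- observed_objective(mf, theta, lambda, pen_weights)
    if (delta < tol) { converged <- TRUE; break }
  }
  es <- e_step(mf, theta)
  beta <- theta[seq_len(mf$p_pen)]
  gamma <- theta[-seq_len(mf$p_pen)]
  llw <- weighted_loglik(mf, theta, es$weights)
  df <- sum(beta != 0) + mf$q
  structure(list(
    theta = theta, beta = beta, gamma = gamma,
    lambda = lambda, pen_weights = pen_weights, ridge = ridge,
    weights = es$weights, E_cs = es$E_cs, E_ct = es$E_ct,
    loglik_weighted = llw, loglik_observed = observed_loglik(mf, theta),
    objective = trace, df = df,
    bic = -2 * llw + df * log(mf$n),
    em_iterations = it, converged = converged, separation = separation,
    frame = mf
  ), class = "hapepi_emfit")
}

#' @export
print.hapepi_emfit <- function(x, ...) {
  cat(sprintf("penalized EM fit: lambda = %.4g, BIC = %.3f, df = %d, %d EM iterations%s\n",
              x$lambda, x$bic, x$df, x$em_iterations,
              if (x$converged) "" else " (NOT converged)"))
  nz <- x$beta[x$beta != 0]
  if (length(nz)) {
    cat("nonzero genetic effects:\n"); print(round(nz, 4))
  } else cat("no genetic effect selected\n")
  invisible(x)
}

# Unpenalized maximum-likelihood fit by EM-weighted Newton (IRLS).
# Used for the adaptive-weight reference estimates: full Newton handles the
# flat, strongly coupled likelihood near separation where one-coordinate
# descent needs excessive updates. `ridge` adds a quadratic stabilizer on
# the genetic effects.
em_ml_fit <- function(mf, ridge = 0, tol = 1e-6, max_iter = 200L) {
  p_tot <- ncol(mf$X)
  pen_mask <- c(rep(1, mf$p_pen), rep(0, p_tot - mf$p_pen))
  theta <- numeric(p_tot)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    es <- e_step(mf, theta)
    th <- theta
    for (k in seq_len(100L)) {
      pr <- stats::plogis(drop(mf$X %*% th))
      grad <- drop(-2 * crossprod(mf$X, es$weights * (mf$y_row - pr))) +
        2 * ridge * pen_mask * th
      H <- 2 * crossprod(mf$X, (es$weights * pr * (1 - pr)) * mf$X) +
        diag(2 * ridge * pen_mask + 1e-10, p_tot)
      step <- tryCatch(solve(H, -grad), error = function(e) NULL)
      if (is.null(step)) stop("singular Hessian in the unpenalized reference fit")
      if (max(abs(step)) > 2) step <- step * 2 / max(abs(step))  # damping
      th <- th + step
      if (max(abs(step)) < 1e-10 || max(abs(th)) > 50) break
    }
    delta <- max(abs(th - theta))
    theta <- th
    if (max(abs(theta)) > 50) break   # runaway: separation
    if (delta < tol) { converged <- TRUE; break }
  }
  names(theta) <- mf$coef_names
  list(theta = theta, beta = theta[seq_len(mf$p_pen)],
       converged = converged, em_iterations = it,
       separation = any(abs(mf$X %*% theta) > 30))
}

#' Adaptive penalty weights from the unpenalized fit
#'
#' Fits the full model without penalty (the logistic maximum-likelihood fit,
#' EM-weighted for phase-ambiguous subjects, computed by Newton iteration)
#' and sets `w_j = 1 / |beta_hat_j|`, flooring `|beta_hat_j|` at `1e-3` so
#' weights are capped at 1000. If the unpenalized fit does not converge or
#' shows separation, a ridge-stabilized fit (coefficient `1e-4`) is used
#' instead, with a warning.
#'
#' @inheritParams gauss_seidel_solve
#' @param floor Lower floor on `|beta_hat_j|`.
#' @param ... Ignored (accepted so callers can share EM settings with
#'   [em_fit()]).
#' @return Named weight vector with attribute `beta_ref` (the reference
#'   estimates) and `ridged` (whether the fallback was used).
#' @export
adaptive_weights <- function(mf, floor = 1e-3, ...) {
  if (length(unique(mf$y)) < 2L)
    stop("adaptive weights need both cases and controls")
  fit <- tryCatch(em_ml_fit(mf), error = function(e) NULL)
  ridged <- FALSE
  if (is.null(fit) || !fit$converged || fit$separation) {
    warning("unpenalized reference fit unstable (separation); using ridge-stabilized fit")
    fit <- em_ml_fit(mf, ridge = 1e-4)
    ridged <- TRUE
  }
  w <- 1 / pmax(abs(fit$beta), floor)
  names(w) <- effect_names()
  attr(w, "beta_ref") <- fit$beta
  attr(w, "ridged") <- ridged
  w
}

#' Fit the penalty path and select lambda by BIC
#'
#' Builds a log-spaced grid of `nlambda` values from `lambda_max` (the
#' smallest penalty keeping every genetic effect at zero, computed from the
#' null-model score) down to `lambda_max * lambda_min_ratio`, fits the EM
#' model at each value warm-starting from the previous solution, and returns
#' the fit minimizing `BIC = -2L + d log(n)`, where `d` counts the nonzero
#' genetic effects plus all unpenalized parameters. Ties in BIC go to the
#' larger lambda (the sparser model).
#'
#' @inheritParams gauss_seidel_solve
#' @param nlambda Number of grid points.
#' @param lambda_min_ratio Ratio of the smallest to the largest lambda.
#' @param lambda Optional explicit grid (sorted descending internally).
#' @param ... Passed to [em_fit()].
#' @return Object of class `hapepi_path`: `fit` (the selected
#'   `hapepi_emfit`), `lambda` grid, per-lambda `bic`, `df` and coefficient
#'   matrix, and the index of the winner.
#' @export
select_lambda <- function(mf, pen_weights, nlambda = 50L,
                          lambda_min_ratio = 0.001, lambda = NULL, ...) {
  null_fit <- em_fit(mf, lambda = Inf, pen_weights = pen_weights, ...)
  if (is.null(lambda)) {
    Fv <- score_vector(mf, null_fit$theta, null_fit$weights)
    lam_max <- max(abs(Fv[seq_len(mf$p_pen)]) / pen_weights)
    if (!is.finite(lam_max) || lam_max <= 0) lam_max <- 1e-3
    lambda <- exp(seq(log(lam_max), log(lam_max * lambda_min_ratio),
                      length.out = nlambda))
  } else {
    lambda <- sort(as.numeric(lambda), decreasing = TRUE)
  }
  fits <- vector("list", length(lambda))
  theta <- null_fit$theta
  any_ok <- FALSE
  for (k in seq_along(lambda)) {
    fits[[k]] <- tryCatch(
      em_fit(mf, lambda = lambda[k], pen_weights = pen_weights,
             init = theta, ...),
      error = function(e) e)
    if (!inherits(fits[[k]], "error")) {
      theta <- fits[[k]]$theta
      any_ok <- any_ok || fits[[k]]$converged
    }
  }
  ok <- !vapply(fits, inherits, logical(1L), "error") &
        vapply(fits, function(f) if (inherits(f, "error")) FALSE else f$converged,
               logical(1L))
  if (!any(ok)) stop("no lambda produced a converged fit")
  bic <- rep(Inf, length(lambda))
  df <- rep(NA_integer_, length(lambda))
  coefs <- matrix(NA_real_, length(lambda), ncol(mf$X),
                  dimnames = list(NULL, mf$coef_names))
  for (k in seq_along(lambda)) {
    if (ok[k]) {
      bic[k] <- fits[[k]]$bic
      df[k] <- fits[[k]]$df
      coefs[k, ] <- fits[[k]]$theta
    }
  }
  best <- which.min(bic)   # grid is descending: first minimum = largest lambda
  structure(list(
    fit = fits[[best]], lambda = lambda, bic = bic, df = df,
    coefficients = coefs, best = best, null_fit = null_fit
  ), class = "hapepi_path")
}

#' @export
print.hapepi_path <- function(x, ...) {
  cat(sprintf("BIC-tuned penalty path: %d lambda values, selected lambda = %.4g (BIC %.3f)\n",
              length(x$lambda), x$lambda[x$best], x$bic[x$best]))
  print(x$fit)
  invisible(x)
}
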