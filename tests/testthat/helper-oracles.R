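# Independent oracles used across the test files. These deliberately avoid
# the package's own solver paths.

# Central-difference gradient.
num_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(j) {
    e <- numeric(length(x)); e[j] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

# FISTA proximal-gradient solver for the weighted-L1 logistic problem
#   min_theta  -2 sum(w_obs * loglik) + lambda * sum(pen_w * |theta_pen|)
# Independent of the package's Gauss-Seidel implementation.
fista_l1_logistic <- function(X, y, w_obs, lambda, pen_w, pen_idx,
                              max_iter = 50000, tol = 1e-12) {
  p <- ncol(X)
  smooth <- function(th) {
    pr <- pmin(pmax(stats::plogis(drop(X %*% th)), 1e-12), 1 - 1e-12)
    -2 * sum(w_obs * (y * log(pr) + (1 - y) * log(1 - pr)))
  }
  grad <- function(th) {
    pr <- stats::plogis(drop(X %*% th))
    drop(-2 * crossprod(X, w_obs * (y - pr)))
  }
  pen_term <- function(th) lambda * sum(pen_w * abs(th[pen_idx]))
  prox <- function(v, step) {
    out <- v
    thr <- step * lambda * pen_w
    out[pen_idx] <- sign(v[pen_idx]) * pmax(abs(v[pen_idx]) - thr, 0)
    out
  }
  th <- numeric(p); z <- th; tk <- 1
  L <- 0.5 * sum(w_obs) * max(rowSums(X^2))   # conservative Lipschitz bound
  step <- 1 / L
  obj_old <- smooth(th) + pen_term(th)
  for (k in seq_len(max_iter)) {
    g <- grad(z)
    th_new <- prox(z - step * g, step)
    # backtracking in case the bound is loose the other way
    while (smooth(th_new) > smooth(z) + sum(g * (th_new - z)) +
           sum((th_new - z)^2) / (2 * step) + 1e-10) {
      step <- step / 2
      th_new <- prox(z - step * g, step)
    }
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    z <- th_new + ((tk - 1) / t_new) * (th_new - th)
    th <- th_new; tk <- t_new
    if (k %% 50 == 0) {
      obj <- smooth(th) + pen_term(th)
      if (abs(obj_old - obj) < tol * (1 + abs(obj))) break
      obj_old <- obj
    }
  }
  list(theta = th, objective = smooth(th) + pen_term(th))
}

# Brute-force Bayes posterior over the 4 joint phase configurations of a
# doubly ambiguous subject.
brute_force_m4_posterior <- function(theta, y, copies_t_fixed = NULL,
                                     phi_s, phi_t, gamma_x = 1) {
  cells <- expand.grid(cs = c(1L, 0L), ct = c(1L, 0L))[c(1, 3, 2, 4), ] # s-major
  pri <- ifelse(cells$cs == 1, phi_s, 1 - phi_s) *
         ifelse(cells$ct == 1, phi_t, 1 - phi_t)
  X <- cbind(design_matrix(cells$cs, cells$ct), gamma_x)
  pr <- stats::plogis(drop(X %*% theta))
  b <- if (y == 1) pr else 1 - pr
  post <- pri * b / sum(pri * b)
  list(post = post,
       E_cs = sum(post[cells$cs == 1]),
       E_ct = sum(post[cells$ct == 1]))
}

# Exhaustive grid search (step over the 3-simplex) for two-locus haplotype
# frequencies; independent check on the EM estimator.
grid_search_hap_freqs <- function(genotypes, step = 0.005) {
  g <- genotypes
  counts <- tabulate(g[, 1] * 3 + g[, 2] + 1, nbins = 9)
  K <- round(1 / step)
  best_ll <- -Inf; best_p <- NULL
  for (i in 0:K) {
    for (j in 0:(K - i)) {
      k <- 0:(K - i - j)
      p11 <- i * step; p12 <- j * step; p21 <- k * step
      p22 <- 1 - p11 - p12 - p21
      # genotype cell probabilities for each candidate in the k-vector
      pr <- rbind(
        p11^2, 2 * p11 * p12, p12^2,
        2 * p11 * p21, 2 * (p11 * p22 + p12 * p21), 2 * p12 * p22,
        p21^2, 2 * p21 * p22, p22^2
      )
      ll <- colSums(counts * log(pmax(pr, 1e-300)))
      m <- which.max(ll)
      if (ll[m] > best_ll) {
        best_ll <- ll[m]
        best_p <- c(p11, p12, p21[m], p22[m])
      }
    }
  }
  names(best_p) <- paste0("p", haplotypes())
  best_p
}

# Deterministic two-block dataset with known phase used by several solver
# tests (phase-known: subjects with a double heterozygote are dropped, so
# the mixture machinery is vacuous). Oversamples so that about `n` subjects
# survive and the unpenalized MLE is well-defined.
make_phase_known_data <- function(n = 300, seed = 42, effects = NULL) {
  set.seed(seed)
  if (is.null(effects)) effects <- c(0.8, 0.4, 0, 0, 0.5, 0, 0, 0)
  dat <- simulate_epistasis_data(ceiling(n / 0.6), effects = effects,
                                 seed = sample.int(1e6, 1))
  gs <- dat$genotypes[, 1:2]; gt <- dat$genotypes[, 3:4]
  amb <- (gs[, 1] == 1 & gs[, 2] == 1) | (gt[, 1] == 1 & gt[, 2] == 1)
  keep <- which(!amb)[seq_len(min(n, sum(!amb)))]
  list(gs = gs[keep, ], gt = gt[keep, ],
       y = dat$phenotype[keep], truth = dat$truth)
}
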