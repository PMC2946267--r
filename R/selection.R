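# Outer model search: choose the risk-haplotype pair by minimum BIC over all
# 4 x 4 candidates, and assess selected effects with permutation p-values.

#' Search all risk-haplotype pairs by BIC
#'
#' Every haplotype of each block is treated as a candidate risk haplotype.
#' For each of the 16 ordered pairs the composite-diplotype mapping and the
#' phase-mixture prior are rebuilt, adaptive weights are recomputed and the
#' full BIC-tuned penalty path is fitted; the pair minimizing BIC wins. Ties
#' are broken deterministically by lexicographic haplotype order
#' (`[11] < [12] < [21] < [22]`, block s first).
#'
#' @param gs,gt n x 2 genotype matrices for blocks s and t.
#' @param y Binary phenotype.
#' @param covariates Optional covariate matrix.
#' @param freqs_s,freqs_t Haplotype frequencies (estimated from the data by
#'   default).
#' @param nlambda,lambda_min_ratio Penalty path settings, see
#'   [select_lambda()].
#' @param ... Passed to [em_fit()].
#' @return Object of class `hapepi_risksearch`: `candidates` data frame
#'   (risk pair, BIC, df, lambda), the winning `path`/`fit`, and the winner's
#'   risk haplotype indices.
#' @export
search_risk_haplotypes <- function(gs, gt, y, covariates = NULL,
                                   freqs_s = estimate_haplotype_frequencies(gs),
                                   freqs_t = estimate_haplotype_frequencies(gt),
                                   nlambda = 50L, lambda_min_ratio = 0.001,
                                   ...) {
  cand <- expand.grid(risk_t = 1:4, risk_s = 1:4)[, c("risk_s", "risk_t")]
  cand <- cand[order(cand$risk_s, cand$risk_t), ]   # lexicographic order
  bics <- rep(NA_real_, nrow(cand))
  dfs <- rep(NA_integer_, nrow(cand))
  lams <- rep(NA_real_, nrow(cand))
  paths <- vector("list", nrow(cand))
  errs <- character(0)
  for (k in seq_len(nrow(cand))) {
    res <- tryCatch({
      mf <- build_model_frame(gs, gt, y, covariates,
                              risk_s = cand$risk_s[k], risk_t = cand$risk_t[k],
                              freqs_s = freqs_s, freqs_t = freqs_t)
      w <- adaptive_weights(mf, ...)
      select_lambda(mf, w, nlambda = nlambda,
                    lambda_min_ratio = lambda_min_ratio, ...)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errs <- c(errs, conditionMessage(res))
    } else {
      paths[[k]] <- res
      bics[k] <- res$bic[res$best]
      dfs[k] <- res$df[res$best]
      lams[k] <- res$lambda[res$best]
    }
  }
  if (all(is.na(bics)))
    stop("all risk-haplotype candidates failed: ", paste(unique(errs), collapse = "; "))
  best <- which(!is.na(bics) & bics == min(bics, na.rm = TRUE))[1L]  # first = lexicographic tie-break
  structure(list(
    candidates = data.frame(
      risk_s = hap_label(cand$risk_s), risk_t = hap_label(cand$risk_t),
      bic = bics, df = dfs, lambda = lams),
    best = best,
    risk_s = cand$risk_s[best], risk_t = cand$risk_t[best],
    path = paths[[best]], fit = paths[[best]]$fit,
    n_failed = length(errs)
  ), class = "hapepi_risksearch")
}

#' @export
print.hapepi_risksearch <- function(x, ...) {
  cat(sprintf("risk-haplotype search: winner %s (block s) x %s (block t), BIC %.3f\n",
              hap_label(x$risk_s), hap_label(x$risk_t),
              x$candidates$bic[x$best]))
  print(x$candidates, row.names = FALSE)
  invisible(x)
}

#' Permutation p-values for the selected effects
#'
#' The phenotype vector is permuted (covariates stay attached to their
#' subjects), the full pipeline — adaptive weights, BIC-tuned penalty path —
#' is re-run with the risk-haplotype pair held fixed at the observed-data
#' winner, and effect `j` scores a hit whenever its permuted estimate is
#' nonzero. The empirical p-value is `hits / n_perm`. Optionally the risk
#' pair can be re-searched per permutation (`re_search = TRUE`, ~16x slower).
#'
#' @inheritParams search_risk_haplotypes
#' @param risk_s,risk_t The risk pair of the observed-data fit.
#' @param n_perm Number of permutations (the conventional default is 1000).
#' @param seed Optional RNG seed for reproducibility.
#' @param re_search Re-run the risk-haplotype search per permutation.
#' @return Object of class `hapepi_perm`: per-effect `pvalues`, hit counts,
#'   `n_perm` and the hit indicator matrix.
#' @export
permutation_pvalues <- function(gs, gt, y, covariates = NULL,
                                risk_s, risk_t,
                                freqs_s = estimate_haplotype_frequencies(gs),
                                freqs_t = estimate_haplotype_frequencies(gt),
                                n_perm = 1000L, seed = NULL,
                                nlambda = 50L, lambda_min_ratio = 0.001,
                                re_search = FALSE, ...) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  hits <- matrix(NA, n_perm, 8L, dimnames = list(NULL, effect_names()))
  failed <- 0L
  for (b in seq_len(n_perm)) {
    yp <- sample(y)
    res <- tryCatch({
      if (re_search) {
        sr <- search_risk_haplotypes(gs, gt, yp, covariates,
                                     freqs_s = freqs_s, freqs_t = freqs_t,
                                     nlambda = nlambda,
                                     lambda_min_ratio = lambda_min_ratio, ...)
        sr$fit$beta
      } else {
        mf <- build_model_frame(gs, gt, yp, covariates,
                                risk_s = risk_s, risk_t = risk_t,
                                freqs_s = freqs_s, freqs_t = freqs_t)
        w <- adaptive_weights(mf, ...)
        select_lambda(mf, w, nlambda = nlambda,
                      lambda_min_ratio = lambda_min_ratio, ...)$fit$beta
      }
    }, error = function(e) NULL)
    if (is.null(res)) failed <- failed + 1L else hits[b, ] <- res != 0
  }
  if (failed > 0L)
    warning(failed, " permutation(s) failed and count as non-hits")
  counts <- colSums(hits, na.rm = TRUE)
  structure(list(
    pvalues = counts / n_perm, hits = counts, n_perm = n_perm,
    n_failed = failed, hit_matrix = hits
  ), class = "hapepi_perm")
}

#' @export
print.hapepi_perm <- function(x, ...) {
  cat(sprintf("permutation test (%d permutations%s)\n", x$n_perm,
              if (x$n_failed) paste0(", ", x$n_failed, " failed") else ""))
  p <- x$pvalues
  lab <- ifelse(p == 0, paste0("< ", format(1 / x$n_perm)), format(p))
  print(data.frame(effect = names(p), hits = x$hits, p_value = lab),
        row.names = FALSE)
  invisible(x)
}

#' Bonferroni adjustment helper for multi-pair scans
#'
#' @param p Vector of per-pair permutation p-values.
#' @param n_pairs Number of block pairs tested (defaults to `length(p)`).
#' @return Adjusted p-values, capped at 1.
#' @export
bonferroni_adjust <- function(p, n_pairs = length(p)) pmin(1, p * n_pairs)
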