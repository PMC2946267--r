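# User-facing model interface: hapepi() fits the haplotype-epistasis model
# for one block pair and returns a classed object with the usual methods.

#' Fit the haplotype-haplotype epistasis model for a pair of blocks
#'
#' The workhorse of the package. For two 2-SNP haplotype blocks, unphased
#' genotypes are mapped to composite diplotypes relative to a risk haplotype
#' per block, the phase-ambiguous double heterozygote is treated as a
#' mixture inside an EM loop, and the eight Cockerham genetic effects
#' (additive, dominance and their four interactions) are estimated by
#' adaptively weighted L1-penalized logistic regression, with the penalty
#' tuned by BIC. By default every haplotype of each block is tried as the
#' risk haplotype and the pair minimizing BIC is reported; optionally the
#' selected effects are assessed by permutation p-values.
#'
#' @param genotypes n x 4 matrix or data frame of 0/1/2 genotype codes
#'   (count of allele "2"): the two SNPs of block s, then the two SNPs of
#'   block t, unless `blocks` names the columns explicitly. Subjects with
#'   any missing genotype are dropped with a message.
#' @param phenotype Binary vector, 1 = case, 0 = control.
#' @param blocks Optional list of two character vectors naming the two
#'   genotype columns of each block, e.g.
#'   `list(s = c("rs1", "rs2"), t = c("rs3", "rs4"))`.
#' @param covariates Optional numeric matrix/data frame of covariates
#'   (adjusted for, never penalized).
#' @param risk `"search"` (default) tries all 16 risk-haplotype pairs;
#'   `"fixed"` uses `risk_pair`.
#' @param risk_pair Length-2 character, e.g. `c("[11]", "[11]")`; used when
#'   `risk = "fixed"`.
#' @param freq_from Estimate block haplotype frequencies from the pooled
#'   sample (default) or from controls only.
#' @param nlambda,lambda_min_ratio Penalty path settings ([select_lambda()]).
#' @param n_perm Number of phenotype permutations for empirical p-values
#'   (0 skips the permutation test).
#' @param seed Optional seed for the permutation test.
#' @param ... Passed to [em_fit()] (e.g. `tol`, `max_iter`).
#' @return Object of class `hapepi` with components `coefficients` (all
#'   effects), `beta` (the 8 genetic effects), `gamma` (intercept and
#'   covariates), `risk_s`/`risk_t`, `bic`, `lambda`, `candidates` (the risk
#'   search table when applicable), `pvalues` (when `n_perm > 0`), the block
#'   haplotype frequencies and phase-mixture priors, and the underlying
#'   penalty-path and EM fits.
#' @seealso [summary.hapepi()], [risk_group_odds()], [simulate_epistasis_data()]
#' @examples
#' dat <- simulate_epistasis_data(300, scenario = "S2", seed = 7)
#' fit <- hapepi(dat$genotypes, dat$phenotype, risk = "fixed",
#'               risk_pair = c("[11]", "[11]"), nlambda = 15)
#' fit
#' @export
hapepi <- function(genotypes, phenotype, blocks = NULL, covariates = NULL,
                   risk = c("search", "fixed"), risk_pair = c("[11]", "[11]"),
                   freq_from = c("pooled", "controls"),
                   nlambda = 50L, lambda_min_ratio = 0.001,
                   n_perm = 0L, seed = NULL, ...) {
  risk <- match.arg(risk)
  freq_from <- match.arg(freq_from)
  cl <- match.call()
  g <- as.matrix(genotypes)
  if (!is.null(blocks)) {
    if (length(blocks) != 2L || any(lengths(blocks) != 2L))
      stop("blocks must be a list of two pairs of column names")
    cols <- c(blocks[[1L]], blocks[[2L]])
    if (!all(cols %in% colnames(g)))
      stop("block SNPs not found in genotypes: ",
           paste(setdiff(cols, colnames(g)), collapse = ", "))
    g <- g[, cols, drop = FALSE]
  }
  if (ncol(g) != 4L)
    stop("expected 4 genotype columns (2 SNPs per block); use `blocks` to select them")
  y <- as.integer(phenotype)
  if (!is.null(covariates)) covariates <- as.matrix(covariates)
  keep <- stats::complete.cases(g) & !is.na(y)
  if (!is.null(covariates)) keep <- keep & stats::complete.cases(covariates)
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    message("dropped ", n_dropped, " subject(s) with missing data")
    g <- g[keep, , drop = FALSE]
    y <- y[keep]
    if (!is.null(covariates)) covariates <- covariates[keep, , drop = FALSE]
  }
  gs <- g[, 1:2, drop = FALSE]; gt <- g[, 3:4, drop = FALSE]
  fsub <- if (freq_from == "controls") y == 0L else rep(TRUE, length(y))
  freqs_s <- estimate_haplotype_frequencies(gs[fsub, , drop = FALSE])
  freqs_t <- estimate_haplotype_frequencies(gt[fsub, , drop = FALSE])

  if (risk == "search") {
    sr <- search_risk_haplotypes(gs, gt, y, covariates,
                                 freqs_s = freqs_s, freqs_t = freqs_t,
                                 nlambda = nlambda,
                                 lambda_min_ratio = lambda_min_ratio, ...)
    path <- sr$path
    risk_s <- sr$risk_s; risk_t <- sr$risk_t
    candidates <- sr$candidates
  } else {
    risk_s <- normalize_hap(risk_pair[1L]); risk_t <- normalize_hap(risk_pair[2L])
    mf <- build_model_frame(gs, gt, y, covariates,
                            risk_s = risk_s, risk_t = risk_t,
                            freqs_s = freqs_s, freqs_t = freqs_t)
    w <- adaptive_weights(mf, ...)
    path <- select_lambda(mf, w, nlambda = nlambda,
                          lambda_min_ratio = lambda_min_ratio, ...)
    candidates <- NULL
  }
  fit <- path$fit
  perm <- NULL
  if (n_perm > 0L) {
    perm <- permutation_pvalues(gs, gt, y, covariates,
                                risk_s = risk_s, risk_t = risk_t,
                                freqs_s = freqs_s, freqs_t = freqs_t,
                                n_perm = n_perm, seed = seed,
                                nlambda = nlambda,
                                lambda_min_ratio = lambda_min_ratio, ...)
  }
  structure(list(
    coefficients = fit$theta, beta = fit$beta, gamma = fit$gamma,
    risk_s = hap_label(risk_s), risk_t = hap_label(risk_t),
    bic = fit$bic, lambda = fit$lambda, df = fit$df,
    candidates = candidates, pvalues = perm,
    freqs_s = freqs_s, freqs_t = freqs_t,
    phi_s = phase_mixture_prior(freqs_s), phi_t = phase_mixture_prior(freqs_t),
    path = path, fit = fit,
    n = length(y), n_dropped = n_dropped, risk_mode = risk,
    call = cl
  ), class = "hapepi")
}

#' @export
print.hapepi <- function(x, ...) {
  cat("haplotype-haplotype epistasis model\n")
  cat("call: "); print(x$call)
  cat(sprintf("n = %d subjects%s; risk haplotypes %s (block s) x %s (block t)%s\n",
              x$n,
              if (x$n_dropped) paste0(" (", x$n_dropped, " dropped)") else "",
              x$risk_s, x$risk_t,
              if (x$risk_mode == "search") " [BIC search]" else " [fixed]"))
  cat(sprintf("lambda = %.4g, BIC = %.3f\n", x$lambda, x$bic))
  nz <- x$beta[x$beta != 0]
  if (length(nz)) {
    cat("selected genetic effects:\n")
    print(round(nz, 4))
  } else {
    cat("no genetic effect selected (null model)\n")
  }
  invisible(x)
}

#' Summary of a fitted haplotype-epistasis model
#'
#' Tabulates the eight genetic effects (estimate, selected flag and, when a
#' permutation test was run, the empirical p-value), the unpenalized
#' nuisance coefficients, and the risk-group odds ratios implied by any
#' selected interaction effect.
#'
#' @param object A `hapepi` fit.
#' @param ... Unused.
#' @export
summary.hapepi <- function(object, ...) {
  tab <- data.frame(
    effect = effect_names(),
    estimate = unname(object$beta),
    selected = unname(object$beta != 0)
  )
  if (!is.null(object$pvalues)) tab$perm_p <- unname(object$pvalues$pvalues)
  or_tabs <- list()
  for (eff in c("i_aa", "i_ad", "i_da", "i_dd")) {
    if (object$beta[[eff]] != 0)
      or_tabs[[eff]] <- risk_group_odds(object$beta[[eff]], effect = eff)
  }
  structure(list(effects = tab, gamma = object$gamma,
                 risk_s = object$risk_s, risk_t = object$risk_t,
                 bic = object$bic, lambda = object$lambda, n = object$n,
                 phi_s = object$phi_s, phi_t = object$phi_t,
                 odds_ratios = or_tabs, call = object$call),
            class = "summary.hapepi")
}

#' @export
print.summary.hapepi <- function(x, ...) {
  cat("haplotype-haplotype epistasis model\n")
  cat(sprintf("risk haplotypes: %s x %s; n = %d; lambda = %.4g; BIC = %.3f\n",
              x$risk_s, x$risk_t, x$n, x$lambda, x$bic))
  cat(sprintf("phase-mixture priors: phi_s = %.4f, phi_t = %.4f\n",
              x$phi_s, x$phi_t))
  cat("\ngenetic effects:\n")
  print(x$effects, row.names = FALSE, digits = 4)
  cat("\nunpenalized coefficients:\n")
  print(round(x$gamma, 4))
  for (eff in names(x$odds_ratios)) {
    cat(sprintf("\nrisk-group odds ratios implied by %s:\n", eff))
    print(x$odds_ratios[[eff]], row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' @export
coef.hapepi <- function(object, ...) object$coefficients

#' Predicted disease probabilities
#'
#' For new unphased genotypes the linear predictor is averaged over the
#' phase mixture with its prior weights (no phenotype is available for a
#' posterior), giving `P(y = 1)` per subject.
#'
#' @param object A `hapepi` fit.
#' @param genotypes n x 4 genotype matrix as in [hapepi()]; defaults to the
#'   training data.
#' @param covariates Covariate matrix matching the fit.
#' @param type `"response"` for probabilities, `"link"` for the logit.
#' @param ... Unused.
#' @export
predict.hapepi <- function(object, genotypes = NULL, covariates = NULL,
                           type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(genotypes)) {
    mf <- object$fit$frame
  } else {
    g <- as.matrix(genotypes)
    mf <- build_model_frame(g[, 1:2, drop = FALSE], g[, 3:4, drop = FALSE],
                            y = rep(0L, nrow(g)), covariates = covariates,
                            risk_s = object$risk_s, risk_t = object$risk_t,
                            freqs_s = object$freqs_s, freqs_t = object$freqs_t)
  }
  p_row <- row_probs(mf, object$coefficients)
  pr <- rowsum(mf$prior * p_row, mf$subject)[, 1L] /
        rowsum(mf$prior, mf$subject)[, 1L]
  if (type == "response") pr else stats::qlogis(pr)
}

#' @export
fitted.hapepi <- function(object, ...) predict(object)

#' @export
residuals.hapepi <- function(object, type = c("response", "deviance"), ...) {
  type <- match.arg(type)
  y <- object$fit$frame$y
  p <- fitted(object)
  if (type == "response") return(y - p)
  sign(y - p) * sqrt(-2 * (y * log(p) + (1 - y) * log1p(-p)))
}

#' @export
simulate.hapepi <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- fitted(object)
  out <- as.data.frame(replicate(nsim, stats::rbinom(length(p), 1L, p)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.hapepi <- function(x, ...) {
  graphics::barplot(x$beta, ylab = "estimate", las = 2,
                    main = sprintf("genetic effects (risk %s x %s)",
                                   x$risk_s, x$risk_t))
  graphics::abline(h = 0)
  invisible(x)
}

#' Risk-group odds ratios implied by an interaction effect
#'
#' A selected interaction coefficient partitions the nine composite-
#' diplotype cells into groups sharing the same interaction code; the log
#' odds of disease differ between groups by `code * coefficient`, so the
#' odds ratio of each group against the zero-code reference group is
#' `exp(code * coefficient)`. For the additive-by-dominance codes the groups
#' are the reference `R1` (code 0), `R2` (code -1/2, odds ratio
#' `exp(-i_ad/2)`) and `R3` (code +1/2, odds ratio `exp(i_ad/2)`).
#'
#' @param coefficient The interaction estimate, or a `hapepi` fit (in which
#'   case the named effect is extracted).
#' @param effect Which interaction: `"i_aa"`, `"i_ad"`, `"i_da"` or `"i_dd"`.
#' @return Data frame with one row per risk group: group label, interaction
#'   code, log-odds offset and odds ratio against the reference.
#' @examples
#' risk_group_odds(-0.45, "i_ad")   # odds ratios 1.25 and 0.80
#' @export
risk_group_odds <- function(coefficient, effect = "i_ad") {
  if (inherits(coefficient, "hapepi")) coefficient <- coefficient$beta[[effect]]
  if (!effect %in% c("i_aa", "i_ad", "i_da", "i_dd"))
    stop("effect must be one of the four interaction terms")
  cells <- expand.grid(ks = 2:0, kt = 2:0)
  codes <- sort(unique(design_matrix(cells$ks, cells$kt)[, effect]))
  # reference group = code 0 when present, else the smallest |code|
  ref <- if (any(codes == 0)) 0 else codes[which.min(abs(codes))]
  codes <- c(ref, setdiff(codes, ref))
  data.frame(
    group = paste0("R", seq_along(codes)),
    code = codes,
    log_odds_offset = codes * coefficient,
    odds_ratio = exp(codes * coefficient)
  )
}
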