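# Two-SNP haplotype block machinery: genotype -> composite diplotype mapping,
# two-locus haplotype frequency estimation, phase-ambiguity mixture prior.

#' The four haplotypes of a biallelic two-SNP block
#'
#' Haplotypes are written as the ordered alleles at the two SNPs, with alleles
#' coded 1 (major by convention) and 2 (minor). Internally they are indexed
#' 1-4 in the order `[11]`, `[12]`, `[21]`, `[22]`.
#'
#' @return Character vector `c("11", "12", "21", "22")`.
#' @export
haplotypes <- function() c("11", "12", "21", "22")

# Accept haplotype as index 1:4, "11", or "[11]"; return integer index.
normalize_hap <- function(h) {
  if (is.numeric(h)) {
    h <- as.integer(h)
    if (any(is.na(h)) || any(h < 1L) || any(h > 4L))
      stop("haplotype index must be in 1:4")
    return(h)
  }
  key <- gsub("\\[|\\]", "", as.character(h))
  i <- match(key, haplotypes())
  if (any(is.na(i)))
    stop("unknown haplotype: ", paste(h[is.na(i)], collapse = ", "))
  i
}

hap_label <- function(i) paste0("[", haplotypes()[i], "]")

# Alleles (1/2) of haplotype index h at SNP 1 and SNP 2.
hap_allele1 <- function(h) ifelse(h > 2L, 2L, 1L)
hap_allele2 <- function(h) ifelse(h %% 2L == 0L, 2L, 1L)

# Coerce an n x 2 genotype object, cells in {0,1,2} = count of allele "2".
as_geno_matrix <- function(genotypes) {
  g <- as.matrix(genotypes)
  if (ncol(g) != 2L) stop("a block genotype matrix must have exactly 2 columns")
  storage.mode(g) <- "integer"
  if (any(is.na(g))) stop("missing genotypes must be removed before analysis")
  if (any(g < 0L | g > 2L)) stop("genotype codes must be 0, 1 or 2")
  g
}

# Diplotype configuration(s) compatible with a genotype (g1, g2).
# Non-ambiguous genotypes have one configuration; the double heterozygote
# (1,1) has two: {[11],[22]} and {[12],[21]}.
diplotype_configs <- function(g1, g2) {
  al <- function(g) switch(g + 1L, c(1L, 1L), c(1L, 2L), c(2L, 2L))
  a1 <- al(g1); a2 <- al(g2)
  hap_idx <- function(x, y) 2L * (x - 1L) + y
  cfg1 <- c(hap_idx(a1[1L], a2[1L]), hap_idx(a1[2L], a2[2L]))
  if (g1 == 1L && g2 == 1L) {
    list(cfg1, c(hap_idx(1L, 2L), hap_idx(2L, 1L)))
  } else {
    list(cfg1)
  }
}

#' Validate a set of two-locus haplotype frequencies
#' @noRd
check_freqs <- function(freqs) {
  p <- as.numeric(freqs)
  if (length(p) != 4L || any(!is.finite(p)) || any(p < -1e-12))
    stop("haplotype frequencies must be 4 non-negative numbers")
  if (abs(sum(p) - 1) > 1e-8) stop("haplotype frequencies must sum to 1")
  pmax(p, 0)
}

#' Phase-ambiguity mixture prior for the double heterozygote
#'
#' The genotype 12/12 is compatible with two diplotype configurations,
#' `[11][22]` and `[12][21]`. Under Hardy-Weinberg equilibrium the
#' conditional probability of the `[11][22]` configuration given the
#' genotype is `phi = p11*p22 / (p11*p22 + p12*p21)`.
#'
#' @param freqs Numeric length-4 haplotype frequencies in the order
#'   `[11], [12], [21], [22]` (e.g. from [estimate_haplotype_frequencies()]).
#' @return The probability `phi` of configuration `[11][22]`.
#' @export
phase_mixture_prior <- function(freqs) {
  p <- check_freqs(freqs)
  s <- p[1L] * p[4L] + p[2L] * p[3L]
  if (s <= 0)
    stop("degenerate frequencies: both double-heterozygote configurations have probability 0")
  p[1L] * p[4L] / s
}

#' Map an unphased two-SNP genotype to a composite diplotype
#'
#' A composite diplotype is the count of copies of the designated risk
#' haplotype `H` carried by a subject: `HH` (2 copies), `HHbar` (1) or
#' `HbarHbar` (0). All genotypes map uniquely except the double heterozygote
#' 12/12, which is a two-component mixture: the configuration containing the
#' risk haplotype carries one copy, the other carries none, with mixture
#' weights given by the conditional configuration probabilities.
#'
#' @param g Integer length-2 genotype `(g1, g2)`, each the 0/1/2 count of
#'   allele "2" at the SNP.
#' @param risk Risk haplotype: index 1-4 or a label such as `"[11]"`.
#' @param freqs Haplotype frequencies (required only for the 12/12 genotype).
#' @return An object of class `composite_diplotype`: a list with `copies`
#'   (candidate risk-copy counts), `weights` (their probabilities), `status`
#'   (labels) and `ambiguous`.
#' @examples
#' map_to_composite(c(0, 0), "[11]")                      # HH
#' map_to_composite(c(1, 1), "[11]", rep(0.25, 4))        # 50/50 mixture
#' @export
map_to_composite <- function(g, risk, freqs = NULL) {
  g <- as.integer(g)
  if (length(g) != 2L || any(is.na(g)) || any(g < 0L) || any(g > 2L))
    stop("genotype must be two codes in {0,1,2}")
  r <- normalize_hap(risk)
  cfgs <- diplotype_configs(g[1L], g[2L])
  copies <- vapply(cfgs, function(cf) sum(cf == r), integer(1L))
  if (length(cfgs) == 1L) {
    out <- list(copies = copies, weights = 1, ambiguous = FALSE)
  } else {
    if (is.null(freqs))
      stop("the 12/12 genotype needs haplotype frequencies for its mixture weights")
    phi <- phase_mixture_prior(freqs)
    w <- c(phi, 1 - phi)            # weight of [11][22], then [12][21]
    ord <- order(-copies)           # H-bearing configuration first
    out <- list(copies = copies[ord], weights = w[ord], ambiguous = TRUE)
  }
  out$risk <- hap_label(r)
  out$status <- c("HbarHbar", "HHbar", "HH")[out$copies + 1L]
  class(out) <- "composite_diplotype"
  out
}

#' @export
print.composite_diplotype <- function(x, ...) {
  if (!x$ambiguous) {
    cat(sprintf("composite diplotype: %s (risk %s)\n", x$status, x$risk))
  } else {
    cat(sprintf("composite diplotype mixture (risk %s):\n", x$risk))
    for (k in seq_along(x$copies))
      cat(sprintf("  %-9s weight %.6g\n", x$status[k], x$weights[k]))
  }
  invisible(x)
}

# Vectorized mapping of a whole block. Returns per-subject risk-copy counts
# (NA for ambiguous subjects), the ambiguity flag, and the prior probability
# that an ambiguous subject carries one risk copy (P(c = 1)).
block_map <- function(g, risk, freqs) {
  g <- as_geno_matrix(g)
  r <- normalize_hap(risk)
  amb <- g[, 1L] == 1L & g[, 2L] == 1L
  # copies per unambiguous genotype cell, indexed by g1*3 + g2 + 1
  cell_copies <- integer(9L)
  for (g1 in 0:2) for (g2 in 0:2) {
    if (g1 == 1L && g2 == 1L) next
    cf <- diplotype_configs(g1, g2)[[1L]]
    cell_copies[g1 * 3L + g2 + 1L] <- sum(cf == r)
  }
  copies <- cell_copies[g[, 1L] * 3L + g[, 2L] + 1L]
  copies[amb] <- NA_integer_
  phi <- phase_mixture_prior(freqs)
  # configuration [11][22] carries the risk copy iff risk is [11] or [22]
  p_c1 <- if (r %in% c(1L, 4L)) phi else 1 - phi
  list(copies = copies, ambiguous = amb, p_c1 = p_c1, risk = r)
}

#' Classify subjects by phase ambiguity of the two blocks
#'
#' Group `M1`: neither block is the double heterozygote 12/12; `M2`: only
#' block s is; `M3`: only block t; `M4`: both. Groups M2-M4 require mixture
#' modelling in the likelihood.
#'
#' @param gs,gt n x 2 genotype matrices for blocks s and t (codes 0/1/2).
#' @return Factor with levels `M1`-`M4`, one element per subject.
#' @export
classify_phase_groups <- function(gs, gt) {
  gs <- as_geno_matrix(gs); gt <- as_geno_matrix(gt)
  if (nrow(gs) != nrow(gt)) stop("blocks must cover the same subjects")
  as_ <- gs[, 1L] == 1L & gs[, 2L] == 1L
  at_ <- gt[, 1L] == 1L & gt[, 2L] == 1L
  factor(ifelse(!as_ & !at_, "M1",
         ifelse(as_ & !at_, "M2",
         ifelse(!as_ & at_, "M3", "M4"))), levels = c("M1", "M2", "M3", "M4"))
}

#' Combinatorial structure of haplotype blocks with k SNPs
#'
#' For a block of `n_snps` biallelic SNPs there are `3^n` unphased genotypes;
#' a genotype is phase-ambiguous iff it is heterozygous at two or more loci.
#' A genotype heterozygous at k loci is compatible with `2^(k-1)` diplotype
#' configurations, so the largest mixture in a single-block likelihood has
#' `2^(n-1)` components and crossing two such blocks gives up to
#' `4^(n-1)` mixture cells. Regardless of `n_snps` there are always exactly
#' 3 composite diplotypes per block and 9 per block pair.
#'
#' @param n_snps Number of SNPs per block (>= 1).
#' @return Named list of counts.
#' @examples
#' count_block_states(2)   # 9 genotypes, 1 ambiguous, 81 pairs, 64 unambiguous
#' count_block_states(3)   # 7 ambiguous genotypes, 16 mixture cells crossed
#' @export
count_block_states <- function(n_snps) {
  if (!is.numeric(n_snps) || length(n_snps) != 1L || is.na(n_snps) || n_snps < 1)
    stop("n_snps must be a single integer >= 1")
  n <- as.integer(n_snps)
  ng <- as.integer(3^n)
  n_amb <- as.integer(ng - 2^n - n * 2^(n - 1))  # <= 1 het locus is phase-known
  list(
    n_snps                    = n,
    genotypes_per_block       = ng,
    ambiguous_per_block       = n_amb,
    unambiguous_per_block     = ng - n_amb,
    genotype_pairs            = as.integer(ng^2),
    unambiguous_pairs         = as.integer((ng - n_amb)^2),
    composite_diplotypes      = 3L,
    composite_pairs           = 9L,
    max_mixture_per_block     = as.integer(2^(n - 1)),
    mixture_cells_two_blocks  = as.integer(4^(n - 1))
  )
}

# Genotype cell probabilities (9 cells, order g1*3+g2+1) under HWE.
two_locus_genotype_probs <- function(freqs) {
  p <- check_freqs(freqs)
  pr <- numeric(9L)
  for (g1 in 0:2) for (g2 in 0:2) {
    cfgs <- diplotype_configs(g1, g2)
    val <- 0
    for (cf in cfgs) {
      mult <- if (cf[1L] == cf[2L]) 1 else 2
      val <- val + mult * p[cf[1L]] * p[cf[2L]]
    }
    pr[g1 * 3L + g2 + 1L] <- val
  }
  pr
}

hap_freq_loglik <- function(counts, freqs) {
  pr <- two_locus_genotype_probs(freqs)
  keep <- counts > 0
  sum(counts[keep] * log(pmax(pr[keep], 1e-300)))
}

#' Estimate two-locus haplotype frequencies by EM
#'
#' Maximum-likelihood frequencies of the four haplotypes `[11],[12],[21],[22]`
#' from unphased genotypes under Hardy-Weinberg equilibrium. All genotypes
#' except the double heterozygote contribute known haplotype counts; the EM
#' splits 12/12 subjects between the `[11][22]` and `[12][21]` configurations
#' according to the current frequency estimates.
#'
#' When the sample consists solely of double heterozygotes the likelihood
#' depends on the frequencies only through `p11*p22 + p12*p21`; the symmetric
#' solution `(1/4, 1/4, 1/4, 1/4)` is returned with
#' `attr(, "identifiable") = FALSE` and a warning.
#'
#' @param genotypes n x 2 matrix of 0/1/2 codes for one block.
#' @param tol Convergence tolerance on the maximum absolute frequency change.
#' @param max_iter Iteration cap.
#' @return Object of class `hap_freqs`: named numeric of length 4 with
#'   attributes `iterations`, `converged`, `loglik` (per-iteration trace) and
#'   `identifiable`.
#' @export
estimate_haplotype_frequencies <- function(genotypes, tol = 1e-8, max_iter = 5000L) {
  g <- as_geno_matrix(genotypes)
  n <- nrow(g)
  if (n < 1L) stop("at least one subject is required")
  counts <- tabulate(g[, 1L] * 3L + g[, 2L] + 1L, nbins = 9L)
  # haplotype counts contributed by the 8 unambiguous cells
  base <- numeric(4L)
  for (g1 in 0:2) for (g2 in 0:2) {
    if (g1 == 1L && g2 == 1L) next
    cf <- diplotype_configs(g1, g2)[[1L]]
    k <- counts[g1 * 3L + g2 + 1L]
    base[cf[1L]] <- base[cf[1L]] + k
    base[cf[2L]] <- base[cf[2L]] + k
  }
  n_dh <- counts[5L]
  if (n_dh == n) {
    warning("all subjects are double heterozygotes; haplotype frequencies are not identifiable")
    out <- structure(rep(0.25, 4), names = paste0("p", haplotypes()),
                     class = "hap_freqs", iterations = 0L, converged = TRUE,
                     loglik = hap_freq_loglik(counts, rep(0.25, 4)),
                     identifiable = FALSE)
    return(out)
  }
  p <- (base + 0.5) / sum(base + 0.5)
  ll <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    s <- p[1L] * p[4L] + p[2L] * p[3L]
    phi <- if (s > 0) p[1L] * p[4L] / s else 0.5
    e <- base + n_dh * c(phi, 1 - phi, 1 - phi, phi)
    p_new <- e / (2 * n)
    ll[it] <- hap_freq_loglik(counts, p_new)
    if (max(abs(p_new - p)) < tol) {
      p <- p_new
      converged <- TRUE
      break
    }
    p <- p_new
  }
  structure(as.numeric(p), names = paste0("p", haplotypes()),
            class = "hap_freqs", iterations = it, converged = converged,
            loglik = ll, identifiable = TRUE)
}

#' @export
print.hap_freqs <- function(x, ...) {
  cat("two-locus haplotype frequencies (EM,", attr(x, "iterations"), "iterations)\n")
  print(round(unclass(x)[1:4], 6))
  if (!attr(x, "identifiable"))
    cat("note: frequencies not identifiable from this sample\n")
  invisible(x)
}
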