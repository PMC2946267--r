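# File input/output: genotype CSV, PLINK ped/map, QC filters, results table
# and the reproducibility manifest.

#' Read a genotype CSV
#'
#' One row per subject, one column per SNP, cells in `{0, 1, 2}` (count of
#' allele "2") or `NA`.
#'
#' @param path CSV file path.
#' @return Integer matrix with SNP column names.
#' @export
read_genotype_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "integer"
  bad <- !is.na(m) & !(m %in% 0:2)
  if (any(bad)) stop("genotype codes outside {0,1,2} in ", path)
  m
}

#' Read PLINK ped/map files
#'
#' Minimal text-format reader: the `.map` file supplies SNP identifiers, the
#' `.ped` file the six standard leading columns plus two allele columns per
#' SNP. Allele pairs are recoded to 0/1/2 as the count of the minor allele
#' (the less frequent allele in the file; ties broken alphabetically).
#' `0` or `-9` alleles are treated as missing.
#'
#' @param ped,map File paths.
#' @return List with `genotypes` (0/1/2 matrix), `phenotype` (0/1 when the
#'   ped phenotype column is coded 1/2, otherwise NA), `alleles` (per-SNP
#'   major/minor letters) and the `map` data frame.
#' @export
read_ped_map <- function(ped, map) {
  mp <- utils::read.table(map, header = FALSE, stringsAsFactors = FALSE)
  snps <- as.character(mp[[2L]])
  pd <- utils::read.table(ped, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(pd) != 6L + 2L * length(snps))
    stop("ped file has ", ncol(pd), " columns; expected ",
         6L + 2L * length(snps), " for ", length(snps), " SNPs")
  n <- nrow(pd)
  geno <- matrix(NA_integer_, n, length(snps), dimnames = list(NULL, snps))
  alleles <- matrix(NA_character_, length(snps), 2L,
                    dimnames = list(snps, c("major", "minor")))
  for (j in seq_along(snps)) {
    a1 <- pd[[6L + 2L * j - 1L]]
    a2 <- pd[[6L + 2L * j]]
    a1[a1 %in% c("0", "-9")] <- NA
    a2[a2 %in% c("0", "-9")] <- NA
    tab <- table(c(a1, a2))
    if (length(tab) > 2L) stop("SNP ", snps[j], " has more than two alleles")
    ord <- order(-tab, names(tab))   # ties broken alphabetically
    major <- names(tab)[ord[1L]]
    minor <- if (length(tab) == 2L) names(tab)[ord[2L]] else NA_character_
    alleles[j, ] <- c(major, minor)
    cnt <- (!is.na(a1) & a1 == minor) + (!is.na(a2) & a2 == minor)
    cnt[is.na(a1) | is.na(a2)] <- NA_integer_
    geno[, j] <- as.integer(cnt)
  }
  ph <- suppressWarnings(as.integer(pd[[6L]]))
  phenotype <- ifelse(ph %in% c(1L, 2L), ph - 1L, NA_integer_)
  list(genotypes = geno, phenotype = phenotype, alleles = alleles, map = mp)
}

# 1-df chi-square goodness-of-fit test for Hardy-Weinberg equilibrium
# from 0/1/2 genotype counts.
hwe_chisq_test <- function(g) {
  g <- g[!is.na(g)]
  n <- length(g)
  if (n == 0L) return(NA_real_)
  obs <- tabulate(g + 1L, 3L)
  q <- (obs[2L] + 2 * obs[3L]) / (2 * n)   # minor allele frequency
  exp_ <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
  if (any(exp_ == 0)) return(1)
  stat <- sum((obs - exp_)^2 / exp_)
  stats::pchisq(stat, df = 1L, lower.tail = FALSE)
}

#' Quality-control filter for SNPs
#'
#' Flags SNPs with minor allele frequency below `maf_min` or with a
#' Hardy-Weinberg chi-square p-value below `hwe_p` computed in the control
#' subjects.
#'
#' @param genotypes 0/1/2 genotype matrix.
#' @param phenotype Binary phenotype (controls = 0) used for the HWE test;
#'   if missing, HWE is tested in all subjects.
#' @param maf_min Minimum minor allele frequency (default 0.05).
#' @param hwe_p Minimum HWE p-value (default 0.001).
#' @return Data frame per SNP: `snp`, `maf`, `hwe_p`, `keep`.
#' @export
qc_filter <- function(genotypes, phenotype = NULL, maf_min = 0.05,
                      hwe_p = 0.001) {
  g <- as.matrix(genotypes)
  snps <- colnames(g)
  if (is.null(snps)) snps <- paste0("snp", seq_len(ncol(g)))
  ctrl <- if (is.null(phenotype)) rep(TRUE, nrow(g)) else phenotype == 0L
  maf <- apply(g, 2L, function(x) {
    x <- x[!is.na(x)]
    q <- sum(x) / (2 * length(x))
    min(q, 1 - q)
  })
  hw <- apply(g[ctrl, , drop = FALSE], 2L, hwe_chisq_test)
  data.frame(snp = snps, maf = maf, hwe_p = hw,
             keep = maf >= maf_min & (is.na(hw) | hw >= hwe_p),
             row.names = NULL)
}

#' Results table for one or more fitted block pairs
#'
#' One row per block pair: block and risk-haplotype labels, the eight effect
#' estimates, BIC, lambda and (when available) permutation p-values.
#'
#' @param fits A `hapepi` fit or list of them.
#' @param pair_names Optional character labels for the pairs.
#' @return Data frame.
#' @export
results_table <- function(fits, pair_names = NULL) {
  if (inherits(fits, "hapepi")) fits <- list(fits)
  rows <- lapply(seq_along(fits), function(k) {
    f <- fits[[k]]
    row <- data.frame(
      pair = if (is.null(pair_names)) paste0("pair", k) else pair_names[k],
      risk_s = f$risk_s, risk_t = f$risk_t,
      t(f$beta), bic = f$bic, lambda = f$lambda,
      check.names = FALSE
    )
    if (!is.null(f$pvalues)) {
      pv <- f$pvalues$pvalues
      names(pv) <- paste0("p_", names(pv))
      row <- cbind(row, t(pv))
    }
    row
  })
  do.call(rbind, rows)
}

#' Write a run manifest for exact reproducibility
#'
#' Records the package version, the seed, the configuration and the MD5
#' hashes of all input files as sorted JSON. Identical inputs and
#' configuration produce a byte-identical manifest.
#'
#' @param path Output JSON path.
#' @param config Named list of run settings.
#' @param inputs Character vector of input file paths to hash.
#' @param seed The run seed (may be NULL).
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, config, inputs = character(0), seed = NULL) {
  hashes <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  names(hashes) <- basename(inputs)
  manifest <- list(
    package = "hapepi",
    version = as.character(utils::packageVersion("hapepi")),
    seed = seed,
    config = config,
    input_md5 = hashes
  )
  json <- jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA, null = "null")
  writeLines(json, path)
  invisible(manifest)
}
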