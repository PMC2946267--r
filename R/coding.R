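# Cockerham orthogonal coding of composite diplotypes.
#
# Per block, the composite diplotype (risk-copy count 2/1/0) is coded by an
# additive score x in {1, 0, -1} and a dominance score z in {-1/2, 1/2, -1/2}.
# The eight genetic effects for a block pair are
#   beta = (a_s, a_t, d_s, d_t, i_aa, i_ad, i_da, i_dd)
# with design row (x_s, x_t, z_s, z_t, x_s x_t, x_s z_t, z_s x_t, z_s z_t).

#' Names of the eight genetic effects, in canonical order
#' @export
effect_names <- function() c("a_s", "a_t", "d_s", "d_t", "i_aa", "i_ad", "i_da", "i_dd")

# Accept composite status as copies 0/1/2 or labels HH/HHbar/HbarHbar.
normalize_copies <- function(status) {
  if (is.numeric(status)) {
    k <- as.integer(status)
    if (any(is.na(k)) || any(k < 0L) || any(k > 2L))
      stop("risk-copy counts must be 0, 1 or 2 (ambiguous subjects must be expanded by the caller)")
    return(k)
  }
  k <- match(as.character(status), c("HbarHbar", "HHbar", "HH")) - 1L
  if (any(is.na(k))) stop("unknown composite diplotype status")
  k
}

#' Additive/dominance codes of a composite diplotype
#'
#' `HH` (2 risk copies) codes as `(x, z) = (1, -1/2)`, `HHbar` (1 copy) as
#' `(0, 1/2)` and `HbarHbar` (0 copies) as `(-1, -1/2)`.
#'
#' @param status Composite diplotype: risk-copy count 0/1/2 or label
#'   `"HH"`, `"HHbar"`, `"HbarHbar"`. Must be unambiguous; mixtures are
#'   expanded into their component statuses by the likelihood machinery.
#' @return For a single status, a named numeric `c(x =, z =)`; for a vector,
#'   a 2-column matrix.
#' @export
code_block <- function(status) {
  k <- normalize_copies(status)
  x <- as.numeric(k - 1L)
  z <- ifelse(k == 1L, 0.5, -0.5)
  if (length(k) == 1L) c(x = x, z = z) else cbind(x = x, z = z)
}

#' Design row(s) for the eight genetic effects
#'
#' Builds the Cockerham design for a pair of composite diplotypes, ordered to
#' match [effect_names()]: main effects `x_s, x_t, z_s, z_t`, then the
#' interactions `x_s*x_t, x_s*z_t, z_s*x_t, z_s*z_t`.
#'
#' @param status_s,status_t Composite diplotypes for blocks s and t (copy
#'   counts 0/1/2 or labels), recycled to common length.
#' @return Numeric matrix with one row per subject and 8 named columns
#'   (a single row is returned as a named vector by [design_row()]).
#' @export
design_matrix <- function(status_s, status_t) {
  ks <- normalize_copies(status_s)
  kt <- normalize_copies(status_t)
  n <- max(length(ks), length(kt))
  ks <- rep_len(ks, n); kt <- rep_len(kt, n)
  xs <- as.numeric(ks - 1L); zs <- ifelse(ks == 1L, 0.5, -0.5)
  xt <- as.numeric(kt - 1L); zt <- ifelse(kt == 1L, 0.5, -0.5)
  m <- cbind(xs, xt, zs, zt, xs * xt, xs * zt, zs * xt, zs * zt)
  colnames(m) <- effect_names()
  m
}

#' @rdname design_matrix
#' @export
design_row <- function(status_s, status_t) {
  drop(design_matrix(status_s, status_t)[1L, ])
}
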