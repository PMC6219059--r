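#' Observed allele frequencies of a dosage matrix
#'
#' @param genotypes Numeric matrix of allele dosages (0/1/2, `NA` allowed),
#'   individuals in rows, loci in columns.
#' @return Named numeric vector of frequencies of the counted allele.
#' @export
allele_freqs <- function(genotypes) {
  stopifnot(is.matrix(genotypes))
  colMeans(genotypes, na.rm = TRUE) / 2
}

#' Filter loci on minor allele frequency
#'
#' Keeps loci with `min(p, 1 - p) > threshold`, computed from observed
#' frequencies (so `threshold = 0` drops monomorphic loci only).
#'
#' @inheritParams allele_freqs
#' @param threshold MAF threshold in `[0, 0.5)`; loci must exceed it strictly.
#' @return The dosage matrix restricted to retained loci (ids preserved).
#' @export
maf_filter <- function(genotypes, threshold = 0.01) {
  stopifnot(is.matrix(genotypes), threshold >= 0, threshold < 0.5)
  p <- allele_freqs(genotypes)
  keep <- !is.na(p) & pmin(p, 1 - p) > threshold
  genotypes[, keep, drop = FALSE]
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' `G = Z Z' / (2 * sum(p_j (1 - p_j)))` with `Z = M - 2p`. Missing dosages
#' are mean-imputed to `2 p_j` before centering (they then contribute zero to
#' Z). Frequencies default to those observed in `genotypes`; base-population
#' frequencies can be supplied instead.
#'
#' @inheritParams allele_freqs
#' @param freqs Optional numeric vector of allele frequencies, one per locus.
#' @param ridge Value added to the diagonal (default 0); a small ridge such as
#'   `1e-8` makes a GRM safely invertible for GBLUP.
#' @return A symmetric matrix with individual ids as dimnames and attribute
#'   `source = "genomic"`.
#' @export
grm <- function(genotypes, freqs = NULL, ridge = 0) {
  stopifnot(is.matrix(genotypes), ncol(genotypes) >= 1)
  p <- if (is.null(freqs)) allele_freqs(genotypes) else freqs
  stopifnot(length(p) == ncol(genotypes))
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) {
    stop("all loci are monomorphic: GRM denominator 2*sum(p(1-p)) is zero",
         call. = FALSE)
  }
  Z <- sweep(genotypes, 2, 2 * p)
  Z[is.na(Z)] <- 0
  G <- tcrossprod(Z) / denom
  if (ridge > 0) diag(G) <- diag(G) + ridge
  dimnames(G) <- list(rownames(genotypes), rownames(genotypes))
  attr(G, "source") <- "genomic"
  G
}
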