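#' Construct a validated pedigree
#'
#' Builds a pedigree object from a data frame of trio records. Parent codes
#' `"0"`, `0` and `NA` all denote an unknown parent. The pedigree is sorted
#' topologically (parents before offspring) and validated: ids must be unique,
#' every non-missing parent must itself appear as an individual, and no
#' individual may be its own ancestor.
#'
#' @param data Data frame with one row per individual.
#' @param id,sire,dam Names of the columns holding individual, sire and dam
#'   ids. Defaults `"id"`, `"sire"`, `"dam"`.
#' @return A tibble of class `"pedigree"` with character columns `id`, `sire`,
#'   `dam` (`NA` = unknown parent), in topological order. Any further columns
#'   of `data` are carried along.
#' @examples
#' ped <- as_pedigree(data.frame(id = c("s", "d", "o"),
#'                               sire = c("0", "0", "s"),
#'                               dam  = c("0", "0", "d")))
#' @export
as_pedigree <- function(data, id = "id", sire = "sire", dam = "dam") {
  stopifnot(is.data.frame(data))
  miss <- setdiff(c(id, sire, dam), names(data))
  if (length(miss) > 0) {
    stop("pedigree columns not found: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ped <- tibble::as_tibble(data)
  names(ped)[match(c(id, sire, dam), names(ped))] <- c("id", "sire", "dam")
  ped <- dplyr::relocate(ped, "id", "sire", "dam")
  ped$id <- as.character(ped$id)
  ped$sire <- unknown_to_na(ped$sire)
  ped$dam <- unknown_to_na(ped$dam)

  if (anyDuplicated(ped$id)) {
    dup <- unique(ped$id[duplicated(ped$id)])
    stop("duplicated individual ids: ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  parents <- c(ped$sire, ped$dam)
  bad <- setdiff(parents[!is.na(parents)], ped$id)
  if (length(bad) > 0) {
    stop("parent id(s) not present as individuals: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }

  ped <- topo_sort_pedigree(ped)
  class(ped) <- c("pedigree", class(ped))
  ped
}

unknown_to_na <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & (x == "0" | x == "")] <- NA_character_
  x
}

# Kahn-style iterative placement; detects cycles (incl. self-ancestry).
topo_sort_pedigree <- function(ped) {
  n <- nrow(ped)
  sire_i <- match(ped$sire, ped$id)
  dam_i <- match(ped$dam, ped$id)
  placed <- logical(n)
  order <- integer(0)
  repeat {
    ready <- !placed &
      (is.na(sire_i) | placed[pmax(sire_i, 1L)] & !is.na(sire_i)) &
      (is.na(dam_i) | placed[pmax(dam_i, 1L)] & !is.na(dam_i))
    ready[is.na(ready)] <- FALSE
    if (!any(ready)) break
    order <- c(order, which(ready))
    placed[ready] <- TRUE
  }
  if (!all(placed)) {
    stop("pedigree contains a cycle (individual its own ancestor?) involving: ",
         paste(utils::head(ped$id[!placed], 5), collapse = ", "), call. = FALSE)
  }
  ped[order, , drop = FALSE]
}

#' Numerator relationship matrix by the tabular method
#'
#' Computes the dense pedigree-based numerator relationship matrix A
#' (Wright's relationships), with `diag(A) = 1 + F` where `F` is the
#' inbreeding coefficient. Intended for desk-scale pedigrees (up to a few
#' thousand individuals).
#'
#' @param pedigree A [as_pedigree()] object (or a data frame coercible to one).
#' @return A symmetric numeric matrix with ids as dimnames and attribute
#'   `source = "pedigree"`.
#' @export
nrm <- function(pedigree) {
  ped <- ensure_pedigree(pedigree)
  n <- nrow(ped)
  s <- match(ped$sire, ped$id)
  d <- match(ped$dam, ped$id)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    si <- s[i]; di <- d[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (!is.na(si)) row <- row + 0.5 * A[si, j]
      if (!is.na(di)) row <- row + 0.5 * A[di, j]
      A[i, j] <- row
      A[j, i] <- row
    }
    A[i, i] <- 1 + if (!is.na(si) && !is.na(di)) 0.5 * A[si, di] else 0
  }
  attr(A, "source") <- "pedigree"
  A
}

ensure_pedigree <- function(pedigree) {
  if (inherits(pedigree, "pedigree")) pedigree else as_pedigree(pedigree)
}

#' Inbreeding coefficients
#'
#' `F_i = diag(A)_i - 1` from the tabular numerator relationship matrix;
#' founders have `F = 0`.
#'
#' @inheritParams nrm
#' @return A tibble with columns `id` and `F`, in pedigree order.
#' @export
inbreeding <- function(pedigree) {
  ped <- ensure_pedigree(pedigree)
  A <- nrm(ped)
  tibble::tibble(id = ped$id, F = unname(diag(A) - 1))
}

#' Genetic-variance factor of a focal set
#'
#' The scalar `mean(diag(K)) - mean(K)` over the focal block of a relationship
#' matrix, i.e. `tr(S K)/n` with `S` the centering matrix. Verbally this is
#' `1 + Fbar - 2*fbar`: it multiplies the base genetic variance to give the
#' expected empirical variance of true breeding values within the focal set,
#' and appears in every LR expectation. The grand mean includes the diagonal
#' (the exact quadratic-form quantity).
#'
#' @param K Relationship matrix with id dimnames (from [nrm()] or [grm()]).
#' @param focal Character ids, or integer/logical index, of the focal
#'   individuals. Default: all.
#' @return A single number.
#' @export
variance_factor <- function(K, focal = NULL) {
  Kf <- focal_block(K, focal)
  mean(diag(Kf)) - mean(Kf)
}

focal_block <- function(K, focal = NULL) {
  stopifnot(is.matrix(K))
  if (is.null(focal)) return(K)
  if (is.character(focal)) {
    miss <- setdiff(focal, rownames(K))
    if (length(miss) > 0) {
      stop("focal id(s) not in relationship matrix: ",
           paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
    }
    focal <- match(focal, rownames(K))
  }
  if (length(focal) == 0 || (is.logical(focal) && !any(focal))) {
    stop("empty focal set", call. = FALSE)
  }
  K[focal, focal, drop = FALSE]
}
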