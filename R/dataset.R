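# SFS dataset container: per-locus counts, lengths, optional substitution
# counts to an outgroup.

#' Multilocus SFS dataset
#'
#' @param counts Integer matrix of per-locus spectra, `K` rows; `n - 1`
#'   columns (derived-allele classes `1..n-1`) if unfolded, `floor(n/2)`
#'   columns (minor-allele classes) if folded.  A vector is taken as a
#'   single locus.
#' @param m Numeric vector of locus lengths in bp (length `K`).
#' @param n Sample size (alleles).
#' @param x Optional integer vector of substitution counts (length `K`).
#' @param folded Logical; whether `counts` are folded spectra.
#' @param ids Optional character vector of locus labels.
#' @return An object of class `"sfs_dataset"`.
#' @export
sfs_dataset <- function(counts, m, n, x = NULL, folded = FALSE, ids = NULL) {
  if (is.vector(counts)) counts <- matrix(counts, nrow = 1L)
  counts <- as.matrix(counts)
  K <- nrow(counts)
  n <- as.integer(n)
  if (n < 2L) stop("n must be >= 2")
  L <- if (folded) n %/% 2L else n - 1L
  if (ncol(counts) != L)
    stop(sprintf("counts must have %d columns for n = %d (%s)",
                 L, n, if (folded) "folded" else "unfolded"))
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (length(m) != K || any(!is.finite(m)) || any(m <= 0))
    stop("m must be positive locus lengths, one per locus")
  if (!is.null(x)) {
    if (length(x) != K || any(!is.finite(x)) || any(x < 0) ||
        any(x != round(x)))
      stop("x must be non-negative substitution counts, one per locus")
    x <- as.numeric(x)
  }
  if (is.null(ids)) ids <- paste0("locus", seq_len(K))
  if (anyDuplicated(ids)) stop("duplicate locus ids")
  structure(list(n = n, folded = isTRUE(folded), ids = as.character(ids),
                 m = as.numeric(m), counts = counts, x = x),
            class = "sfs_dataset")
}

#' @export
print.sfs_dataset <- function(x, ...) {
  cat(sprintf("SFS dataset: %d %s, n = %d alleles, %s%s\n",
              nrow(x$counts), if (nrow(x$counts) == 1) "locus" else "loci",
              x$n, if (x$folded) "folded" else "unfolded",
              if (!is.null(x$x)) ", with divergence counts" else ""))
  cat(sprintf("  segregating sites: total %d (per-locus %s)\n",
              as.integer(sum(x$counts)),
              paste(utils::head(rowSums(x$counts), 5L), collapse = ", ")))
  invisible(x)
}

#' Per-locus numbers of segregating sites
#'
#' @param data An [sfs_dataset()].
#' @return Numeric vector `S_k = sum_i d_{k,i}`.
#' @export
segregating_sites <- function(data) rowSums(data$counts)

#' Fold an unfolded dataset
#'
#' Collapses derived-allele classes `i` and `n - i` into minor-allele
#' classes; the total count per locus is conserved.
#'
#' @param data An unfolded [sfs_dataset()].
#' @return A folded [sfs_dataset()].
#' @export
fold_dataset <- function(data) {
  if (data$folded) stop("dataset is already folded")
  folded <- t(apply(data$counts, 1L, fold_expected, n = data$n))
  if (data$n %/% 2L == 1L) folded <- matrix(folded, ncol = 1L)
  sfs_dataset(folded, data$m, data$n, x = data$x, folded = TRUE,
              ids = data$ids)
}

#' Pool loci into a single combined spectrum
#'
#' Sums counts classwise across loci (and substitution counts if present),
#' producing the single-locus dataset used by naive combined-data analyses.
#'
#' @param data An unfolded [sfs_dataset()] with uniform sample size.
#' @return An [sfs_dataset()] with one locus of length `sum(m)`.
#' @export
pool_dataset <- function(data) {
  if (data$folded) stop("pooling is defined for unfolded data")
  sfs_dataset(colSums(data$counts), sum(data$m), data$n,
              x = if (!is.null(data$x)) sum(data$x) else NULL,
              ids = "pooled")
}

#' Subset loci of a dataset
#'
#' @param data An [sfs_dataset()].
#' @param idx Integer indices of the loci to keep (repeats allowed, as in a
#'   bootstrap resample).
#' @return An [sfs_dataset()].
#' @export
subset_loci <- function(data, idx) {
  ids <- data$ids[idx]
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  sfs_dataset(data$counts[idx, , drop = FALSE], data$m[idx], data$n,
              x = if (!is.null(data$x)) data$x[idx] else NULL,
              folded = data$folded, ids = ids)
}

## validate that a model and dataset agree in dimensions
.check_dims <- function(data, model) {
  if (length(model$loci) != nrow(data$counts))
    stop("model and data disagree in the number of loci")
  invisible(TRUE)
}
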