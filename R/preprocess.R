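#' Quantile normalization across samples
#'
#' Forces every column (sample) of the matrix to the same empirical
#' distribution: the across-column mean of order statistics. Within-column
#' rank order is preserved, and ties within a column receive the mean of the
#' target quantiles they span. The transform is idempotent.
#'
#' @param matrix Numeric matrix, genes x samples, all values finite.
#' @return Matrix of the same shape and dimnames. A single-column input is
#'   returned unchanged with a warning (there is nothing to normalize
#'   against).
#' @export
quantile_normalize <- function(matrix) {
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    stop("quantile_normalize expects a numeric matrix", call. = FALSE)
  }
  if (!all(is.finite(matrix))) {
    stop("quantile_normalize: non-finite values in input", call. = FALSE)
  }
  if (ncol(matrix) < 2L) {
    warning("quantile normalization skipped: fewer than 2 samples")
    return(matrix)
  }
  out <- limma::normalizeQuantiles(matrix, ties = TRUE)
  dimnames(out) <- dimnames(matrix)
  out
}

#' Standardize a numeric vector to z-scores
#'
#' `(x - mean(x)) / sd(x)` with the sample (n-1 denominator) standard
#' deviation, so the output has mean 0 and sd 1.
#'
#' @param values Numeric vector, length >= 2, not all equal.
#' @return Numeric vector of z-scores (names preserved).
#' @export
zscore <- function(values) {
  if (length(values) < 2L) {
    stop("zscore requires at least 2 values", call. = FALSE)
  }
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) {
    stop("zscore undefined for a constant vector", call. = FALSE)
  }
  (values - mean(values)) / s
}

#' Restrict a signature matrix and a mixture matrix to their shared genes
#'
#' Deconvolution uses the overlap of the signature's genes with the mixture's
#' genes as the final feature set. Both matrices are returned restricted to
#' that intersection, in the signature's gene order.
#'
#' @param signature Numeric matrix, signature genes x classes.
#' @param mixture Numeric matrix, genes x mixture samples.
#' @return List with elements `signature` and `mixture`, both row-restricted
#'   to the common genes in identical order, and `n_common`.
#' @export
align_genes <- function(signature, mixture) {
  common <- intersect(rownames(signature), rownames(mixture))
  if (length(common) == 0L) {
    stop("no genes shared between signature and mixture", call. = FALSE)
  }
  if (length(common) < ncol(signature)) {
    stop("only ", length(common), " shared genes for ", ncol(signature),
         " cell types: system underdetermined", call. = FALSE)
  }
  list(signature = signature[common, , drop = FALSE],
       mixture = mixture[common, , drop = FALSE],
       n_common = length(common))
}

# Standardize a signature matrix for regression. "global" (default) uses one
# mean/sd over all entries, keeping relative magnitudes across cell types
# intact; "per-column" standardizes each cell-type column separately.
standardize_signature <- function(signature, scope = c("global", "per-column")) {
  scope <- match.arg(scope)
  if (scope == "global") {
    s <- stats::sd(as.vector(signature))
    if (!is.finite(s) || s == 0) {
      stop("signature matrix is constant; cannot standardize", call. = FALSE)
    }
    out <- (signature - mean(signature)) / s
  } else {
    out <- apply(signature, 2L, zscore)
    dimnames(out) <- dimnames(signature)
  }
  out
}
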