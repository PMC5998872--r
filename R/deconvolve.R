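#' Deconvolution configuration
#'
#' @param nu_grid Candidate nu values for the support-vector regression, each
#'   in (0, 1]; nu bounds the fraction of support vectors and training
#'   errors. Default `c(0.25, 0.5, 0.75)`.
#' @param zscore_scope How the signature matrix is standardized before the
#'   fit: `"global"` (one mean/sd over all entries, preserving relative
#'   magnitudes across cell types; the default) or `"per-column"`.
#' @param cost SVR cost constant C (default 1); nu controls the
#'   support-vector fraction while cost scales the penalty.
#' @param tolerance Solver termination tolerance (default 1e-6).
#' @return A `deconv_config` list.
#' @export
deconv_config <- function(nu_grid = c(0.25, 0.5, 0.75),
                          zscore_scope = c("global", "per-column"),
                          cost = 1, tolerance = 1e-6) {
  zscore_scope <- match.arg(zscore_scope)
  nu_grid <- sort(unique(as.numeric(nu_grid)))
  if (length(nu_grid) == 0L || any(nu_grid <= 0 | nu_grid > 1)) {
    stop("nu_grid must be non-empty with every nu in (0, 1]", call. = FALSE)
  }
  if (cost <= 0) stop("cost must be positive", call. = FALSE)
  structure(list(nu_grid = nu_grid, zscore_scope = zscore_scope,
                 cost = cost, tolerance = tolerance),
            class = "deconv_config")
}

#' Fit one linear-kernel nu-SVR and extract cell-type coefficients
#'
#' Regresses the standardized mixture vector on the rows of the standardized
#' signature matrix (observations = genes, features = cell types) with
#' `e1071::svm(type = "nu-regression", kernel = "linear")`. The primal weight
#' vector, one coefficient per cell type, is recovered from the support
#' vectors as `t(coefs) %*% SV`. Support vectors correspond to a subset of
#' signature genes.
#'
#' @param S_std Standardized signature matrix, genes x classes.
#' @param m_std Standardized mixture vector over the same genes.
#' @param nu The nu parameter, in (0, 1].
#' @param cost SVR cost constant (default 1).
#' @param tolerance Solver tolerance (default 1e-6).
#' @return Named numeric vector of raw (possibly negative) coefficients, one
#'   per class.
#' @export
fit_single_nu <- function(S_std, m_std, nu, cost = 1, tolerance = 1e-6) {
  if (nrow(S_std) < ncol(S_std)) {
    stop("fewer genes than cell types: system underdetermined", call. = FALSE)
  }
  if (length(m_std) != nrow(S_std)) {
    stop("mixture vector length does not match signature genes", call. = FALSE)
  }
  fit <- tryCatch(
    e1071::svm(x = S_std, y = m_std, type = "nu-regression",
               kernel = "linear", nu = nu, cost = cost, scale = FALSE,
               tolerance = tolerance),
    error = function(e) {
      stop("nu-SVR solver failed at nu = ", nu, ": ", conditionMessage(e),
           call. = FALSE)
    })
  w <- as.vector(t(fit$coefs) %*% fit$SV)
  stats::setNames(w, colnames(S_std))
}

#' Clip negative coefficients and normalize to proportions
#'
#' Negative regression coefficients are set to 0 and the remainder divided by
#' their sum, yielding non-negative fractions that sum to 1.
#'
#' @param raw_coefficients Numeric vector with at least one positive entry.
#' @return Numeric vector of proportions (names preserved).
#' @export
clip_and_normalize <- function(raw_coefficients) {
  w <- pmax(raw_coefficients, 0)
  s <- sum(w)
  if (s <= 0) {
    stop("all coefficients non-positive: proportions undefined", call. = FALSE)
  }
  w / s
}

#' Fit the nu grid for one mixture and keep the lowest-RMSE model
#'
#' Every nu in the grid is fit; the model minimizing the root-mean-square
#' error between the standardized mixture and its reconstruction
#' `S_std %*% w_raw` (raw, pre-clipping coefficients) is selected, ties going
#' to the smallest nu. The winning coefficients are then clipped at zero and
#' normalized to sum to 1.
#'
#' @param S_std Standardized signature matrix, genes x classes.
#' @param m_std Standardized mixture vector.
#' @param config A [deconv_config()].
#' @return A `fit_result` list: `raw_coefficients`, `proportions`,
#'   `chosen_nu`, `reconstruction_rmse`, `reconstruction_correlation`.
#' @export
select_nu <- function(S_std, m_std, config = deconv_config()) {
  fits <- lapply(config$nu_grid, function(nu) {
    tryCatch(fit_single_nu(S_std, m_std, nu, cost = config$cost,
                           tolerance = config$tolerance),
             error = function(e) e)
  })
  ok <- !vapply(fits, inherits, logical(1), "error")
  if (!any(ok)) {
    stop("every nu in the grid failed; first error: ",
         conditionMessage(fits[[1]]), call. = FALSE)
  }
  rmses <- rep(Inf, length(fits))
  for (k in which(ok)) {
    recon <- as.vector(S_std %*% fits[[k]])
    rmses[k] <- sqrt(mean((m_std - recon)^2))
  }
  best <- which.min(rmses)  # grid sorted ascending: ties pick smallest nu
  w <- fits[[best]]
  recon <- as.vector(S_std %*% w)
  structure(list(raw_coefficients = w,
                 proportions = clip_and_normalize(w),
                 chosen_nu = config$nu_grid[best],
                 reconstruction_rmse = rmses[best],
                 reconstruction_correlation = stats::cor(m_std, recon)),
            class = "fit_result")
}

#' Estimate cell-type proportions in bulk mixtures
#'
#' The full solving stage: the mixture matrix is quantile normalized, genes
#' are restricted to the overlap with the signature, the signature is
#' standardized (scope per `config`) and each mixture column z-scored over
#' the shared genes, and each sample is deconvolved independently by
#' linear-kernel nu-SVR with nu selected by lowest reconstruction RMSE.
#' Negative coefficients are clipped and the rest normalized to sum to 1.
#'
#' @param mixtures Numeric matrix, genes x mixture samples, linear scale.
#' @param signature Numeric matrix, signature genes x classes (raw class
#'   means, e.g. from [build_signature_matrix()]).
#' @param config A [deconv_config()].
#' @return A `proportion_table` (see [proportion_table()]): per-sample
#'   fractions plus chosen nu, reconstruction RMSE and correlation.
#' @export
deconvolve <- function(mixtures, signature, config = deconv_config()) {
  validate_expression_matrix(mixtures, "mixtures")
  mixtures <- quantile_normalize(mixtures)
  al <- align_genes(signature, mixtures)
  S_std <- standardize_signature(al$signature, scope = config$zscore_scope)
  classes <- colnames(signature)
  n <- ncol(al$mixture)
  frac <- matrix(NA_real_, n, length(classes),
                 dimnames = list(colnames(al$mixture), classes))
  nu <- rmse <- rho <- numeric(n)
  for (j in seq_len(n)) {
    res <- tryCatch(
      select_nu(S_std, zscore(al$mixture[, j]), config = config),
      error = function(e) {
        stop("sample '", colnames(al$mixture)[j], "': ", conditionMessage(e),
             call. = FALSE)
      })
    frac[j, ] <- res$proportions
    nu[j] <- res$chosen_nu
    rmse[j] <- res$reconstruction_rmse
    rho[j] <- res$reconstruction_correlation
  }
  proportion_table(frac, chosen_nu = nu, reconstruction_rmse = rmse,
                   reconstruction_correlation = rho)
}
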