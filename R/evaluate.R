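#' Pearson correlation with explicit degenerate-input contract
#'
#' @param x,y Numeric vectors of equal length >= 2, neither constant.
#' @return The product-moment correlation.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 2L) stop("need at least 2 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Root-mean-square error
#'
#' @param x,y Numeric vectors of equal length >= 1.
#' @return `sqrt(mean((x - y)^2))`.
#' @export
rmse <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) == 0L) stop("empty input", call. = FALSE)
  sqrt(mean((x - y)^2))
}

#' Restrict proportions to a class subset and rescale rows to 1
#'
#' Benchmark data often type only a subset of cell types (and at coarser
#' granularity, e.g. resting and activated NK cells counted together as NK
#' cells). Fine classes are first summed into benchmark classes per
#' `class_map`, then restricted to `classes` and each sample's fractions
#' renormalized to sum to 1.
#'
#' @param estimates A `proportion_table` or a samples x classes matrix.
#' @param classes Character vector: the benchmark classes to keep.
#' @param class_map Optional named character vector mapping fine class ->
#'   benchmark class; unmapped classes keep their own label.
#' @return A `proportion_table` over `classes` (diagnostics, if present,
#'   are preserved).
#' @export
rescale_subset <- function(estimates, classes, class_map = NULL) {
  if (inherits(estimates, "proportion_table")) {
    frac <- proportion_matrix(estimates)
    diag <- estimates[, c("chosen_nu", "reconstruction_rmse",
                          "reconstruction_correlation")]
  } else {
    frac <- as.matrix(estimates)
    diag <- NULL
  }
  if (length(classes) == 0L) stop("empty class subset", call. = FALSE)
  mapped <- colnames(frac)
  if (!is.null(class_map)) {
    hit <- mapped %in% names(class_map)
    mapped[hit] <- class_map[mapped[hit]]
  }
  agg <- t(rowsum(t(frac), group = mapped))
  missing <- setdiff(classes, colnames(agg))
  if (length(missing) > 0L) {
    stop("class(es) absent from estimates: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  sub <- agg[, classes, drop = FALSE]
  s <- rowSums(sub)
  zero <- which(s <= 0)
  if (length(zero) > 0L) {
    stop("subset fractions sum to 0 for sample(s): ",
         paste(rownames(sub)[zero], collapse = ", "), call. = FALSE)
  }
  sub <- sub / s
  if (is.null(diag)) {
    proportion_table(sub)
  } else {
    proportion_table(sub, chosen_nu = diag$chosen_nu,
                     reconstruction_rmse = diag$reconstruction_rmse,
                     reconstruction_correlation =
                       diag$reconstruction_correlation)
  }
}

#' Benchmark estimated proportions against known compositions
#'
#' Estimates are mapped/rescaled onto the classes present in the truth table
#' (see [rescale_subset()]); classes estimated but never typed in the truth
#' are dropped with a message. Pearson correlation and RMSE on proportions
#' are reported per cell type (across samples), per sample (across cell
#' types) and pooled over all sample-class cells. Reconstruction RMSE on
#' signature-gene expression is a different quantity, carried per sample in
#' the deconvolution diagnostics.
#'
#' @param estimates A `proportion_table` or samples x classes matrix.
#' @param truth A `proportion_table` or samples x classes matrix of reference
#'   compositions (e.g. flow cytometry fractions).
#' @param class_map Optional named character vector mapping fine estimate
#'   classes to truth classes.
#' @return A `benchmark_result` list: `per_class` and `per_sample` data
#'   frames of `pearson_r` and `rmse`, pooled `pearson_r` and `rmse`, and
#'   the class subset used.
#' @export
benchmark_proportions <- function(estimates, truth, class_map = NULL) {
  tm <- if (inherits(truth, "proportion_table")) proportion_matrix(truth)
        else as.matrix(truth)
  em <- if (inherits(estimates, "proportion_table"))
          proportion_matrix(estimates) else as.matrix(estimates)
  mapped <- colnames(em)
  if (!is.null(class_map)) {
    hit <- mapped %in% names(class_map)
    mapped[hit] <- class_map[mapped[hit]]
  }
  dropped <- setdiff(unique(mapped), colnames(tm))
  if (length(dropped) > 0L) {
    message("class(es) not typed in truth, dropped from benchmark: ",
            paste(dropped, collapse = ", "))
  }
  samples <- intersect(rownames(em), rownames(tm))
  if (length(samples) == 0L) {
    stop("no shared samples between estimates and truth", call. = FALSE)
  }
  classes <- sort(intersect(unique(mapped), colnames(tm)))
  est <- proportion_matrix(rescale_subset(em[samples, , drop = FALSE],
                                          classes, class_map))
  tru <- tm[samples, classes, drop = FALSE]
  tru <- tru / rowSums(tru)
  per_class <- data.frame(
    class = classes,
    pearson_r = vapply(classes, function(k)
      if (stats::sd(tru[, k]) == 0 || stats::sd(est[, k]) == 0) NA_real_
      else pearson(est[, k], tru[, k]), numeric(1)),
    rmse = vapply(classes, function(k) rmse(est[, k], tru[, k]), numeric(1)),
    row.names = NULL)
  per_sample <- data.frame(
    sample_id = samples,
    pearson_r = vapply(samples, function(s)
      if (stats::sd(tru[s, ]) == 0 || stats::sd(est[s, ]) == 0) NA_real_
      else pearson(est[s, ], tru[s, ]), numeric(1)),
    rmse = vapply(samples, function(s) rmse(est[s, ], tru[s, ]), numeric(1)),
    row.names = NULL)
  structure(list(per_class = per_class,
                 per_sample = per_sample,
                 pooled_pearson_r = pearson(as.vector(est), as.vector(tru)),
                 pooled_rmse = rmse(as.vector(est), as.vector(tru)),
                 classes = classes,
                 n_samples = length(samples)),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("Benchmark over", x$n_samples, "samples,", length(x$classes),
      "cell types\n")
  cat("  pooled Pearson r:", signif(x$pooled_pearson_r, 4),
      "| pooled RMSE:", signif(x$pooled_rmse, 4), "\n")
  print(x$per_class, digits = 3)
  invisible(x)
}

#' Overlap summary of two gene sets
#'
#' Generic set-overlap utility for comparing signature gene lists (e.g. a
#' newly built list against a published one).
#'
#' @param a,b Character vectors of gene IDs.
#' @return List with sizes of both sets, the intersection size and the counts
#'   unique to each.
#' @export
gene_set_overlap <- function(a, b) {
  a <- unique(a); b <- unique(b)
  list(n_a = length(a), n_b = length(b),
       n_shared = length(intersect(a, b)),
       n_only_a = length(setdiff(a, b)),
       n_only_b = length(setdiff(b, a)))
}
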