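#' Hierarchical clustering of reference arrays
#'
#' Agglomerative complete-linkage clustering of the sample columns in
#' Euclidean distance, used to eyeball whether replicate arrays group with
#' their annotated cell type.
#'
#' @param matrix Numeric matrix, genes x samples, finite values.
#' @return An [stats::hclust] tree whose leaves are the sample labels.
#' @export
cluster_samples <- function(matrix) {
  validate_expression_matrix(matrix)
  if (ncol(matrix) < 2L) {
    stop("clustering requires at least 2 samples", call. = FALSE)
  }
  # columns sorted by label first so equal-height merges resolve by label
  ord <- order(colnames(matrix))
  stats::hclust(stats::dist(t(matrix[, ord, drop = FALSE]),
                            method = "euclidean"),
                method = "complete")
}

#' Export a sample dendrogram in Newick format
#' @param hc An [stats::hclust] tree from [cluster_samples()].
#' @param path Optional output path; when `NULL` the Newick string is
#'   returned instead.
#' @return The Newick string (invisibly when written to file).
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  nwk <- ape::write.tree(ape::as.phylo(hc))
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}

#' Flag reference arrays that disagree with their phenotype label
#'
#' For each sample, Pearson correlations to every other sample of the same
#' annotated class are computed. A sample is flagged as an outlier when
#' strictly more than `pair_fraction` of those within-class pairs have
#' correlation below `r_threshold`. Classes with a single member cannot be
#' assessed and are skipped with a warning.
#'
#' @param matrix Numeric matrix, genes x samples.
#' @param annotation Named character vector (sample -> class).
#' @param r_threshold Pearson correlation below which a pair counts as
#'   discordant (default 0.85).
#' @param pair_fraction Fraction of a sample's within-class pairs that must be
#'   discordant, exceeded strictly, to flag it (default 2/3).
#' @return A `qc_report`: list with `evidence` (one row per assessed sample:
#'   class, number of pairs, number of low pairs, fraction, min/median
#'   within-class correlation, flagged), `outliers` (flagged sample IDs),
#'   `dendrogram` (complete-linkage tree) and the thresholds used.
#' @export
detect_outliers <- function(matrix, annotation, r_threshold = 0.85,
                            pair_fraction = 2 / 3) {
  validate_expression_matrix(matrix)
  validate_annotation(matrix, annotation)
  classes <- unique(annotation)
  rows <- list()
  for (cl in classes) {
    members <- names(annotation)[annotation == cl]
    if (length(members) < 2L) {
      warning("class '", cl, "' has a single sample; outlier screen skipped")
      next
    }
    cm <- stats::cor(matrix[, members, drop = FALSE])
    for (s in members) {
      peers <- setdiff(members, s)
      r <- cm[s, peers]
      n_low <- sum(r < r_threshold)
      frac <- n_low / length(r)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s, class = cl, n_pairs = length(r), n_low = n_low,
        frac_low = frac, min_r = min(r), median_r = stats::median(r),
        flagged = frac > pair_fraction, stringsAsFactors = FALSE)
    }
  }
  evidence <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_id = character(), class = character(),
               n_pairs = integer(), n_low = integer(), frac_low = numeric(),
               min_r = numeric(), median_r = numeric(), flagged = logical())
  structure(list(evidence = evidence,
                 outliers = evidence$sample_id[evidence$flagged],
                 dendrogram = cluster_samples(matrix),
                 r_threshold = r_threshold,
                 pair_fraction = pair_fraction),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:", nrow(x$evidence), "samples screened;",
      length(x$outliers), "flagged (r <", x$r_threshold, "in >",
      signif(x$pair_fraction, 3), "of within-class pairs)\n")
  if (length(x$outliers)) cat("  outliers:", paste(x$outliers, collapse = ", "), "\n")
  invisible(x)
}

#' Suggest cell-type classes whose profiles do not segregate
#'
#' A class pair is suggested for merging when the mean between-class
#' correlation is at least as high as the weaker of the two mean within-class
#' correlations, i.e. the two replicate groups interleave rather than form
#' separate clusters. Merging itself is always an explicit user action.
#'
#' @param matrix Numeric matrix, genes x samples.
#' @param annotation Named character vector (sample -> class).
#' @return Data frame of suggested pairs with within- and between-class mean
#'   correlations (possibly zero rows).
#' @export
suggest_merges <- function(matrix, annotation) {
  classes <- names(class_census(annotation))
  out <- list()
  if (length(classes) < 2L) {
    return(data.frame(class_a = character(), class_b = character(),
                      within_a = numeric(), within_b = numeric(),
                      between = numeric()))
  }
  mean_within <- function(cl) {
    m <- names(annotation)[annotation == cl]
    if (length(m) < 2L) return(NA_real_)
    cm <- stats::cor(matrix[, m, drop = FALSE])
    mean(cm[upper.tri(cm)])
  }
  for (i in seq_len(length(classes) - 1L)) {
    for (j in seq(i + 1L, length(classes))) {
      a <- names(annotation)[annotation == classes[i]]
      b <- names(annotation)[annotation == classes[j]]
      wa <- mean_within(classes[i]); wb <- mean_within(classes[j])
      bt <- mean(stats::cor(matrix[, a, drop = FALSE],
                            matrix[, b, drop = FALSE]))
      if (!is.na(wa) && !is.na(wb) && bt >= min(wa, wb)) {
        out[[length(out) + 1L]] <- data.frame(
          class_a = classes[i], class_b = classes[j],
          within_a = wa, within_b = wb, between = bt)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(class_a = character(), class_b = character(),
               within_a = numeric(), within_b = numeric(), between = numeric())
}

#' Remove reference samples from a matrix and its annotation
#'
#' @param matrix Numeric matrix, genes x samples.
#' @param annotation Named character vector (sample -> class).
#' @param sample_ids Samples to drop; all must exist in the matrix.
#' @return List with `matrix` and `annotation` minus the dropped columns.
#'   A warning reports any class left with fewer than 2 members.
#' @export
drop_samples <- function(matrix, annotation, sample_ids) {
  if (length(sample_ids) == 0L) {
    return(list(matrix = matrix, annotation = annotation))
  }
  unknown <- setdiff(sample_ids, colnames(matrix))
  if (length(unknown) > 0L) {
    stop("unknown sample(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  keep <- setdiff(colnames(matrix), sample_ids)
  ann <- annotation[setdiff(names(annotation), sample_ids)]
  census <- class_census(ann)
  small <- names(census)[census < 2L]
  if (length(small) > 0L) {
    warning("class(es) reduced below 2 replicates: ",
            paste(small, collapse = ", "))
  }
  list(matrix = matrix[, keep, drop = FALSE], annotation = ann)
}

#' Merge cell-type classes in an annotation
#'
#' Reassigns every sample of the listed classes to a single new label, e.g.
#' collapsing resting and activated mast cells into one mast-cell category.
#'
#' @param annotation Named character vector (sample -> class).
#' @param labels_to_merge Character vector of existing class labels.
#' @param new_label Replacement label.
#' @return Updated annotation.
#' @export
merge_classes <- function(annotation, labels_to_merge, new_label) {
  unknown <- setdiff(labels_to_merge, annotation)
  if (length(unknown) > 0L) {
    stop("unknown class label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  annotation[annotation %in% labels_to_merge] <- new_label
  annotation
}
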