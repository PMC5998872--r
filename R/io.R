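#' Read a genes-by-samples expression matrix from delimited text
#'
#' Expects a header row of sample labels and a first column of gene symbols.
#' All remaining cells must be numeric. Duplicate gene rows are collapsed to
#' their per-sample mean (a symmetric, order-independent rule); the number of
#' collapsed rows is recorded in the `"n_collapsed"` attribute. All statistics
#' downstream operate on linear-scale intensities, so files stored on the log2
#' scale must be declared with `log2_input = TRUE` and are anti-logged at load.
#'
#' @param path Path to a TSV or CSV file.
#' @param delimiter Field separator. `NULL` (default) auto-detects from the
#'   file extension: `.csv` means comma, anything else tab.
#' @param log2_input Logical; if `TRUE`, values are transformed by `2^x` at
#'   load so that the in-memory matrix is linear-scale.
#' @return Numeric matrix, genes x samples, with gene symbols as row names and
#'   sample labels as column names. Attribute `"n_collapsed"` holds the number
#'   of duplicate gene rows that were averaged away.
#' @export
read_expression_matrix <- function(path, delimiter = NULL, log2_input = FALSE) {
  if (!file.exists(path)) {
    stop("expression matrix file not found: ", path, call. = FALSE)
  }
  sep <- delimiter %||% detect_delimiter(path)
  header <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  sample_ids <- header[-1]
  if (length(sample_ids) == 0L) {
    stop("empty expression matrix: no sample columns in ", path, call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample labels in ", path, ": ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (length(readLines(path, n = 2L)) < 2L) {
    stop("empty expression matrix: no gene rows in ", path, call. = FALSE)
  }
  body <- utils::read.table(path, sep = sep, skip = 1L, header = FALSE,
                            colClasses = "character", check.names = FALSE,
                            quote = "\"", comment.char = "")
  if (ncol(body) != length(header)) {
    stop("malformed file ", path, ": header has ", length(header),
         " fields but data rows have ", ncol(body), call. = FALSE)
  }
  gene_ids <- body[[1]]
  values <- suppressWarnings(
    vapply(body[-1], as.numeric, numeric(nrow(body)))
  )
  values <- matrix(values, nrow = nrow(body),
                   dimnames = list(gene_ids, sample_ids))
  bad <- which(is.na(values) | !is.finite(values), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("non-numeric or non-finite cell at gene '", gene_ids[bad[1, 1]],
         "', sample '", sample_ids[bad[1, 2]], "' in ", path, call. = FALSE)
  }
  n_in <- nrow(values)
  values <- collapse_duplicate_genes(values)
  if (log2_input) values <- 2^values
  attr(values, "n_collapsed") <- n_in - nrow(values)
  values
}

#' Write an expression matrix to delimited text
#'
#' @param matrix Numeric matrix, genes x samples, with dimnames.
#' @param path Output path; delimiter chosen from the extension
#'   (`.csv` = comma, otherwise tab).
#' @return Invisibly, `path`.
#' @export
write_expression_matrix <- function(matrix, path) {
  validate_expression_matrix(matrix)
  sep <- detect_delimiter(path)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("gene", colnames(matrix)), collapse = sep), con)
  body <- apply(matrix, 1L, function(v)
    paste(format(v, digits = 15, trim = TRUE, scientific = FALSE),
          collapse = sep))
  writeLines(paste(rownames(matrix), body, sep = sep), con)
  invisible(path)
}

detect_delimiter <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

collapse_duplicate_genes <- function(values) {
  if (!anyDuplicated(rownames(values))) return(values)
  ids <- rownames(values)
  out <- rowsum(values, group = ids, reorder = FALSE) /
    as.vector(table(factor(ids, levels = unique(ids))))
  out
}

validate_expression_matrix <- function(x, arg = "matrix") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(arg, " must be a numeric matrix (genes x samples)", call. = FALSE)
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop(arg, " must carry gene row names and sample column names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(x))) {
    stop(arg, " has duplicate gene identifiers", call. = FALSE)
  }
  if (anyDuplicated(colnames(x))) {
    stop(arg, " has duplicate sample labels", call. = FALSE)
  }
  if (!all(is.finite(x))) stop(arg, " contains non-finite values", call. = FALSE)
  invisible(x)
}

#' Read a sample-to-cell-type annotation
#'
#' A two-column delimited file (sample label, cell-type class). A header line
#' is detected and skipped when its first field is `sample` or `sample_id`.
#' Consistent duplicate rows are collapsed; conflicting duplicates (same
#' sample, different class) are an error.
#'
#' @param path Path to a two-column TSV/CSV.
#' @param delimiter Field separator; `NULL` auto-detects from the extension.
#' @return Named character vector mapping sample label to class label.
#' @export
read_annotation <- function(path, delimiter = NULL) {
  if (!file.exists(path)) {
    stop("annotation file not found: ", path, call. = FALSE)
  }
  sep <- delimiter %||% detect_delimiter(path)
  tab <- utils::read.table(path, sep = sep, header = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "")
  if (ncol(tab) < 2L) {
    stop("annotation must have two columns (sample, class): ", path,
         call. = FALSE)
  }
  if (tolower(tab[1, 1]) %in% c("sample", "sample_id")) tab <- tab[-1, ]
  ann <- stats::setNames(tab[[2]], tab[[1]])
  dup <- unique(names(ann)[duplicated(names(ann))])
  for (s in dup) {
    if (length(unique(ann[names(ann) == s])) > 1L) {
      stop("sample '", s, "' annotated with conflicting classes", call. = FALSE)
    }
  }
  ann[!duplicated(names(ann))]
}

#' Write a sample annotation to two-column TSV
#' @param annotation Named character vector (sample -> class).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_annotation <- function(annotation, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(annotation), annotation, sep = "\t"), con)
  invisible(path)
}

#' Tabulate class membership of an annotation
#' @param annotation Named character vector (sample -> class).
#' @return Named integer vector: class label -> number of samples.
#' @export
class_census <- function(annotation) {
  tab <- table(annotation)
  stats::setNames(as.integer(tab), names(tab))
}

#' Check that an annotation matches an expression matrix
#'
#' Every annotated sample must be a column of the matrix. With
#' `require_replicates = TRUE` (used ahead of differential testing) every
#' class must have at least two annotated samples.
#'
#' @param matrix Expression matrix (genes x samples).
#' @param annotation Named character vector (sample -> class).
#' @param require_replicates Logical; demand >= 2 samples per class.
#' @return Invisibly, the annotation restricted to the matrix samples.
#' @export
validate_annotation <- function(matrix, annotation, require_replicates = FALSE) {
  missing <- setdiff(names(annotation), colnames(matrix))
  if (length(missing) > 0L) {
    stop("annotated samples absent from expression matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (require_replicates) {
    census <- class_census(annotation)
    small <- names(census)[census < 2L]
    if (length(small) > 0L) {
      stop("classes with fewer than 2 replicates: ",
           paste(small, collapse = ", "), call. = FALSE)
    }
  }
  invisible(annotation)
}

#' Construct a proportion table
#'
#' Per-sample cell-type fractions plus fit diagnostics. Fractions must be
#' non-negative and each row must sum to 1 (to within 1e-8).
#'
#' @param fractions Numeric matrix, samples x classes, with dimnames.
#' @param chosen_nu Numeric vector, the nu picked for each sample (or `NA`).
#' @param reconstruction_rmse Numeric vector of per-sample reconstruction RMSE.
#' @param reconstruction_correlation Numeric vector of per-sample Pearson r
#'   between the standardized mixture and its reconstruction.
#' @return A `proportion_table`: a data frame with a `sample_id` column, one
#'   column per class, and trailing diagnostic columns; the class labels are
#'   kept in the `"class_labels"` attribute.
#' @export
proportion_table <- function(fractions, chosen_nu = NA_real_,
                             reconstruction_rmse = NA_real_,
                             reconstruction_correlation = NA_real_) {
  if (!is.matrix(fractions) || is.null(rownames(fractions)) ||
      is.null(colnames(fractions))) {
    stop("fractions must be a samples x classes matrix with dimnames",
         call. = FALSE)
  }
  n <- nrow(fractions)
  out <- data.frame(sample_id = rownames(fractions),
                    fractions, check.names = FALSE,
                    chosen_nu = rep_len(chosen_nu, n),
                    reconstruction_rmse = rep_len(reconstruction_rmse, n),
                    reconstruction_correlation =
                      rep_len(reconstruction_correlation, n),
                    row.names = NULL)
  structure(out, class = c("proportion_table", "data.frame"),
            class_labels = colnames(fractions))
}

#' Extract the fraction matrix from a proportion table
#' @param table A `proportion_table`.
#' @return Numeric matrix, samples x classes.
#' @export
proportion_matrix <- function(table) {
  classes <- attr(table, "class_labels")
  m <- as.matrix(table[, classes, drop = FALSE])
  rownames(m) <- table$sample_id
  m
}

validate_proportion_table <- function(table, tol = 1e-8) {
  frac <- proportion_matrix(table)
  if (any(frac < 0)) {
    stop("proportion table violates non-negativity", call. = FALSE)
  }
  bad <- which(abs(rowSums(frac) - 1) > tol)
  if (length(bad) > 0L) {
    stop("proportion rows do not sum to 1: sample(s) ",
         paste(rownames(frac)[bad], collapse = ", "), call. = FALSE)
  }
  invisible(table)
}

#' Write a proportion table to CSV
#'
#' Header row of class labels, one row per sample, diagnostics in trailing
#' columns. The table is validated first; re-reading reproduces the values to
#' better than 1e-12.
#'
#' @param table A `proportion_table`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_proportion_table <- function(table, path) {
  validate_proportion_table(table)
  con <- file(path, open = "wb")
  on.exit(close(con))
  num <- vapply(table, is.numeric, logical(1))
  tab <- table
  tab[num] <- lapply(tab[num], function(v)
    format(v, digits = 17, trim = TRUE, scientific = FALSE))
  writeLines(paste(names(tab), collapse = ","), con)
  writeLines(do.call(paste, c(unclass(tab), sep = ",")), con)
  invisible(path)
}

#' Read a proportion table written by [write_proportion_table()]
#' @param path CSV path.
#' @return A `proportion_table`.
#' @export
read_proportion_table <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  diag_cols <- c("chosen_nu", "reconstruction_rmse",
                 "reconstruction_correlation")
  classes <- setdiff(names(tab), c("sample_id", diag_cols))
  frac <- as.matrix(tab[, classes, drop = FALSE])
  rownames(frac) <- tab$sample_id
  proportion_table(frac,
                   chosen_nu = tab$chosen_nu,
                   reconstruction_rmse = tab$reconstruction_rmse,
                   reconstruction_correlation = tab$reconstruction_correlation)
}

#' Read a gene list (one symbol per line)
#' @param path Text file path.
#' @return Character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x[nzchar(trimws(x))]
}

#' Write a gene list, one symbol per line
#' @param genes Character vector.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_list <- function(genes, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(genes, con)
  invisible(path)
}

#' Write a signature matrix with a JSON metadata sidecar
#'
#' The matrix (genes x cell types) goes to TSV; construction metadata (chosen
#' G, condition number, scan trace, thresholds) to `<path>.json`.
#'
#' @param signature Numeric matrix, genes x classes.
#' @param path Output TSV path.
#' @param meta Named list of metadata (may be empty).
#' @return Invisibly, `path`.
#' @export
write_signature_matrix <- function(signature, path, meta = list()) {
  write_expression_matrix(signature, path)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a signature matrix written by [write_signature_matrix()]
#' @param path TSV path; the sidecar `<path>.json` is read when present.
#' @return Matrix with, if available, a `"meta"` attribute.
#' @export
read_signature_matrix <- function(path) {
  sig <- read_expression_matrix(path)
  attr(sig, "n_collapsed") <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    attr(sig, "meta") <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  sig
}
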