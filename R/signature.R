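#' Black list of genes expressed in normal (non-hematopoietic) tissues
#'
#' A gene is black-listed when its enrichment score exceeds `es_threshold` in
#' strictly more than `tissue_fraction` of the observed tissue types. The
#' enrichment-score table is consumed as input (genes x tissues); computing
#' the scores themselves is out of scope.
#'
#' @param es_table Numeric matrix, genes x tissues, of enrichment scores.
#' @param es_threshold Score above which a tissue counts as expressing the
#'   gene (default 0, strict).
#' @param tissue_fraction Fraction of tissues that must be exceeded, strictly
#'   (default 0.05).
#' @return Character vector of black-listed gene IDs with attribute
#'   `source = "normal_tissue"`.
#' @export
normal_tissue_blacklist <- function(es_table, es_threshold = 0,
                                    tissue_fraction = 0.05) {
  if (!is.matrix(es_table) || nrow(es_table) == 0L) {
    stop("es_table must be a non-empty genes x tissues matrix", call. = FALSE)
  }
  if (!all(is.finite(es_table))) {
    stop("non-finite enrichment scores", call. = FALSE)
  }
  frac <- rowMeans(es_table > es_threshold)
  structure(rownames(es_table)[frac > tissue_fraction],
            source = "normal_tissue")
}

#' Black list of genes expressed in cancer cell lines
#'
#' A gene is black-listed when its log2 expression exceeds `expr_threshold`
#' (strictly) in at least one cell line.
#'
#' @param ccle_table Numeric matrix, genes x cell lines, log2 expression.
#' @param expr_threshold Log2 expression cutoff (default 7, strict).
#' @return Character vector of black-listed gene IDs with attribute
#'   `source = "cancer"`.
#' @export
cancer_blacklist <- function(ccle_table, expr_threshold = 7) {
  if (!is.matrix(ccle_table)) {
    stop("ccle_table must be a genes x cell-lines matrix", call. = FALSE)
  }
  if (nrow(ccle_table) == 0L) return(structure(character(), source = "cancer"))
  if (!all(is.finite(ccle_table))) {
    stop("non-finite expression values", call. = FALSE)
  }
  hit <- apply(ccle_table > expr_threshold, 1L, any)
  structure(rownames(ccle_table)[hit], source = "cancer")
}

#' Remove black-listed genes from an expression matrix
#'
#' Filtration happens before differential-expression gene selection, so a
#' black-listed gene can never enter the signature.
#'
#' @param matrix Numeric matrix, genes x samples.
#' @param blacklists Character vector of gene IDs, or a list of such vectors.
#' @return The matrix without the black-listed rows; per-list removal counts
#'   are reported via `message()`.
#' @export
apply_blacklists <- function(matrix, blacklists) {
  if (!is.list(blacklists)) blacklists <- list(blacklists)
  all_banned <- character()
  for (bl in blacklists) {
    n <- sum(rownames(matrix) %in% bl)
    message("black list [", attr(bl, "source") %||% "user", "]: ",
            n, " gene(s) removed")
    all_banned <- union(all_banned, bl)
  }
  matrix[!(rownames(matrix) %in% all_banned), , drop = FALSE]
}

# Vectorized Welch statistics for matched gene rows of two replicate groups.
# a, b: genes x replicates matrices. Returns t, Welch-Satterthwaite df and
# two-sided p per gene. Genes where both groups are constant and equal get
# t = 0, p = 1; constant-but-different genes get t = +/-Inf, p = 0.
welch_rows <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1L)
  vb <- rowSums((b - mb)^2) / (nb - 1L)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1L) + (vb / nb)^2 / (nb - 1L))
  zero_var <- se2 == 0
  equal <- zero_var & (ma == mb)
  t[equal] <- 0
  df[equal] <- na + nb - 2L
  t[zero_var & !equal] <- sign(ma - mb)[zero_var & !equal] * Inf
  df[zero_var & !equal] <- na + nb - 2L
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

#' Welch's two-sided unequal-variance t-test
#'
#' `t = (mean_a - mean_b) / sqrt(s2_a/n_a + s2_b/n_b)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value from the t
#' distribution. If both groups are constant and equal the gene is trivially
#' non-differential (`t = 0`, `p = 1`); if both are constant but different the
#' standardization is undefined and an error is raised.
#'
#' @param group_a,group_b Numeric vectors, each length >= 2.
#' @return List with `t`, `df`, `p`.
#' @export
welch_t_test <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  res <- welch_rows(matrix(group_a, nrow = 1L), matrix(group_b, nrow = 1L))
  if (is.infinite(res$t)) {
    stop("both groups constant with different means: t undefined",
         call. = FALSE)
  }
  list(t = res$t, df = res$df, p = res$p)
}

#' False-discovery-rate adjusted q-values
#'
#' Benjamini-Hochberg step-up adjustment by default. A Storey-style variant
#' scales the BH values by an estimate of the null proportion
#' `pi0 = min(1, mean(p > 0.5) / 0.5)`; it is offered because pi0-adaptive
#' q-values are common in expression screens, but pi0 estimation is unstable
#' for small test families, hence not the default.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @param method `"BH"` (default) or `"storey"`.
#' @return Numeric vector of q-values, monotone in `p_values`.
#' @export
qvalues <- function(p_values, method = c("BH", "storey")) {
  method <- match.arg(method)
  if (any(p_values < 0 | p_values > 1 | !is.finite(p_values))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  q <- stats::p.adjust(p_values, method = "BH")
  if (method == "storey") {
    pi0 <- min(1, mean(p_values > 0.5) / 0.5)
    if (pi0 <= 0) pi0 <- 1 / length(p_values)  # every p small: keep q positive
    q <- pmin(q * pi0, 1)
  }
  q
}

#' Pairwise differential expression between cell-type classes
#'
#' For every unordered pair of classes, each gene is tested with Welch's
#' two-sided unequal-variance t-test on the replicate columns; q-values are
#' computed within that pair's family of tests. Genes with
#' `q < q_cutoff` are retained and ranked by descending absolute log2 fold
#' change of the class means (with a pseudocount of `pseudocount` on the
#' linear scale); rank ties break by gene ID for determinism.
#'
#' @param matrix Numeric matrix, genes x samples (linear-scale, typically
#'   quantile-normalized).
#' @param annotation Named character vector (sample -> class); every class
#'   needs >= 2 replicates.
#' @param q_cutoff Significance cutoff on the q-value, strict (default 0.3).
#' @param pseudocount Added to both class means before the log-ratio
#'   (default 1), guarding against division by zero on dim genes.
#' @param q_method Passed to [qvalues()].
#' @return A `pairwise_deg` data frame with columns `class_a`, `class_b`,
#'   `gene`, `t`, `df`, `p`, `q`, `log2_fc`, `rank`, one block per pair,
#'   significant genes only.
#' @export
pairwise_deg <- function(matrix, annotation, q_cutoff = 0.3, pseudocount = 1,
                         q_method = "BH") {
  validate_expression_matrix(matrix)
  validate_annotation(matrix, annotation)
  census <- class_census(annotation)
  small <- names(census)[census < 2L]
  if (length(small) > 0L) {
    stop("pairwise testing impossible: class(es) with < 2 replicates: ",
         paste(small, collapse = ", "), call. = FALSE)
  }
  if (any(census == 2L)) {
    warning("class(es) with only 2 replicates (low power): ",
            paste(names(census)[census == 2L], collapse = ", "))
  }
  classes <- sort(names(census))
  blocks <- list()
  for (i in seq_len(length(classes) - 1L)) {
    for (j in seq(i + 1L, length(classes))) {
      ca <- classes[i]; cb <- classes[j]
      a <- matrix[, names(annotation)[annotation == ca], drop = FALSE]
      b <- matrix[, names(annotation)[annotation == cb], drop = FALSE]
      w <- welch_rows(a, b)
      q <- qvalues(w$p, method = q_method)
      lfc <- log2((rowMeans(a) + pseudocount) / (rowMeans(b) + pseudocount))
      keep <- which(q < q_cutoff)
      if (length(keep) == 0L) next
      ord <- keep[order(-abs(lfc[keep]), rownames(matrix)[keep])]
      blocks[[length(blocks) + 1L]] <- data.frame(
        class_a = ca, class_b = cb, gene = rownames(matrix)[ord],
        t = w$t[ord], df = w$df[ord], p = w$p[ord], q = q[ord],
        log2_fc = lfc[ord], rank = seq_along(ord),
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  out <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(class_a = character(), class_b = character(),
               gene = character(), t = numeric(), df = numeric(),
               p = numeric(), q = numeric(), log2_fc = numeric(),
               rank = integer())
  structure(out, class = c("pairwise_deg", "data.frame"),
            classes = classes, q_cutoff = q_cutoff)
}

#' Union of each pair's top-G ranked differential genes
#'
#' Pairs with fewer than `G` significant genes contribute all of theirs. The
#' union is deduplicated and sorted by gene ID for a deterministic gene list.
#'
#' @param deg A `pairwise_deg` table from [pairwise_deg()].
#' @param G Number of top-ranked genes taken from each pair (>= 1).
#' @return Character vector of gene IDs.
#' @export
top_g_union <- function(deg, G) {
  if (G < 1L) stop("G must be >= 1", call. = FALSE)
  if (nrow(deg) == 0L) {
    stop("empty differential-expression table", call. = FALSE)
  }
  sort(unique(deg$gene[deg$rank <= G]))
}

#' Build a signature matrix from a gene list
#'
#' `S[g, k]` is the mean expression of gene `g` over the replicate samples of
#' class `k`. Columns are ordered by class label, rows by the supplied gene
#' list.
#'
#' @param matrix Numeric matrix, genes x samples.
#' @param annotation Named character vector (sample -> class).
#' @param gene_list Genes to keep; all must be present in the matrix.
#' @return Numeric matrix, genes x classes.
#' @export
build_signature <- function(matrix, annotation, gene_list) {
  missing <- setdiff(gene_list, rownames(matrix))
  if (length(missing) > 0L) {
    stop("gene(s) absent from matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  validate_annotation(matrix, annotation)
  classes <- sort(unique(annotation))
  S <- vapply(classes, function(cl) {
    rowMeans(matrix[gene_list, names(annotation)[annotation == cl],
                    drop = FALSE])
  }, numeric(length(gene_list)))
  S <- matrix(S, nrow = length(gene_list),
              dimnames = list(gene_list, classes))
  S
}

#' 2-norm condition number of a signature matrix
#'
#' `kappa_2 = sigma_max / sigma_min` from the singular values. A lower
#' condition number means the linear system `M ~ S F` is better posed, which
#' is the criterion used to size the signature gene list.
#'
#' @param S Numeric matrix with at least as many rows (genes) as columns
#'   (classes).
#' @return Positive real; `Inf` (with a warning) for a rank-deficient matrix.
#' @export
condition_number <- function(S) {
  if (nrow(S) < ncol(S)) {
    stop("signature must have at least as many genes as classes",
         call. = FALSE)
  }
  d <- svd(S, nu = 0, nv = 0)$d
  if (min(d) <= max(d) * .Machine$double.eps * max(dim(S))) {
    warning("rank-deficient signature matrix: condition number infinite")
    return(Inf)
  }
  max(d) / min(d)
}

#' Choose the signature gene-list size G by condition-number minimization
#'
#' For each `G` in `[g_min, g_max]` the top-G union list is formed, the
#' corresponding signature matrix built (on raw linear-scale class means,
#' before any standardization), and its condition number recorded. The chosen
#' `G` attains the minimum condition number; ties go to the smallest `G`.
#' Values of `G` whose union list has fewer genes than classes are skipped.
#'
#' @param deg A `pairwise_deg` table.
#' @param matrix Numeric matrix, genes x samples, same one used for testing.
#' @param annotation Named character vector (sample -> class).
#' @param g_min,g_max Scan range for G (defaults 5 and 100).
#' @return A `g_selection`: list with `trace` (data frame of G, union-list
#'   size, condition number), `chosen_G`, `condition_number`, `gene_list` and
#'   the chosen `signature` matrix.
#' @export
select_g <- function(deg, matrix, annotation, g_min = 5L, g_max = 100L) {
  if (nrow(deg) == 0L) stop("empty differential-expression table", call. = FALSE)
  if (g_min < 1L || g_max < g_min) stop("invalid G range", call. = FALSE)
  r <- length(unique(annotation))
  gs <- seq.int(g_min, g_max)
  trace <- data.frame(G = gs, union_size = NA_integer_, kappa = NA_real_)
  for (k in seq_along(gs)) {
    genes <- top_g_union(deg, gs[k])
    trace$union_size[k] <- length(genes)
    if (length(genes) < r) next  # underdetermined; skipped
    S <- build_signature(matrix, annotation, genes)
    trace$kappa[k] <- condition_number(S)
  }
  if (all(is.na(trace$kappa))) {
    stop("no G in [", g_min, ", ", g_max, "] yields at least ", r, " genes",
         call. = FALSE)
  }
  best <- which.min(trace$kappa)  # first index: ties resolve to smallest G
  gene_list <- top_g_union(deg, trace$G[best])
  structure(list(trace = trace,
                 chosen_G = trace$G[best],
                 condition_number = trace$kappa[best],
                 gene_list = gene_list,
                 signature = build_signature(matrix, annotation, gene_list)),
            class = "g_selection")
}

#' @export
print.g_selection <- function(x, ...) {
  cat("Signature gene-list selection: G =", x$chosen_G,
      "| condition number =", signif(x$condition_number, 4),
      "|", length(x$gene_list), "signature genes\n")
  invisible(x)
}

#' Build a signature matrix end-to-end
#'
#' Convenience wrapper over the whole construction: quantile normalization of
#' the reference arrays, black-list filtering, pairwise Welch testing with
#' FDR control, and condition-number-driven sizing of the top-G union list.
#' Outlier removal and class merging are deliberate user actions taken before
#' calling this (see [detect_outliers()], [drop_samples()],
#' [merge_classes()]).
#'
#' @param matrix Reference expression matrix, genes x samples, linear scale.
#' @param annotation Named character vector (sample -> class), >= 2 replicates
#'   per class.
#' @param blacklists Optional character vector or list of vectors of genes to
#'   exclude before testing.
#' @param q_cutoff,g_min,g_max,pseudocount,q_method See [pairwise_deg()] and
#'   [select_g()].
#' @param normalize Quantile-normalize the references first (default `TRUE`).
#' @return A `g_selection` (see [select_g()]) with an extra `deg` element
#'   holding the pairwise differential-expression table.
#' @export
build_signature_matrix <- function(matrix, annotation, blacklists = NULL,
                                   q_cutoff = 0.3, g_min = 5L, g_max = 100L,
                                   pseudocount = 1, q_method = "BH",
                                   normalize = TRUE) {
  validate_annotation(matrix, annotation, require_replicates = TRUE)
  x <- if (normalize) quantile_normalize(matrix) else matrix
  if (!is.null(blacklists)) {
    x <- apply_blacklists(x, blacklists)
    if (nrow(x) == 0L) {
      stop("all genes black-listed; nothing left to select from",
           call. = FALSE)
    }
  }
  deg <- pairwise_deg(x, annotation, q_cutoff = q_cutoff,
                      pseudocount = pseudocount, q_method = q_method)
  sel <- select_g(deg, x, annotation, g_min = g_min, g_max = g_max)
  sel$deg <- deg
  sel
}
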