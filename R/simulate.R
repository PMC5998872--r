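#' Specification for the synthetic reference/mixture generator
#'
#' The generator emulates a replicated reference panel of cell types with
#' planted marker genes, plus bulk mixtures formed as proportion-weighted
#' sums of the cell-type profiles with known ground truth. Defaults describe
#' a moderately sized immune panel: 8 cell types profiled over 1000 genes
#' with 5 markers per type, 3 replicate arrays per type with 1% log-scale
#' replicate noise, and 50 mixtures with flat-Dirichlet compositions.
#'
#' @param n_classes Number of cell types r.
#' @param n_genes Number of genes g.
#' @param markers_per_class Planted marker genes per class (disjoint sets).
#' @param replicates_per_class Reference replicates per class.
#' @param marker_effect Fold elevation of a marker in its own class
#'   (default 10, a typical marker-gene contrast).
#' @param noise_sd Replicate/mixture noise level. For the default
#'   `"lognormal"` model this is the sd on the log2 scale (multiplicative
#'   noise, matching microarray intensity behavior); for `"gaussian"` it is
#'   an additive sd in intensity units.
#' @param noise_model `"lognormal"` (default) or `"gaussian"`.
#' @param dirichlet_alpha Symmetric Dirichlet concentration for mixture
#'   compositions (default 1 = flat).
#' @param n_mixtures Number of mixture samples.
#' @param seed Integer seed fixing all randomness.
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(n_classes = 8L, n_genes = 1000L,
                           markers_per_class = 5L, replicates_per_class = 3L,
                           marker_effect = 10, noise_sd = 0.01,
                           noise_model = c("lognormal", "gaussian"),
                           dirichlet_alpha = 1, n_mixtures = 50L,
                           seed = 1L) {
  noise_model <- match.arg(noise_model)
  spec <- list(n_classes = as.integer(n_classes),
               n_genes = as.integer(n_genes),
               markers_per_class = as.integer(markers_per_class),
               replicates_per_class = as.integer(replicates_per_class),
               marker_effect = marker_effect, noise_sd = noise_sd,
               noise_model = noise_model,
               dirichlet_alpha = dirichlet_alpha,
               n_mixtures = as.integer(n_mixtures), seed = as.integer(seed))
  with(spec, {
    if (n_classes < 1L || n_genes < 1L || markers_per_class < 1L ||
        replicates_per_class < 1L || n_mixtures < 1L) {
      stop("all counts must be >= 1", call. = FALSE)
    }
    if (markers_per_class * n_classes > n_genes) {
      stop("more planted markers than genes", call. = FALSE)
    }
    if (noise_sd < 0 || marker_effect <= 0 || dirichlet_alpha <= 0) {
      stop("noise_sd must be >= 0; marker_effect and dirichlet_alpha > 0",
           call. = FALSE)
    }
  })
  structure(spec, class = "generator_spec")
}

# Positive right-skewed base intensities, shared by all classes so that
# non-marker genes are not differential between classes. Background genes
# span the full microarray dynamic range (log2 sd 2); marker genes sit in a
# narrower mid-intensity band (log2 sd 1) so that the cell-type contrast,
# not base heterogeneity, dominates the signature rows — mimicking lineage
# markers that are moderately expressed in their own type and near
# background elsewhere.
draw_base_profile <- function(g, marker_pos) {
  base <- 2^stats::rnorm(g, mean = 6, sd = 2)
  base[marker_pos] <- 2^stats::rnorm(length(marker_pos), mean = 6, sd = 1)
  base
}

apply_noise <- function(x, spec) {
  e <- matrix(stats::rnorm(length(x)), nrow = nrow(x))  # always consume draws
  if (spec$noise_model == "lognormal") x * 2^(e * spec$noise_sd)
  else pmax(x + e * spec$noise_sd, 0)
}

#' Generate replicated synthetic reference profiles
#'
#' Each class shares one common base profile with its own disjoint marker
#' set elevated `marker_effect`-fold; replicates are the class profile times
#' multiplicative log-normal noise (or plus Gaussian noise). Deterministic
#' under the spec's seed.
#'
#' @param spec A [generator_spec()].
#' @return A `synthetic_references` list: `expression` (genes x replicate
#'   samples), `annotation` (sample -> class), `base_profiles` (genes x
#'   classes, the noise-free class means), `marker_genes` (list of marker IDs
#'   per class) and the `spec`.
#' @export
generate_references <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)
  g <- spec$n_genes; r <- spec$n_classes; m <- spec$markers_per_class
  gene_ids <- sprintf("G%05d", seq_len(g))
  class_ids <- sprintf("CT%02d", seq_len(r))
  marker_pos <- sample.int(g, r * m)
  base <- draw_base_profile(g, marker_pos)
  marker_idx <- split(marker_pos, rep(seq_len(r), each = m))
  profiles <- matrix(base, g, r, dimnames = list(gene_ids, class_ids))
  for (k in seq_len(r)) {
    profiles[marker_idx[[k]], k] <- profiles[marker_idx[[k]], k] *
      spec$marker_effect
  }
  reps <- spec$replicates_per_class
  sample_ids <- as.vector(vapply(class_ids, function(cl)
    paste0(cl, "_rep", seq_len(reps)), character(reps)))
  expr <- matrix(NA_real_, g, r * reps,
                 dimnames = list(gene_ids, sample_ids))
  for (k in seq_len(r)) {
    cols <- (k - 1L) * reps + seq_len(reps)
    expr[, cols] <- apply_noise(
      matrix(profiles[, k], g, reps), spec)
  }
  annotation <- stats::setNames(rep(class_ids, each = reps), sample_ids)
  structure(list(expression = expr, annotation = annotation,
                 base_profiles = profiles,
                 marker_genes = stats::setNames(
                   lapply(marker_idx, function(i) gene_ids[i]), class_ids),
                 spec = spec),
            class = "synthetic_references")
}

#' Generate bulk mixtures with known ground-truth proportions
#'
#' Compositions are drawn row-wise from a symmetric Dirichlet; each mixture
#' column is the proportion-weighted sum of the noise-free class profiles
#' plus noise. At `noise_sd = 0` the mixture model holds exactly:
#' `M[, j] == base_profiles %*% F[j, ]`.
#'
#' @param references A `synthetic_references` from [generate_references()].
#' @param spec Optional [generator_spec()]; defaults to the one embedded in
#'   `references`.
#' @param proportions Optional mixtures x classes matrix of fixed
#'   compositions (rows summing to 1) overriding the Dirichlet draw, e.g.
#'   one-hot rows for pure-type mixtures.
#' @return A `synthetic_mixtures` list: `expression` (genes x mixtures),
#'   `truth` (mixtures x classes proportion matrix) and the `spec`.
#' @export
generate_mixtures <- function(references, spec = references$spec,
                              proportions = NULL) {
  stopifnot(inherits(references, "synthetic_references"))
  set.seed(spec$seed + 1L)
  S <- references$base_profiles
  r <- ncol(S)
  if (is.null(proportions)) {
    gam <- matrix(stats::rgamma(spec$n_mixtures * r,
                                shape = spec$dirichlet_alpha),
                  spec$n_mixtures, r)
    F_true <- gam / rowSums(gam)
  } else {
    F_true <- as.matrix(proportions)
    if (ncol(F_true) != r || any(F_true < 0) ||
        any(abs(rowSums(F_true) - 1) > 1e-9)) {
      stop("proportions must be mixtures x ", r,
           " with non-negative rows summing to 1", call. = FALSE)
    }
  }
  colnames(F_true) <- colnames(S)
  rownames(F_true) <- sprintf("MIX%03d", seq_len(nrow(F_true)))
  M <- S %*% t(F_true)
  colnames(M) <- rownames(F_true)
  M <- apply_noise(M, spec)
  structure(list(expression = M, truth = F_true, spec = spec),
            class = "synthetic_mixtures")
}

#' Replace one reference sample with a profile from another class
#'
#' Builds a planted-outlier fixture: the named sample's column becomes a
#' noisy copy of the donor class's base profile while its annotation keeps
#' the original (now wrong) label, so QC should flag it.
#'
#' @param references A `synthetic_references`.
#' @param sample_id Reference sample to overwrite.
#' @param donor_class Class whose base profile is planted.
#' @param noise_sd Optional noise level for the planted copy (defaults to
#'   the spec's `noise_sd`).
#' @return The modified `synthetic_references` (dimensions unchanged).
#' @export
plant_outlier <- function(references, sample_id, donor_class,
                          noise_sd = references$spec$noise_sd) {
  stopifnot(inherits(references, "synthetic_references"))
  if (!sample_id %in% colnames(references$expression)) {
    stop("unknown sample: ", sample_id, call. = FALSE)
  }
  if (!donor_class %in% colnames(references$base_profiles)) {
    stop("unknown donor class: ", donor_class, call. = FALSE)
  }
  spec2 <- references$spec
  spec2$noise_sd <- noise_sd
  set.seed(spec2$seed + 2L)
  col <- apply_noise(references$base_profiles[, donor_class, drop = FALSE],
                     spec2)
  references$expression[, sample_id] <- col
  references
}
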