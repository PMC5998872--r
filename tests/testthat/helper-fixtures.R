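# Shared in-code fixtures for the test suite.

# Tiny genes x samples matrix with labels.
make_expr <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- genes %||% rownames(m) %||% sprintf("g%02d", seq_len(nrow(m)))
  colnames(m) <- samples %||% colnames(m) %||% sprintf("s%02d", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Write a genes x samples matrix as TSV/CSV the way a user would provide it.
write_fixture_matrix <- function(m, path, sep = "\t",
                                 gene_ids = rownames(m)) {
  lines <- c(paste(c("gene", colnames(m)), collapse = sep),
             vapply(seq_len(nrow(m)), function(i)
               paste(c(gene_ids[i], format(m[i, ], trim = TRUE)),
                     collapse = sep), character(1)))
  writeLines(lines, path)
  path
}

# Small replicated reference panel with unmistakable per-class markers:
# class k's markers sit at `high`, background at `low`, plus tiny jitter so
# variances are nonzero.
make_marker_refs <- function(n_classes = 3, markers_per_class = 2,
                             n_extra_genes = 4, reps = 3,
                             high = 100, low = 1, jitter = 0.01,
                             seed = 42) {
  set.seed(seed)
  g <- n_classes * markers_per_class + n_extra_genes
  genes <- sprintf("g%02d", seq_len(g))
  classes <- LETTERS[seq_len(n_classes)]
  samples <- as.vector(vapply(classes, function(cl)
    paste0(cl, seq_len(reps)), character(reps)))
  base <- rep(low, g)
  m <- matrix(base, g, n_classes * reps, dimnames = list(genes, samples))
  for (k in seq_len(n_classes)) {
    rows <- (k - 1) * markers_per_class + seq_len(markers_per_class)
    m[rows, (k - 1) * reps + seq_len(reps)] <- high
  }
  m <- m * (1 + matrix(stats::rnorm(length(m), 0, jitter), nrow(m)))
  ann <- stats::setNames(rep(classes, each = reps), samples)
  marker_genes <- lapply(seq_len(n_classes), function(k)
    genes[(k - 1) * markers_per_class + seq_len(markers_per_class)])
  names(marker_genes) <- classes
  list(expression = m, annotation = ann, marker_genes = marker_genes)
}

# Brute-force Welch statistics straight from the defining formulas.
welch_oracle <- function(a, b) {
  va <- stats::var(a); vb <- stats::var(b)
  na <- length(a); nb <- length(b)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Step-up BH adjustment from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p, decreasing = TRUE)
  q <- rep(NA_real_, m)
  run_min <- Inf
  for (i in ord) {
    rank_i <- sum(p <= p[i])
    run_min <- min(run_min, p[i] * m / rank_i)
    q[i] <- min(run_min, 1)
  }
  q
}

# Mean-of-order-statistics quantile normalization (no ties).
qn_oracle <- function(x) {
  target <- rowMeans(apply(x, 2, sort))
  out <- apply(x, 2, function(col) target[rank(col)])
  dimnames(out) <- dimnames(x)
  out
}

# nu-SVR primal weights via the LIBSVM dual solved as a QP (kernlab::ipop):
# min 1/2 (a-a*)' K (a-a*) - y'(a-a*)
#   s.t. e'(a-a*) = 0, e'(a+a*) = C*nu*l, 0 <= a_i, a*_i <= C.
nusvr_dual_oracle <- function(X, y, nu, cost = 1) {
  l <- nrow(X)
  K <- X %*% t(X)
  H <- rbind(cbind(K, -K), cbind(-K, K)) + diag(1e-8, 2 * l)
  A <- rbind(c(rep(1, l), rep(-1, l)), rep(1, 2 * l))
  sol <- kernlab::ipop(c = c(-y, y), H = H, A = A,
                       b = c(0, cost * nu * l), r = c(0, 0),
                       l = rep(0, 2 * l), u = rep(cost, 2 * l),
                       sigf = 8, maxiter = 200)
  u <- kernlab::primal(sol)
  as.vector(t(X) %*% (u[1:l] - u[(l + 1):(2 * l)]))
}
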