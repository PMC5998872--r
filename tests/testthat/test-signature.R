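test_that("normal-tissue black list applies strict ES and tissue-fraction rules", {
  es <- matrix(0, 3, 100, dimnames = list(c("in6", "in5", "neg"), NULL))
  es["in6", 1:6] <- 1   # > 0 in 6% of tissues -> listed
  es["in5", 1:5] <- 1   # exactly 5% -> kept (strict >)
  es["neg", ] <- -1     # never above 0 -> kept
  bl <- normal_tissue_blacklist(es)
  expect_identical(as.character(bl), "in6")
  expect_identical(attr(bl, "source"), "normal_tissue")
})

test_that("cancer black list requires strictly exceeding log2 threshold in any line", {
  cc <- matrix(7, 3, 4, dimnames = list(c("hot", "flat", "cold"), NULL))
  cc["hot", 2] <- 7.1
  cc["cold", ] <- 1
  expect_identical(as.character(cancer_blacklist(cc)), "hot")
  empty <- matrix(numeric(), 0, 0)
  expect_length(cancer_blacklist(empty), 0)
})

test_that("apply_blacklists removes listed rows and only those", {
  m <- make_expr(matrix(1:20, 10, 2))
  bl <- structure(rownames(m)[c(1, 5, 9)], source = "user")
  expect_identical(suppressMessages(nrow(apply_blacklists(m, bl))), 7L)
  off <- structure(c("zz1", "zz2"), source = "user")
  expect_identical(suppressMessages(apply_blacklists(m, off)), m)
  all_bl <- structure(rownames(m), source = "user")
  expect_identical(suppressMessages(nrow(apply_blacklists(m, all_bl))), 0L)
})

test_that("Welch test matches hand-derived values and is antisymmetric", {
  res <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)

  res2 <- welch_t_test(c(1, 2), c(3, 5))
  expect_equal(res2$t, -2.2360679, tolerance = 1e-7)
  expect_equal(res2$df, 1.4705882, tolerance = 1e-7)

  res3 <- welch_t_test(c(3, 5), c(1, 2))
  expect_equal(res3$t, -res2$t)
  expect_equal(res3$p, res2$p)

  expect_error(welch_t_test(c(1, 1), c(2, 2)), "constant")
  expect_error(welch_t_test(1, c(2, 3)), "at least 2")
})

test_that("Welch test agrees with stats::t.test and the formula oracle on random fixtures", {
  set.seed(202)
  for (i in 1:100) {
    a <- stats::rnorm(sample(2:8, 1), mean = stats::runif(1, -2, 2),
                      sd = stats::runif(1, 0.5, 3))
    b <- stats::rnorm(sample(2:8, 1), mean = stats::runif(1, -2, 2),
                      sd = stats::runif(1, 0.5, 3))
    got <- welch_t_test(a, b)
    ora <- welch_oracle(a, b)
    ref <- stats::t.test(a, b, var.equal = FALSE)
    expect_lt(abs(got$t - ora$t), 1e-10)
    expect_lt(abs(got$df - ora$df), 1e-10)
    expect_lt(abs(got$p - ora$p), 1e-10)
    expect_lt(abs(got$t - unname(ref$statistic)), 1e-10)
    expect_lt(abs(got$df - unname(ref$parameter)), 1e-10)
  }
})

test_that("BH q-values match the step-up oracle and edge cases", {
  expect_equal(qvalues(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(qvalues(0.2), 0.2)
  expect_equal(qvalues(rep(1, 5)), rep(1, 5))
  set.seed(303)
  for (i in 1:50) {
    p <- stats::runif(sample(1:40, 1))
    q <- qvalues(p)
    expect_equal(q, bh_oracle(p))
    expect_true(all(diff(q[order(p)]) >= -1e-15))  # monotone in p
  }
  expect_error(qvalues(c(0.5, 1.2)), "0, 1")
  # Storey variant never exceeds BH and stays in [0, 1]
  p <- stats::runif(30)
  qs <- qvalues(p, method = "storey")
  expect_true(all(qs <= qvalues(p) + 1e-15))
  expect_true(all(qs >= 0 & qs <= 1))
})

test_that("pairwise DEG detection tests every class pair and ranks by fold change", {
  # noiseless fixture: marker genes differ exactly, non-markers are equal
  fix <- make_marker_refs(n_classes = 3, markers_per_class = 2,
                          n_extra_genes = 4, reps = 3, jitter = 0)
  deg <- suppressWarnings(pairwise_deg(fix$expression, fix$annotation))
  pairs <- unique(deg[, c("class_a", "class_b")])
  expect_identical(nrow(pairs), 3L)  # C(3,2)

  # in pair (A, B) the significant genes are exactly A's and B's markers,
  # with |log2 fold change| descending along the ranks
  block <- deg[deg$class_a == "A" & deg$class_b == "B", ]
  expect_setequal(block$gene, c(fix$marker_genes$A, fix$marker_genes$B))
  expect_true(all(diff(abs(block$log2_fc[order(block$rank)])) <= 1e-12))
  # a lone dominant marker outranks everything in every pair it enters
  solo <- make_marker_refs(n_classes = 3, markers_per_class = 1,
                           n_extra_genes = 4, reps = 3, jitter = 0,
                           high = 1000)
  deg_solo <- suppressWarnings(pairwise_deg(solo$expression,
                                            solo$annotation))
  for (pr in c("B", "C")) {
    blk <- deg_solo[deg_solo$class_a == "A" & deg_solo$class_b == pr, ]
    expect_identical(blk$gene[blk$rank == 1], solo$marker_genes$A)
  }
  # non-marker genes (identical means, zero variance) never reach q < 0.3
  extra <- setdiff(rownames(fix$expression), unlist(fix$marker_genes))
  expect_length(intersect(deg$gene, extra), 0)

  ann_bad <- fix$annotation[fix$annotation != "C" |
                            names(fix$annotation) == "C1"]
  expect_error(suppressWarnings(
    pairwise_deg(fix$expression[, names(ann_bad)], ann_bad)), "C")
})

test_that("top-G union deduplicates, saturates, and grows monotonically", {
  deg <- data.frame(
    class_a = rep(c("A", "A", "B"), each = 2),
    class_b = rep(c("B", "C", "C"), each = 2),
    gene = c("g1", "g2", "g3", "g4", "g5", "g6"),
    rank = rep(1:2, 3))
  expect_length(top_g_union(deg, 2), 6)
  expect_length(top_g_union(deg, 1), 3)
  deg2 <- deg; deg2$gene <- rep(c("g1", "g2"), 3)
  expect_identical(top_g_union(deg2, 2), c("g1", "g2"))
  expect_identical(top_g_union(deg, 50), sort(deg$gene))
  sizes <- vapply(1:5, function(G) length(top_g_union(deg, G)), integer(1))
  expect_true(all(diff(sizes) >= 0))
  expect_error(top_g_union(deg[0, ], 2), "empty")
})

test_that("build_signature averages replicates per class", {
  m <- make_expr(cbind(a1 = c(2, 1), a2 = c(4, 3), b1 = c(10, 8)),
                 genes = c("g1", "g2"))
  ann <- c(a1 = "A", a2 = "A", b1 = "B")
  S <- build_signature(m, ann, c("g1", "g2"))
  expect_equal(unname(S), cbind(c(3, 2), c(10, 8)))
  # permuting replicates changes nothing
  S2 <- build_signature(m[, c(3, 2, 1)], ann, c("g1", "g2"))
  expect_equal(S, S2)
  expect_error(build_signature(m, ann, "missing_gene"), "absent")
})

test_that("condition number equals the singular-value ratio", {
  S <- diag(c(10, 1))
  dimnames(S) <- list(c("g1", "g2"), c("A", "B"))
  expect_equal(condition_number(S), 10)
  expect_equal(condition_number(diag(3)), 1)
  set.seed(404)
  for (i in 1:20) {
    X <- matrix(stats::rnorm(18), 6, 3)
    ev <- sqrt(eigen(crossprod(X), only.values = TRUE)$values)
    expect_lt(abs(condition_number(X) - max(ev) / min(ev)) /
                condition_number(X), 1e-10)
    expect_gte(condition_number(X), 1)
    expect_equal(condition_number(3.7 * X), condition_number(X))
  }
  degenerate <- cbind(c(1, 2, 3), c(2, 4, 6))
  expect_warning(k <- condition_number(degenerate), "rank-deficient")
  expect_identical(k, Inf)
})

test_that("select_g picks the argmin condition number with ties to smallest G", {
  fix <- make_marker_refs(n_classes = 3, markers_per_class = 4,
                          n_extra_genes = 8, reps = 3, jitter = 0)
  deg <- suppressWarnings(pairwise_deg(fix$expression, fix$annotation))
  # low G can yield a rank-deficient (kappa = Inf) matrix, reported by warning
  sel <- suppressWarnings(
    select_g(deg, fix$expression, fix$annotation, g_min = 1, g_max = 10))
  ok <- !is.na(sel$trace$kappa)
  expect_equal(sel$condition_number, min(sel$trace$kappa[ok]))
  expect_equal(sel$chosen_G,
               sel$trace$G[ok][which.min(sel$trace$kappa[ok])])
  # near-orthogonal marker blocks: kappa stays small and the trace
  # saturates once every pair contributes all its markers
  expect_true(all(diff(sel$trace$union_size) >= 0))
  expect_lt(sel$condition_number, 10)
  # significant genes are exactly the planted markers, so a saturated
  # union holds all of them and the chosen list nothing else
  expect_setequal(top_g_union(deg, 10), sort(unlist(fix$marker_genes)))
  expect_true(all(sel$gene_list %in% unlist(fix$marker_genes)))
})

test_that("end-to-end construction recovers planted markers and honors black lists", {
  # two markers per class: every pair's 4 markers fit inside any top-G list
  # with G >= 5, so the chosen list must recover them all
  spec <- generator_spec(n_classes = 4, n_genes = 300, markers_per_class = 2,
                         replicates_per_class = 3, noise_sd = 0.01,
                         n_mixtures = 2, seed = 31)
  refs <- generate_references(spec)
  sel <- suppressWarnings(suppressMessages(
    build_signature_matrix(refs$expression, refs$annotation,
                           g_min = 5, g_max = 40)))
  markers <- unlist(refs$marker_genes)
  expect_gte(mean(markers %in% sel$gene_list), 0.95)

  # a black-listed marker can never reach the final list
  banned <- structure(markers[1:3], source = "user")
  sel2 <- suppressWarnings(suppressMessages(
    build_signature_matrix(refs$expression, refs$annotation,
                           blacklists = banned, g_min = 5, g_max = 40)))
  expect_length(intersect(sel2$gene_list, banned), 0)
})
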