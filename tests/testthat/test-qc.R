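test_that("complete-linkage clustering reproduces hand-computed merge heights", {
  # one gene, three samples at 0, 1, 10: first merge {0,1} at height 1,
  # final merge at complete-linkage height max(9, 10) = 10
  x <- make_expr(matrix(c(0, 1, 10), 1, 3))
  hc <- cluster_samples(x)
  expect_equal(hc$height, c(1, 10))

  # identical columns merge first at height 0
  y <- make_expr(cbind(c(1, 2), c(5, 9), c(1, 2)),
                 samples = c("a", "b", "c"))
  hc2 <- cluster_samples(y)
  expect_equal(hc2$height[1], 0)
  first <- hc2$labels[-hc2$merge[1, ]]
  expect_setequal(first, c("a", "c"))

  # merge heights are non-decreasing
  set.seed(5)
  z <- make_expr(matrix(stats::rnorm(40), 5, 8))
  expect_true(!is.unsorted(cluster_samples(z)$height))
})

test_that("outlier flagging follows the strict more-than-2/3 low-correlation rule", {
  up <- c(1, 2, 3, 4, 5, 6)
  down <- rev(up)
  # class of 3: X anti-correlates with both peers -> 2/2 pairs low -> flagged
  x <- make_expr(cbind(P = up, Q = up + c(0.01, 0, -0.01, 0, 0.01, 0),
                       X = down))
  ann <- c(P = "NK", Q = "NK", X = "NK")
  rep <- detect_outliers(x, ann)
  expect_identical(rep$outliers, "X")
  ev <- rep$evidence
  expect_equal(ev$frac_low[ev$sample_id == "X"], 1)
  expect_false(any(ev$flagged[ev$sample_id != "X"]))

  # identical replicates: all correlations 1, nothing flagged
  y <- make_expr(cbind(up, up, up) + 0.001 * c(1, -1, 2, -2, 1, 0),
                 samples = c("a", "b", "c"))
  expect_length(detect_outliers(y, c(a = "T", b = "T", c = "T"))$outliers, 0)
})

test_that("a sample with exactly 2/3 low pairs is not flagged (strict boundary)", {
  up <- c(1, 2, 3, 4, 5, 6)
  down <- rev(up)
  x <- make_expr(cbind(A = up, X = up + c(0.02, -0.01, 0, 0.01, 0, -0.02),
                       B = down, C = down + c(0, 0.01, -0.01, 0, 0.02, 0)))
  ann <- stats::setNames(rep("M", 4), colnames(x))
  rep <- detect_outliers(x, ann)
  ev <- rep$evidence
  # X: high r to A, low to B and C -> exactly 2 of 3 pairs low
  expect_equal(ev$n_low[ev$sample_id == "X"], 2L)
  expect_false(ev$flagged[ev$sample_id == "X"])
  expect_length(rep$outliers, 0)
})

test_that("outlier flagging is invariant to sample order", {
  set.seed(9)
  fix <- make_marker_refs(n_classes = 3, reps = 4, jitter = 0.3)
  perm <- sample(ncol(fix$expression))
  r1 <- detect_outliers(fix$expression, fix$annotation)
  r2 <- detect_outliers(fix$expression[, perm],
                        fix$annotation[colnames(fix$expression)[perm]])
  expect_setequal(r1$outliers, r2$outliers)
  ev1 <- r1$evidence[order(r1$evidence$sample_id), ]
  ev2 <- r2$evidence[order(r2$evidence$sample_id), ]
  expect_equal(ev1$frac_low, ev2$frac_low)
})

test_that("single-member classes are skipped with a warning", {
  x <- make_expr(matrix(stats::rnorm(12), 3, 4))
  ann <- stats::setNames(c("A", "A", "A", "B"), colnames(x))
  expect_warning(rep <- detect_outliers(x, ann), "single sample")
  expect_false("B" %in% rep$evidence$class)
})

test_that("drop_samples removes columns, updates the census, warns on depletion", {
  fix <- make_marker_refs(n_classes = 2, reps = 3)
  out <- drop_samples(fix$expression, fix$annotation, c("A1", "B2"))
  expect_identical(ncol(out$matrix), 4L)
  expect_identical(class_census(out$annotation), c(A = 2L, B = 2L))

  ident <- drop_samples(fix$expression, fix$annotation, character())
  expect_identical(ident$matrix, fix$expression)

  expect_warning(drop_samples(fix$expression, fix$annotation,
                              c("A1", "A2")), "below 2 replicates")
  expect_error(drop_samples(fix$expression, fix$annotation, "nope"),
               "unknown sample")
})

test_that("merge_classes pools replicate groups and conserves counts", {
  ann <- c(m1 = "mast_resting", m2 = "mast_resting",
           m3 = "mast_activated", m4 = "mast_activated",
           b1 = "B", b2 = "B", b3 = "B")
  merged <- merge_classes(ann, c("mast_resting", "mast_activated"), "mast")
  expect_identical(class_census(merged), c(B = 3L, mast = 4L))
  expect_identical(sum(class_census(merged)), sum(class_census(ann)))

  expect_identical(merge_classes(ann, "B", "B"), ann)
  expect_error(merge_classes(ann, "nope", "x"), "unknown class")

  merged2 <- merge_classes(ann, c("B", "mast_resting"), "pool")
  expect_identical(unname(class_census(merged2)["pool"]), 5L)
})

test_that("a planted cross-class replicate is flagged by the QC screen", {
  spec <- generator_spec(n_classes = 3, n_genes = 30, markers_per_class = 8,
                         replicates_per_class = 4, marker_effect = 50,
                         noise_sd = 0.05, n_mixtures = 2, seed = 21)
  refs <- generate_references(spec)
  planted <- plant_outlier(refs, "CT01_rep2", "CT03")
  x <- quantile_normalize(planted$expression)
  rep <- detect_outliers(x, planted$annotation)
  expect_identical(rep$outliers, "CT01_rep2")

  # planting from the sample's own class leaves it unflagged
  benign <- plant_outlier(refs, "CT01_rep2", "CT01")
  expect_identical(dim(benign$expression), dim(refs$expression))
  rep2 <- detect_outliers(quantile_normalize(benign$expression),
                          benign$annotation)
  expect_false("CT01_rep2" %in% rep2$outliers)
})

test_that("dendrograms export to Newick with all samples as leaves", {
  fix <- make_marker_refs()
  hc <- cluster_samples(fix$expression)
  nwk <- dendrogram_newick(hc)
  tree <- ape::read.tree(text = nwk)
  expect_setequal(tree$tip.label, colnames(fix$expression))
})
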