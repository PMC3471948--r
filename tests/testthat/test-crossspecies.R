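fc_from_means <- function(means, species = "speciesA") {
  compute_fold_changes(dataset_from_means(means, species = species))
}

test_that("ortholog pairing expands many-to-many and reports coverage", {
  ma <- matrix(c(5, 6, 7, 5, 5, 5), ncol = 3, byrow = TRUE,
               dimnames = list(c("mA", "mB"), NULL))
  mb <- matrix(c(5, 5.5, 6, 8, 8, 8), ncol = 3, byrow = TRUE,
               dimnames = list(c("rA", "rB"), NULL))
  fc_a <- fc_from_means(ma)
  fc_b <- fc_from_means(mb, "speciesB")

  p1 <- pair_fold_changes(fc_a, fc_b, ortholog_map("mA", "rA"))
  expect_equal(nrow(p1), 3L)  # one row per comparison
  expect_setequal(p1$comparison, c("B_vs_M", "ICM_vs_B", "ICM_vs_M"))
  expect_equal(p1$fc_a[p1$comparison == "B_vs_M"], 1)
  expect_equal(p1$fc_b[p1$comparison == "B_vs_M"], 0.5)

  p2 <- pair_fold_changes(fc_a, fc_b,
                          ortholog_map(c("mA", "mA"), c("rA", "rB")))
  expect_equal(nrow(p2), 6L)
  expect_equal(sum(p2$gene_a == "mA"), 6L)

  # unmeasured partner dropped + counted, with a warning when nothing pairs
  expect_warning(
    p3 <- pair_fold_changes(fc_a, fc_b, ortholog_map("mA", "rMissing")),
    "no ortholog pair")
  expect_equal(nrow(p3), 0L)
  cov <- attr(p3, "coverage")
  expect_equal(cov$count[cov$metric == "unpaired"], 1L)
  expect_equal(cov$count[cov$metric == "paired"], 0L)

  # one-to-one filter drops shared-gene pairs
  expect_warning(
    p4 <- pair_fold_changes(fc_a, fc_b,
                            ortholog_map(c("mA", "mA", "mB"),
                                         c("rA", "rB", "rB")),
                            one_to_one = TRUE),
    "no ortholog pair")
  expect_equal(nrow(p4), 0L)
})

test_that("pair classification follows the interval heuristics", {
  expect_identical(classify_pair(1.00, 0.95), "similar")   # gap 0.05 < 0.2
  expect_identical(classify_pair(1.0, 0.3), "different")   # gap 0.7, both |FC| > 0.2
  expect_identical(classify_pair(0.5, -0.1), "neither")    # |FC_b| < 0.2
  expect_identical(classify_pair(0.5, 0.2), "neither")     # gap in (0.2, 0.4]
  expect_error(classify_pair(Inf, 0), class = "crossexpr_validation_error")
})

test_that("classification is symmetric in the two species", {
  set.seed(31)
  a <- stats::runif(500, -3, 3)
  b <- stats::runif(500, -3, 3)
  expect_identical(classify_pair(a, b), classify_pair(b, a))
})

test_that("strict inequalities: exact equality is excluded at t_similar = 0", {
  p0 <- classification_params(t_similar = 0, t_different = 0.4)
  expect_identical(classify_pair(1, 1, p0), "neither")
  expect_identical(classify_pair(0.3, 0.3, p0), "neither")
})

test_that("label classes move monotonically with their thresholds", {
  set.seed(77)
  a <- stats::runif(400, -2, 2)
  b <- stats::runif(400, -2, 2)
  l1 <- classify_pair(a, b, classification_params(t_similar = 0.2))
  l2 <- classify_pair(a, b, classification_params(t_similar = 0.5,
                                                  t_different = 0.5))
  expect_true(all(which(l1 == "similar") %in% which(l2 == "similar")))
  d1 <- classify_pair(a, b, classification_params(t_different = 0.4))
  d2 <- classify_pair(a, b, classification_params(t_different = 1.0))
  expect_true(all(which(d2 == "different") %in% which(d1 == "different")))
})

test_that("classify_table preserves row counts and tallies labels", {
  set.seed(13)
  fc_a <- fc_from_means(random_means(40, "m"))
  fc_b <- fc_from_means(random_means(40, "r"), "speciesB")
  map <- ortholog_map(sprintf("m%04d", 1:40), sprintf("r%04d", 1:40))
  paired <- pair_fold_changes(fc_a, fc_b, map)
  lab <- classify_table(paired)
  expect_equal(nrow(lab), nrow(paired))
  counts <- attr(lab, "label_counts")
  for (cmp in unique(lab$comparison)) {
    expect_equal(sum(counts$count[counts$comparison == cmp]),
                 sum(lab$comparison == cmp))
  }
  # row-wise re-check against scalar evaluation
  manual <- mapply(function(x, y) classify_pair(x, y), lab$fc_a, lab$fc_b)
  expect_identical(lab$label, unname(manual))

  expect_warning(
    empty <- pair_fold_changes(fc_a, fc_b, ortholog_map("mX", "rX")),
    "no ortholog pair")
  lab0 <- classify_table(empty)
  expect_equal(nrow(lab0), 0L)
  expect_equal(sum(attr(lab0, "label_counts")$count), 0L)
})

test_that("gene-set restriction partitions the paired table", {
  set.seed(21)
  fc_a <- fc_from_means(random_means(30, "m"))
  fc_b <- fc_from_means(random_means(30, "r"), "speciesB")
  map <- ortholog_map(sprintf("m%04d", 1:30), sprintf("r%04d", 1:30))
  paired <- classify_table(pair_fold_changes(fc_a, fc_b, map))

  only_one <- restrict_to_gene_set(paired, "m0001", map)
  expect_true(all(only_one$gene_a == "m0001"))
  expect_equal(nrow(only_one), 3L)

  none <- restrict_to_gene_set(paired, "not_mapped", map)
  expect_equal(nrow(none), 0L)
  rep <- attr(none, "set_report")
  expect_equal(rep$count[rep$metric == "mapped"], 0L)

  # union over a partition of gene_a recovers the unrestricted table
  parts <- split(unique(paired$gene_a), rep(1:3, length.out = 30))
  rebuilt <- do.call(rbind, lapply(parts, function(p) {
    as.data.frame(restrict_to_gene_set(paired, p, map))
  }))
  rebuilt <- rebuilt[order(rebuilt$comparison, rebuilt$gene_a), ]
  orig <- as.data.frame(paired)[order(paired$comparison, paired$gene_a), ]
  expect_equal(rebuilt, orig, ignore_attr = TRUE)
})

test_that("gene-set summaries match a brute-force tally", {
  set.seed(42)
  fc_a <- fc_from_means(random_means(50, "m"))
  fc_b <- fc_from_means(random_means(50, "r"), "speciesB")
  map <- ortholog_map(sprintf("m%04d", 1:50), sprintf("r%04d", 1:50))
  lab <- classify_table(pair_fold_changes(fc_a, fc_b, map))
  sets <- gene_set_collection(list(
    all = sprintf("m%04d", 1:50),
    some = sprintf("m%04d", sample(50, 15))))
  summ <- gene_set_summary(lab, sets, map)

  # a set covering everything reproduces the global counts
  global <- attr(lab, "label_counts")
  for (cmp in unique(lab$comparison)) {
    row <- summ[summ$set == "all" & summ$comparison == cmp, ]
    expect_equal(row$n_similar,
                 global$count[global$comparison == cmp &
                                global$label == "similar"])
    expect_equal(row$n_different,
                 global$count[global$comparison == cmp &
                                global$label == "different"])
  }
  # brute-force per-set tally
  for (cmp in unique(lab$comparison)) {
    sub <- lab[lab$comparison == cmp & lab$gene_a %in% sets$some, ]
    row <- summ[summ$set == "some" & summ$comparison == cmp, ]
    expect_equal(row$n_similar, sum(sub$label == "similar"))
    expect_equal(row$n_different, sum(sub$label == "different"))
    expect_equal(row$n_neither, sum(sub$label == "neither"))
    want <- sub[sub$label == "different", ]
    want <- want$gene_a[order(-abs(want$fc_a - want$fc_b), want$gene_a)]
    got <- if (nzchar(row$different_genes)) {
      strsplit(row$different_genes, ";")[[1]]
    } else character(0)
    expect_identical(got, unique(want))
  }
})
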