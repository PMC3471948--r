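test_that("simulation is deterministic given the seed", {
  cfg <- simulation_config(n_pairs = 150, seed = 123)
  b1 <- simulate_bundle(cfg)
  b2 <- simulate_bundle(cfg)
  expect_identical(b1$dataset_a$values, b2$dataset_a$values)
  expect_identical(b1$dataset_b$values, b2$dataset_b$values)
  expect_identical(as.data.frame(b1$map), as.data.frame(b2$map))
  expect_identical(b1$truth, b2$truth)
  b3 <- simulate_bundle(simulation_config(n_pairs = 150, seed = 124))
  expect_false(identical(b1$dataset_a$values, b3$dataset_a$values))
})

test_that("config validation rejects inconsistent parameters", {
  expect_error(simulation_config(fractions = c(null = 0.5, concordant = 0.2,
                                               discordant = 0.2,
                                               species_specific = 0.2)),
               "sum to 1", class = "crossexpr_validation_error")
  expect_error(simulation_config(noise_sd = -1),
               class = "crossexpr_validation_error")
  expect_error(simulation_config(unpaired_fraction = 1),
               class = "crossexpr_validation_error")
})

test_that("planted class counts stay within multinomial bounds", {
  b <- simulate_bundle(simulation_config(n_pairs = 2000, seed = 2024))
  # one class draw per pair; truth has one row per comparison and may
  # contain duplicated pairs from many-to-many links
  per_pair <- unique(b$truth[!grepl("_dup$", b$truth$gene_a),
                             c("gene_a", "class")])
  counts <- table(factor(per_pair$class,
                         levels = c("null", "concordant", "discordant",
                                    "species_specific")))
  expected <- c(0.7, 0.1, 0.1, 0.1) * 2000
  for (i in seq_along(expected)) {
    p <- expected[i] / 2000
    lo <- qbinom(0.005, 2000, p)
    hi <- qbinom(0.995, 2000, p)
    expect_gte(counts[i], lo * 0.9)  # map drops ~5% unpaired genes
    expect_lte(counts[i], hi)
  }
})

test_that("stored expected labels equal classify_pair on true fold changes", {
  b <- simulate_bundle(simulation_config(n_pairs = 400, seed = 3))
  recomputed <- classify_pair(b$truth$true_fc_a, b$truth$true_fc_b)
  expect_identical(b$truth$expected_label, recomputed)
  # discordant pairs satisfy the "different" conditions with margin
  disc <- b$truth[b$truth$class == "discordant", ]
  expect_true(all(disc$expected_label == "different"))
  expect_true(all(abs(disc$true_fc_a) > 0.2 & abs(disc$true_fc_b) > 0.2))
  expect_true(all(abs(disc$true_fc_a - disc$true_fc_b) > 0.4))
})

test_that("noise-free simulation is exactly recovered by the pipeline", {
  b <- simulate_bundle(simulation_config(n_pairs = 300, noise_sd = 0,
                                         seed = 17))
  lab <- classify_table(pair_fold_changes(
    compute_fold_changes(b$dataset_a),
    compute_fold_changes(b$dataset_b), b$map))
  rec <- evaluate_recovery(lab, b$truth)
  expect_equal(sum(diag(rec$confusion)), nrow(b$truth))
})

test_that("many-to-many links duplicate a species-B partner", {
  b <- simulate_bundle(simulation_config(n_pairs = 500, seed = 8,
                                         many_to_many_fraction = 0.05))
  dup <- grepl("_dup$", b$map$gene_a)
  expect_gt(sum(dup), 0)
  # every duplicated A gene shares its B partner with the parent pair
  parents <- sub("_dup$", "", b$map$gene_a[dup])
  parent_b <- b$map$gene_b[match(parents, b$map$gene_a)]
  expect_identical(b$map$gene_b[dup], parent_b)
  # the unpaired fraction is measured but missing from the map
  expect_lt(attr(b$map, "n_genes_b"), nrow(b$dataset_b$values))
})

test_that("recovery evaluation handles degenerate label sets and misalignment", {
  b <- simulate_bundle(simulation_config(n_pairs = 100, noise_sd = 0,
                                         seed = 5))
  lab <- classify_table(pair_fold_changes(
    compute_fold_changes(b$dataset_a),
    compute_fold_changes(b$dataset_b), b$map))

  ident <- evaluate_recovery(lab, b$truth)
  expect_true(all(ident$rates$sensitivity[ident$rates$n_true > 0] == 1))

  all_neither <- lab
  all_neither$label <- "neither"
  rec <- evaluate_recovery(all_neither, b$truth)
  sens <- setNames(rec$rates$sensitivity, rec$rates$class)
  expect_equal(unname(sens["similar"]), 0)
  expect_equal(unname(sens["different"]), 0)

  expect_error(evaluate_recovery(lab[-1, ], b$truth),
               "misaligned", class = "crossexpr_validation_error")
})

test_that("different-class sensitivity degrades monotonically with noise", {
  sens_at <- function(noise) {
    b <- simulate_bundle(simulation_config(n_pairs = 600, noise_sd = noise,
                                           seed = 99))
    lab <- classify_table(pair_fold_changes(
      compute_fold_changes(b$dataset_a),
      compute_fold_changes(b$dataset_b), b$map))
    r <- evaluate_recovery(lab, b$truth)$rates
    r$sensitivity[r$class == "different"]
  }
  s <- vapply(c(0.05, 0.3, 0.9), sens_at, numeric(1))
  expect_true(all(diff(s) <= 0))
  expect_gt(s[1], 0.99)
})

test_that("bundles round-trip through the standard file formats", {
  dir <- withr::local_tempdir()
  b <- simulate_bundle(simulation_config(n_pairs = 60, seed = 44))
  write_bundle(b, dir)
  ds <- load_expression(file.path(dir, "expression_a.tsv"),
                        file.path(dir, "samples_a.tsv"))
  expect_equal(ds$values, b$dataset_a$values, tolerance = 1e-5)
  map <- load_ortholog_map(file.path(dir, "ortholog_map.tsv"))
  expect_equal(as.data.frame(map), as.data.frame(b$map),
               ignore_attr = TRUE)
  sets <- load_gene_sets(file.path(dir, "gene_sets.gmt"))
  expect_identical(names(sets), names(b$gene_sets))
  expect_identical(sets$planted_discordant, b$gene_sets$planted_discordant)
})
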