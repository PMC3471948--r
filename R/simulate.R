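#' Simulation configuration
#'
#' Parameters of the synthetic two-species study generator, which
#' emulates the screening design: three cell populations (morula,
#' blastocyst, ICM), a small number of replicate samples per stage, and
#' RMA-like log2 intensities with per-gene baselines, stage effects and
#' replicate noise. Each ortholog pair is planted in one of four
#' classes:
#' * `null` — no stage effect in either species;
#' * `concordant` — identical stage-effect vectors in both species
#'   (magnitude `effect_size`);
#' * `discordant` — stage effects differing between species so that
#'   every comparison's fold-change gap exceeds the `discordant_gap`
#'   and both true fold changes stay away from zero (base effect
#'   `effect_size / 2`);
#' * `species_specific` — effect of magnitude `effect_size` in one
#'   species, none in the other.
#'
#' @param n_pairs Number of ortholog pairs (default 2000).
#' @param fractions Named class fractions summing to 1
#'   (default null 0.7, concordant 0.1, discordant 0.1,
#'   species_specific 0.1).
#' @param effect_size Stage-effect magnitude, log2 units (default 1).
#' @param discordant_gap Cross-species fold-change gap for discordant
#'   pairs, log2 units (default 1).
#' @param noise_sd Per-replicate Gaussian noise sd, log2 units
#'   (default 0.15; 0 gives the noise-free limit).
#' @param n_replicates Replicates per stage (default 2, as in the
#'   study design).
#' @param baseline_mean,baseline_sd Per-gene baseline distribution on
#'   the log2 scale (defaults 8 and 2, typical of RMA summaries).
#' @param unpaired_fraction Fraction of gene pairs measured but left
#'   out of the ortholog map (default 0.05).
#' @param many_to_many_fraction Fraction of mapped pairs that receive
#'   an extra duplicated species-A partner (default 0.02).
#' @param seed Integer seed driving all randomness.
#' @return List of class `SimulationConfig`.
#' @export
simulation_config <- function(n_pairs = 2000,
                              fractions = c(null = 0.7, concordant = 0.1,
                                            discordant = 0.1,
                                            species_specific = 0.1),
                              effect_size = 1.0,
                              discordant_gap = 1.0,
                              noise_sd = 0.15,
                              n_replicates = 2,
                              baseline_mean = 8.0,
                              baseline_sd = 2.0,
                              unpaired_fraction = 0.05,
                              many_to_many_fraction = 0.02,
                              seed = 1L) {
  classes <- c("null", "concordant", "discordant", "species_specific")
  if (!is.numeric(fractions) || !setequal(names(fractions), classes)) {
    cx_validation_error(sprintf("fractions must be named: %s",
                                paste(classes, collapse = ", ")))
  }
  fractions <- fractions[classes]
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-9) {
    cx_validation_error("class fractions must be non-negative and sum to 1")
  }
  if (n_pairs < 1 || n_replicates < 1) {
    cx_validation_error("n_pairs and n_replicates must be positive")
  }
  if (effect_size <= 0 || discordant_gap <= 0) {
    cx_validation_error("effect_size and discordant_gap must be positive")
  }
  if (noise_sd < 0 || baseline_sd < 0) {
    cx_validation_error("noise_sd and baseline_sd must be >= 0")
  }
  if (unpaired_fraction < 0 || unpaired_fraction >= 1 ||
      many_to_many_fraction < 0 || many_to_many_fraction >= 1) {
    cx_validation_error("unpaired/many_to_many fractions must be in [0, 1)")
  }
  structure(list(n_pairs = as.integer(n_pairs), fractions = fractions,
                 effect_size = effect_size, discordant_gap = discordant_gap,
                 noise_sd = noise_sd, n_replicates = as.integer(n_replicates),
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 unpaired_fraction = unpaired_fraction,
                 many_to_many_fraction = many_to_many_fraction,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

## Stage-effect vector (morula, blastocyst, ICM) per class and species.
## Fold changes derive as B - M, ICM - B, ICM - M, so the planted
## effects control all three comparisons jointly (additivity).
sim_effects <- function(class, cfg) {
  es <- cfg$effect_size
  switch(class,
    null = list(a = c(0, 0, 0), b = c(0, 0, 0)),
    concordant = {
      d <- es * sample(c(-1, 1), 2, replace = TRUE)
      e <- c(0, d[1], d[1] + d[2])
      list(a = e, b = e)
    },
    discordant = {
      # base effect es/2 in A; B shifted by the gap g in the same
      # direction: per-comparison gaps (g, g, 2g), all > t_different,
      # and every true |FC| >= es/2 > t_min at defaults.
      s <- es / 2
      g <- cfg$discordant_gap
      sgn <- sample(c(-1, 1), 1)
      list(a = sgn * c(0, s, 2 * s), b = sgn * c(0, s + g, 2 * (s + g)))
    },
    species_specific = {
      d <- es * sample(c(-1, 1), 2, replace = TRUE)
      e <- c(0, d[1], d[1] + d[2])
      if (sample(c(TRUE, FALSE), 1)) list(a = e, b = c(0, 0, 0))
      else list(a = c(0, 0, 0), b = e)
    })
}

effects_to_fc <- function(e) {
  c(B_vs_M = e[2] - e[1], ICM_vs_B = e[3] - e[2], ICM_vs_M = e[3] - e[1])
}

sim_matrix <- function(baselines, effects, n_rep, noise_sd) {
  n_gene <- length(baselines)
  stages <- rep(CX_STAGES, each = n_rep)
  reps <- rep(seq_len(n_rep), times = 3)
  abbr <- c(morula = "M", blastocyst = "B", ICM = "ICM")
  sample_ids <- paste0(abbr[stages], reps)
  truth_mat <- baselines +
    do.call(cbind, lapply(seq_along(stages), function(j) {
      vapply(effects, function(e) e[match(stages[j], CX_STAGES)], numeric(1))
    }))
  noise <- matrix(stats::rnorm(n_gene * length(stages), 0, noise_sd),
                  nrow = n_gene)
  values <- truth_mat + noise
  dimnames(values) <- list(names(baselines), sample_ids)
  list(values = values,
       samples = data.frame(sample_id = sample_ids, stage = stages,
                            replicate = reps, stringsAsFactors = FALSE))
}

#' Simulate a complete two-species study bundle
#'
#' Generates the two expression datasets, the ortholog map, two bundled
#' gene sets (one enriched in discordant pairs, one random) and the
#' ground-truth table. Expected labels are computed by [classify_pair()]
#' on the noise-free fold changes, so truth is unambiguous and the
#' noise-free limit (`noise_sd = 0`) is exactly recoverable.
#'
#' @param config A [simulation_config()].
#' @param params [classification_params()] used for the expected labels.
#' @return List of class `SimulatedBundle` with elements `dataset_a`,
#'   `dataset_b`, `map`, `gene_sets`, `truth`, `config`.
#' @export
simulate_bundle <- function(config = simulation_config(),
                            params = classification_params()) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  n <- config$n_pairs
  classes <- sample(names(config$fractions), n, replace = TRUE,
                    prob = config$fractions)
  ids_a <- sprintf("gA%05d", seq_len(n))
  ids_b <- sprintf("gB%05d", seq_len(n))
  baselines <- stats::rnorm(n, config$baseline_mean, config$baseline_sd)

  eff <- lapply(classes, sim_effects, cfg = config)
  eff_a <- lapply(eff, `[[`, "a")
  eff_b <- lapply(eff, `[[`, "b")

  # ortholog map: drop the unpaired fraction, then duplicate species-A
  # partners for the many-to-many fraction (same truth class)
  n_unpaired <- round(config$unpaired_fraction * n)
  unpaired <- if (n_unpaired > 0) sample(n, n_unpaired) else integer(0)
  mapped <- setdiff(seq_len(n), unpaired)
  n_m2m <- round(config$many_to_many_fraction * n)
  m2m <- if (n_m2m > 0 && length(mapped)) {
    sample(mapped, min(n_m2m, length(mapped)))
  } else integer(0)
  ids_a_dup <- if (length(m2m)) sprintf("gA%05d_dup", m2m) else character(0)

  all_ids_a <- c(ids_a, ids_a_dup)
  baselines_a <- stats::setNames(c(baselines, baselines[m2m]), all_ids_a)
  effects_a <- c(eff_a, eff_a[m2m])
  baselines_b <- stats::setNames(baselines, ids_b)

  ma <- sim_matrix(baselines_a, effects_a, config$n_replicates,
                   config$noise_sd)
  mb <- sim_matrix(baselines_b, eff_b, config$n_replicates,
                   config$noise_sd)
  dataset_a <- expression_dataset("speciesA", ma$values, ma$samples)
  dataset_b <- expression_dataset("speciesB", mb$values, mb$samples)

  map <- ortholog_map(c(ids_a[mapped], ids_a_dup),
                      c(ids_b[mapped], ids_b[m2m]))

  # ground truth for every mapped pair x comparison
  pair_a <- c(ids_a[mapped], ids_a_dup)
  pair_b <- c(ids_b[mapped], ids_b[m2m])
  pair_idx <- c(mapped, m2m)
  truth_rows <- lapply(seq_along(pair_idx), function(k) {
    i <- pair_idx[k]
    fa <- effects_to_fc(eff_a[[i]])
    fb <- effects_to_fc(eff_b[[i]])
    data.frame(gene_a = pair_a[k], gene_b = pair_b[k],
               comparison = names(fa), class = classes[i],
               true_fc_a = unname(fa), true_fc_b = unname(fb),
               stringsAsFactors = FALSE)
  })
  truth <- do.call(rbind, truth_rows)
  truth$expected_label <- classify_pair(truth$true_fc_a, truth$true_fc_b,
                                        params)
  rownames(truth) <- NULL

  # two bundled gene sets on species-A ids: one loaded with discordant
  # pairs, one a random background draw
  disc_a <- ids_a[intersect(mapped, which(classes == "discordant"))]
  other_a <- setdiff(ids_a[mapped], disc_a)
  set_disc <- c(disc_a[seq_len(min(30, length(disc_a)))],
                other_a[seq_len(min(10, length(other_a)))])
  set_rand <- sample(ids_a[mapped], min(40, length(mapped)))
  sets <- list()
  if (length(set_disc)) sets$planted_discordant <- set_disc
  if (length(set_rand)) sets$random_background <- set_rand
  gene_sets <- gene_set_collection(
    sets, description = rep("synthetic", length(sets)))

  structure(list(dataset_a = dataset_a, dataset_b = dataset_b, map = map,
                 gene_sets = gene_sets, truth = truth, config = config),
            class = "SimulatedBundle")
}

#' Write a simulated bundle to disk in the standard formats
#'
#' @param bundle A [simulate_bundle()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "SimulatedBundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(bundle$dataset_a, file.path(dir, "expression_a.tsv"),
                   file.path(dir, "samples_a.tsv"))
  write_expression(bundle$dataset_b, file.path(dir, "expression_b.tsv"),
                   file.path(dir, "samples_b.tsv"))
  write_table(as.data.frame(bundle$map), file.path(dir, "ortholog_map.tsv"))
  gmt <- vapply(names(bundle$gene_sets), function(nm) {
    paste(c(nm, attr(bundle$gene_sets, "description")[[nm]],
            bundle$gene_sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(gmt, file.path(dir, "gene_sets.gmt"))
  write_table(bundle$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Confusion table and per-class recovery rates
#'
#' Compares pipeline labels against the planted expected labels of a
#' simulation. Tables must cover exactly the same (gene_a, gene_b,
#' comparison) keys.
#'
#' @param labels A [classify_table()] result.
#' @param truth The `truth` table of a [simulate_bundle()].
#' @return List with `confusion` (expected x predicted matrix) and
#'   `rates` (per class: sensitivity, specificity).
#' @export
evaluate_recovery <- function(labels, truth) {
  key <- function(d) paste(d$gene_a, d$gene_b, d$comparison, sep = "\r")
  kl <- key(labels)
  kt <- key(truth)
  if (length(kl) != length(kt) || !setequal(kl, kt) || anyDuplicated(kt)) {
    cx_validation_error(
      "label and truth tables are misaligned on (gene_a, gene_b, comparison)")
  }
  pred <- labels$label[match(kt, kl)]
  expected <- factor(truth$expected_label, levels = CX_LABELS)
  predicted <- factor(pred, levels = CX_LABELS)
  confusion <- table(expected = expected, predicted = predicted)
  rates <- do.call(rbind, lapply(CX_LABELS, function(cl) {
    tp <- confusion[cl, cl]
    pos <- sum(confusion[cl, ])
    tn <- sum(confusion[CX_LABELS != cl, CX_LABELS != cl])
    neg <- sum(confusion[CX_LABELS != cl, ])
    data.frame(class = cl,
               sensitivity = if (pos > 0) tp / pos else NA_real_,
               specificity = if (neg > 0) tn / neg else NA_real_,
               n_true = pos, stringsAsFactors = FALSE)
  }))
  rownames(rates) <- NULL
  list(confusion = confusion, rates = rates)
}
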