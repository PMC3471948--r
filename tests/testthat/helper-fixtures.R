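# Fixture builders shared across test files. All fixtures are built in
# code; noise-free datasets use identical replicates so fold changes
# are exact.

# Dataset from a genes x 3 matrix of stage means (morula, blastocyst,
# ICM); each stage gets n_rep replicates equal to the mean plus
# optional per-replicate offsets.
dataset_from_means <- function(means, species = "speciesA", n_rep = 2,
                               offsets = NULL) {
  stopifnot(ncol(means) == 3)
  stages <- rep(c("morula", "blastocyst", "ICM"), each = n_rep)
  reps <- rep(seq_len(n_rep), times = 3)
  ids <- paste0(c(morula = "M", blastocyst = "B", ICM = "ICM")[stages], reps)
  vals <- means[, rep(1:3, each = n_rep), drop = FALSE]
  if (!is.null(offsets)) vals <- vals + offsets
  dimnames(vals) <- list(rownames(means), ids)
  expression_dataset(species, vals,
                     data.frame(sample_id = ids, stage = stages,
                                replicate = reps))
}

random_means <- function(n_genes, prefix = "g") {
  m <- matrix(stats::rnorm(n_genes * 3, 8, 2), ncol = 3)
  rownames(m) <- sprintf("%s%04d", prefix, seq_len(n_genes))
  m
}

# Small two-species fixture with hand-chosen fold changes, written to
# files under `dir` when requested.
tiny_expression_files <- function(dir) {
  means <- matrix(c(5.0, 6.2, 8.0,
                    7.0, 7.0, 7.0,
                    9.0, 8.0, 6.5), ncol = 3, byrow = TRUE)
  rownames(means) <- c("g1", "g2", "g3")
  ds <- dataset_from_means(means, species = "mouse",
                           offsets = matrix(c(-0.2, 0.2), nrow = 3,
                                            ncol = 6, byrow = TRUE))
  write_expression(ds, file.path(dir, "expr.tsv"),
                   file.path(dir, "sheet.tsv"))
  ds
}

# Planted configuration whose three top-20 lists share exactly one
# gene: one globally dominant gene plus three groups of 19 genes with
# graded fold-change magnitudes (additivity forces every large gene to
# be large in at least two comparisons, so magnitudes are staggered so
# each group tops exactly one list).
planted_topn_dataset <- function(n_group = 19, n_filler = 42) {
  i <- seq_len(n_group) / 100
  e_shared <- c(0, 10, 20)
  e_g1 <- cbind(0, 3 + i, 0)            # |FC|: BM 3.x, IB 3.x, IM 0
  e_g2 <- cbind(0, 0, 4 + i)            # BM 0,   IB 4.x, IM 4.x
  e_g3 <- cbind(0, 2.5 + i, 6 + 2 * i)  # BM 2.5x, IB 3.5x, IM 6.x
  f <- seq_len(n_filler) / 1000
  e_fill <- cbind(0, f, 2 * f)
  effects <- rbind(e_shared, e_g1, e_g2, e_g3, e_fill)
  rownames(effects) <- c("shared",
                         sprintf("bm%03d", seq_len(n_group)),
                         sprintf("ib%03d", seq_len(n_group)),
                         sprintf("im%03d", seq_len(n_group)),
                         sprintf("fill%03d", seq_len(n_filler)))
  dataset_from_means(8 + effects)
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
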