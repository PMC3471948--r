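## End-to-end orchestration: load -> fold changes per species ->
## threshold selections and Venn overlaps -> ortholog pairing and
## pattern classification -> gene-set summaries -> figures, with a
## machine-readable run manifest.

CX_CONFIG_KEYS <- c("expression_a", "samples_a", "expression_b", "samples_b",
                    "ortholog_map", "gene_sets", "out_dir", "thresholds",
                    "t_similar", "t_different", "t_min", "top_n",
                    "one_to_one", "highlight", "seed", "log_level",
                    "write_images")

#' Build a pipeline run configuration
#'
#' Defaults are the parameters of the screening design: selection
#' thresholds 1.5 and 3 (log2), pattern thresholds 0.2 / 0.4 / 0.2 and
#' top-N 20 for the heatmap.
#'
#' @param expression_a,samples_a,expression_b,samples_b,ortholog_map
#'   Input file paths ([load_expression()], [load_ortholog_map()]).
#' @param out_dir Output directory (created if missing).
#' @param gene_sets Optional GMT path.
#' @param thresholds Numeric vector of selection thresholds.
#' @param t_similar,t_different,t_min Classification thresholds.
#' @param top_n Genes per comparison for the heatmap union.
#' @param one_to_one Restrict the ortholog map to one-to-one pairs?
#' @param highlight Gene_a identifiers to annotate on scatterplots.
#' @param seed Seed for any stochastic step.
#' @param log_level `"info"` or `"quiet"`.
#' @param write_images Write PNG figures (default `TRUE`)?
#' @return List of class `RunConfig`.
#' @export
run_config <- function(expression_a, samples_a, expression_b, samples_b,
                       ortholog_map, out_dir,
                       gene_sets = NULL,
                       thresholds = c(1.5, 3),
                       t_similar = 0.2, t_different = 0.4, t_min = 0.2,
                       top_n = 20, one_to_one = FALSE,
                       highlight = character(0),
                       seed = 1L, log_level = "info",
                       write_images = TRUE) {
  cfg <- list(expression_a = expression_a, samples_a = samples_a,
              expression_b = expression_b, samples_b = samples_b,
              ortholog_map = ortholog_map, gene_sets = gene_sets,
              out_dir = out_dir, thresholds = thresholds,
              t_similar = t_similar, t_different = t_different,
              t_min = t_min, top_n = as.integer(top_n),
              one_to_one = isTRUE(one_to_one),
              highlight = as.character(highlight),
              seed = as.integer(seed), log_level = log_level,
              write_images = isTRUE(write_images))
  violations <- config_violations(cfg, check_files = FALSE)
  if (length(violations)) {
    cx_validation_error(paste(violations, collapse = "; "))
  }
  structure(cfg, class = "RunConfig")
}

config_violations <- function(cfg, check_files = TRUE) {
  v <- character(0)
  for (key in c("expression_a", "samples_a", "expression_b", "samples_b",
                "ortholog_map", "out_dir")) {
    val <- cfg[[key]]
    if (is.null(val) || !is.character(val) || length(val) != 1L ||
        !nzchar(val)) {
      v <- c(v, sprintf("'%s' must be a single non-empty path", key))
    } else if (check_files && key != "out_dir" && !file.exists(val)) {
      v <- c(v, sprintf("'%s' file does not exist: %s", key, val))
    }
  }
  if (!is.null(cfg$gene_sets)) {
    if (!is.character(cfg$gene_sets) || length(cfg$gene_sets) != 1L) {
      v <- c(v, "'gene_sets' must be a single path")
    } else if (check_files && !file.exists(cfg$gene_sets)) {
      v <- c(v, sprintf("'gene_sets' file does not exist: %s", cfg$gene_sets))
    }
  }
  if (!is.numeric(cfg$thresholds) || !length(cfg$thresholds) ||
      any(cfg$thresholds <= 0)) {
    v <- c(v, "'thresholds' must be positive numbers")
  }
  for (key in c("t_similar", "t_different", "t_min")) {
    if (!is.numeric(cfg[[key]]) || length(cfg[[key]]) != 1L ||
        cfg[[key]] < 0) {
      v <- c(v, sprintf("'%s' must be a non-negative number", key))
    }
  }
  if (is.numeric(cfg$t_similar) && is.numeric(cfg$t_different) &&
      length(cfg$t_similar) == 1L && length(cfg$t_different) == 1L &&
      cfg$t_different < cfg$t_similar) {
    v <- c(v, "'t_different' must be >= 't_similar'")
  }
  if (!is.numeric(cfg$top_n) || length(cfg$top_n) != 1L || cfg$top_n < 1) {
    v <- c(v, "'top_n' must be a positive integer")
  }
  if (!cfg$log_level %in% c("info", "quiet")) {
    v <- c(v, "'log_level' must be 'info' or 'quiet'")
  }
  v
}

#' Validate a YAML/JSON pipeline configuration file
#'
#' Parses the file, checks it against the strict configuration schema
#' (unknown keys are violations), fills defaults for absent keys and
#' returns the typed configuration. On any violation an error carrying
#' the exhaustive list is raised.
#'
#' @param path Path to a YAML (or JSON) configuration file.
#' @return A [run_config()] on success.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) cx_io_error(sprintf("config file not found: %s", path))
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) cx_parse_error(
                    sprintf("cannot parse config: %s", conditionMessage(e))))
  if (!is.list(raw)) cx_parse_error("config must be a mapping of keys")
  unknown <- setdiff(names(raw), CX_CONFIG_KEYS)
  violations <- if (length(unknown)) {
    sprintf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  } else character(0)
  defaults <- list(gene_sets = NULL, thresholds = c(1.5, 3),
                   t_similar = 0.2, t_different = 0.4, t_min = 0.2,
                   top_n = 20L, one_to_one = FALSE,
                   highlight = character(0), seed = 1L,
                   log_level = "info", write_images = TRUE)
  cfg <- raw[intersect(names(raw), CX_CONFIG_KEYS)]
  for (key in names(defaults)) {
    if (is.null(cfg[[key]])) cfg[[key]] <- defaults[[key]]
  }
  cfg$thresholds <- as.numeric(unlist(cfg$thresholds))
  cfg$highlight <- as.character(unlist(cfg$highlight))
  violations <- c(violations, config_violations(cfg, check_files = TRUE))
  if (length(violations)) {
    cx_validation_error(paste(violations, collapse = "; "))
  }
  structure(cfg, class = "RunConfig")
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(errorCondition(
      sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
      class = c("crossexpr_stage_error", "crossexpr_error", "error"),
      call = NULL))
  })
}

#' Run the full cross-species analysis pipeline
#'
#' Executes the stages in fixed order (load, per-species fold changes,
#' threshold selections and Venn overlaps, ortholog pairing and
#' classification, gene-set summaries, figures) and writes every result
#' table plus `manifest.json` under `config$out_dir`. All data TSVs are
#' deterministic: no timestamps or other run-specific content, so a
#' rerun on identical inputs is byte-identical.
#'
#' @param config A [run_config()] or [validate_config()] result.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    if (config$log_level != "quiet") message(line)
  }
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)

  inputs <- c(expression_a = config$expression_a, samples_a = config$samples_a,
              expression_b = config$expression_b, samples_b = config$samples_b,
              ortholog_map = config$ortholog_map)
  if (!is.null(config$gene_sets)) inputs["gene_sets"] <- config$gene_sets
  for (nm in names(inputs)) {
    if (!file.exists(inputs[[nm]])) {
      cx_io_error(sprintf("input '%s' not found: %s", nm, inputs[[nm]]))
    }
  }

  ds_a <- pipeline_stage("load_expression_a",
                         load_expression(config$expression_a, config$samples_a))
  ds_b <- pipeline_stage("load_expression_b",
                         load_expression(config$expression_b, config$samples_b))
  map <- pipeline_stage("load_ortholog_map",
                        load_ortholog_map(config$ortholog_map))
  sets <- if (!is.null(config$gene_sets)) {
    pipeline_stage("load_gene_sets", load_gene_sets(config$gene_sets))
  }
  say("loaded %d/%d genes (A/B), %d ortholog pairs",
      nrow(ds_a$values), nrow(ds_b$values), nrow(map))

  fc_a <- pipeline_stage("fold_changes_a", compute_fold_changes(ds_a))
  fc_b <- pipeline_stage("fold_changes_b", compute_fold_changes(ds_b))
  write_table(fc_a, file.path(out, sprintf("fold_changes_%s.tsv",
                                           ds_a$species_label)))
  write_table(fc_b, file.path(out, sprintf("fold_changes_%s.tsv",
                                           ds_b$species_label)))

  comparisons <- canonical_comparisons()$name
  selection_counts <- list()
  venn_rows <- list()
  for (thr in config$thresholds) {
    params <- selection_params(threshold = thr)
    for (side in list(list(fc = fc_a, ds = ds_a), list(fc = fc_b, ds = ds_b))) {
      lists <- list()
      for (cmp in comparisons) {
        sel <- select_genes(side$fc, cmp, params)
        lists[[cmp]] <- sel$gene_id
        write_table(sel, file.path(out, sprintf("selection_%s_%s_%s.tsv",
                                                side$ds$species_label, cmp,
                                                format(thr))))
        selection_counts[[length(selection_counts) + 1L]] <- data.frame(
          species = side$ds$species_label, comparison = cmp,
          threshold = thr, n_selected = nrow(sel), stringsAsFactors = FALSE)
      }
      vc <- venn_counts(lists)
      vc$species <- side$ds$species_label
      vc$threshold <- thr
      venn_rows[[length(venn_rows) + 1L]] <- vc
    }
  }
  selection_counts <- do.call(rbind, selection_counts)
  venn_table <- do.call(rbind, venn_rows)
  write_table(venn_table, file.path(out, "venn_counts.tsv"))
  say("selections done at thresholds %s",
      paste(config$thresholds, collapse = ", "))

  paired <- pipeline_stage("pair_fold_changes",
                           pair_fold_changes(fc_a, fc_b, map,
                                             one_to_one = config$one_to_one))
  cls_params <- classification_params(config$t_similar, config$t_different,
                                      config$t_min)
  labelled <- pipeline_stage("classify", classify_table(paired, cls_params))
  write_table(labelled, file.path(out, "paired_fc.tsv"))
  write_table(attr(paired, "coverage"), file.path(out, "coverage_report.tsv"))
  say("classified %d pair-comparison rows", nrow(labelled))

  set_summary <- NULL
  if (!is.null(sets)) {
    set_summary <- pipeline_stage("gene_set_summary",
                                  gene_set_summary(labelled, sets, map))
    write_table(set_summary, file.path(out, "geneset_summary.tsv"))
  }

  heat_a <- pipeline_stage("heatmap_a",
    build_heatmap(ds_a, fc_a, n = config$top_n,
                  file = if (config$write_images)
                    file.path(out, sprintf("heatmap_%s.png",
                                           ds_a$species_label))))
  heat_b <- pipeline_stage("heatmap_b",
    build_heatmap(ds_b, fc_b, n = config$top_n,
                  file = if (config$write_images)
                    file.path(out, sprintf("heatmap_%s.png",
                                           ds_b$species_label))))
  write_figure_data(heat_a, file.path(out, sprintf("heatmap_%s_data.tsv",
                                                   ds_a$species_label)))
  write_figure_data(heat_b, file.path(out, sprintf("heatmap_%s_data.tsv",
                                                   ds_b$species_label)))
  for (cmp in comparisons) {
    sc <- pipeline_stage(paste0("scatter_", cmp),
      build_scatter(labelled, cmp, highlight = config$highlight,
                    file = if (config$write_images)
                      file.path(out, sprintf("scatter_%s.png", cmp))))
    write_figure_data(sc, file.path(out, sprintf("scatter_%s_data.tsv", cmp)))
  }
  say("figures written")

  label_counts <- attr(labelled, "label_counts")
  tsvs <- sort(list.files(out, pattern = "\\.tsv$", full.names = TRUE))
  manifest <- list(
    package_version = as.character(utils::packageVersion("crossexpr")),
    timestamp = format(Sys.time(), tz = "UTC"),
    config = unclass(config),
    input_checksums = as.list(tools::md5sum(unname(inputs))),
    counts = list(
      genes_measured_a = nrow(ds_a$values),
      genes_measured_b = nrow(ds_b$values),
      map_pairs = nrow(map),
      selections = selection_counts,
      venn = venn_table,
      labels = label_counts,
      heatmap_genes_a = length(heat_a$genes),
      heatmap_genes_b = length(heat_b$genes)),
    output_checksums = as.list(tools::md5sum(tsvs)))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(out, "run.log"))
  say("manifest written to %s", file.path(out, "manifest.json"))
  invisible(manifest)
}
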