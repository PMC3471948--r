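#' @keywords internal
"_PACKAGE"

## Stage vocabulary is closed: the three cell populations profiled in the
## study design. "ICM" = inner cell mass of the blastocyst.
CX_STAGES <- c("morula", "blastocyst", "ICM")
CX_LABELS <- c("similar", "different", "neither")

cx_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "crossexpr_error", "error"),
                      call = NULL))
}

cx_format_error     <- function(msg) cx_error(msg, "crossexpr_format_error")
cx_parse_error      <- function(msg) cx_error(msg, "crossexpr_parse_error")
cx_validation_error <- function(msg) cx_error(msg, "crossexpr_validation_error")
cx_io_error         <- function(msg) cx_error(msg, "crossexpr_io_error")

#' Construct an expression dataset for one species
#'
#' Bundles a gene-by-sample matrix of log2 expression intensities with its
#' sample annotations (developmental stage and replicate number). Values are
#' assumed to be already summarized on the log2 scale (e.g. RMA output);
#' no transformation is applied.
#'
#' @param species_label Character scalar naming the species.
#' @param values Numeric matrix, rows = genes, columns = samples. Row names
#'   are gene identifiers, column names are sample identifiers.
#' @param samples Data frame with columns `sample_id`, `stage`
#'   (one of `"morula"`, `"blastocyst"`, `"ICM"`) and `replicate`
#'   (positive integer), one row per matrix column, in matrix column order.
#' @return An object of class `ExpressionDataset`.
#' @export
expression_dataset <- function(species_label, values, samples) {
  if (!is.character(species_label) || length(species_label) != 1L ||
      !nzchar(species_label)) {
    cx_validation_error("species_label must be a non-empty string")
  }
  if (!is.matrix(values) || !is.numeric(values)) {
    cx_validation_error("values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    cx_validation_error("values must have gene row names and sample column names")
  }
  if (anyDuplicated(rownames(values))) {
    cx_validation_error("duplicate gene identifiers in expression matrix")
  }
  if (any(!is.finite(values))) {
    cx_validation_error("expression values must all be finite")
  }
  required <- c("sample_id", "stage", "replicate")
  if (!is.data.frame(samples) || !all(required %in% names(samples))) {
    cx_format_error(
      "sample sheet must have columns sample_id, species/stage/replicate")
  }
  samples <- as.data.frame(samples)[, required]
  samples$sample_id <- as.character(samples$sample_id)
  samples$stage <- as.character(samples$stage)
  samples$replicate <- as.integer(samples$replicate)
  if (nrow(samples) != ncol(values) ||
      !identical(samples$sample_id, colnames(values))) {
    cx_validation_error("sample sheet rows must match matrix columns in order")
  }
  bad <- setdiff(unique(samples$stage), CX_STAGES)
  if (length(bad)) {
    cx_validation_error(sprintf(
      "unknown stage label(s): %s (allowed: %s)",
      paste(bad, collapse = ", "), paste(CX_STAGES, collapse = ", ")))
  }
  if (any(is.na(samples$replicate)) || any(samples$replicate < 1L)) {
    cx_validation_error("replicate must be a positive integer")
  }
  if (anyDuplicated(samples[, c("stage", "replicate")])) {
    cx_validation_error("every (stage, replicate) pair must be unique")
  }
  structure(
    list(species_label = species_label, values = values, samples = samples),
    class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset '%s': %d genes x %d samples (%s)\n",
              x$species_label, nrow(x$values), ncol(x$values),
              paste(sprintf("%s:%d", names(table(x$samples$stage)),
                            as.integer(table(x$samples$stage))),
                    collapse = ", ")))
  invisible(x)
}

gene_ids <- function(dataset) rownames(dataset$values)

#' Canonical stage comparisons
#'
#' The three pairwise stage comparisons of the screening design:
#' blastocyst vs morula (`B_vs_M`), ICM vs blastocyst (`ICM_vs_B`) and
#' ICM vs morula (`ICM_vs_M`). Each fold change is the difference of the
#' mean log2 signals, numerator stage minus denominator stage.
#'
#' @return Data frame with columns `name`, `numerator`, `denominator`.
#' @export
canonical_comparisons <- function() {
  data.frame(
    name        = c("B_vs_M", "ICM_vs_B", "ICM_vs_M"),
    numerator   = c("blastocyst", "ICM", "ICM"),
    denominator = c("morula", "blastocyst", "morula"),
    stringsAsFactors = FALSE)
}

#' Construct a stage comparison
#'
#' @param numerator,denominator Stage labels (distinct).
#' @param name Optional comparison name; defaults to
#'   an abbreviated `"<num>_vs_<den>"` form.
#' @return One-row data frame as in [canonical_comparisons()].
#' @export
stage_comparison <- function(numerator, denominator, name = NULL) {
  if (!numerator %in% CX_STAGES || !denominator %in% CX_STAGES) {
    cx_validation_error("stages must be morula, blastocyst or ICM")
  }
  if (identical(numerator, denominator)) {
    cx_validation_error("numerator and denominator stages must differ")
  }
  abbr <- c(morula = "M", blastocyst = "B", ICM = "ICM")
  if (is.null(name)) name <- paste0(abbr[[numerator]], "_vs_", abbr[[denominator]])
  data.frame(name = name, numerator = numerator, denominator = denominator,
             stringsAsFactors = FALSE)
}

#' Construct an ortholog map
#'
#' A set of cross-species gene-identifier pairs (species A, species B),
#' possibly many-to-many, as exported from a biomart-style translation
#' table. Duplicate pairs are collapsed.
#'
#' @param gene_a,gene_b Character vectors of equal length.
#' @return Data frame of class `OrthologMap` with columns `gene_a`,
#'   `gene_b` and attributes `n_genes_a` / `n_genes_b` (distinct genes).
#' @export
ortholog_map <- function(gene_a, gene_b) {
  gene_a <- as.character(gene_a)
  gene_b <- as.character(gene_b)
  if (length(gene_a) != length(gene_b)) {
    cx_validation_error("gene_a and gene_b must have equal length")
  }
  if (any(!nzchar(gene_a)) || any(!nzchar(gene_b)) ||
      any(is.na(gene_a)) || any(is.na(gene_b))) {
    cx_validation_error("gene identifiers must be non-empty")
  }
  pairs <- unique(data.frame(gene_a = gene_a, gene_b = gene_b,
                             stringsAsFactors = FALSE))
  rownames(pairs) <- NULL
  structure(pairs,
            n_genes_a = length(unique(pairs$gene_a)),
            n_genes_b = length(unique(pairs$gene_b)),
            class = c("OrthologMap", "data.frame"))
}

#' @export
print.OrthologMap <- function(x, ...) {
  cat(sprintf("OrthologMap: %d pairs, %d species-A genes, %d species-B genes\n",
              nrow(x), attr(x, "n_genes_a"), attr(x, "n_genes_b")))
  invisible(x)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors of species-A gene
#'   identifiers; members are de-duplicated.
#' @param description Optional character vector of provenance notes,
#'   one per set (recycled if length 1).
#' @return Named list of class `GeneSetCollection` with a
#'   `description` attribute.
#' @export
gene_set_collection <- function(sets, description = NULL) {
  if (!is.list(sets) || is.null(names(sets)) || any(!nzchar(names(sets)))) {
    cx_validation_error("sets must be a named list")
  }
  if (anyDuplicated(names(sets))) {
    cx_format_error(sprintf("duplicate gene-set name(s): %s",
                            paste(unique(names(sets)[duplicated(names(sets))]),
                                  collapse = ", ")))
  }
  sets <- lapply(sets, function(m) unique(as.character(m)))
  if (any(lengths(sets) == 0L)) {
    cx_validation_error("every gene set must have at least one member")
  }
  if (is.null(description)) description <- rep("", length(sets))
  description <- rep_len(as.character(description), length(sets))
  names(description) <- names(sets)
  structure(sets, description = description, class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection: %d sets (%s)\n", length(x),
              paste(sprintf("%s:%d", names(x), lengths(x)), collapse = ", ")))
  invisible(x)
}
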