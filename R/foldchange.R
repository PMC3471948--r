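#' Per-gene stage means
#'
#' Averages the log2 signals of each gene over the replicates of each
#' stage (unweighted arithmetic mean). Computed once per dataset and
#' reused by every comparison, which makes the fold changes exactly
#' additive across comparisons.
#'
#' @param dataset An [expression_dataset()].
#' @param stages Stages required; defaults to all three.
#' @return Numeric matrix, genes x stages.
#' @export
stage_means <- function(dataset, stages = CX_STAGES) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  absent <- setdiff(stages, unique(dataset$samples$stage))
  if (length(absent)) {
    cx_validation_error(sprintf("no samples for stage(s): %s",
                                paste(absent, collapse = ", ")))
  }
  out <- vapply(stages, function(s) {
    cols <- dataset$samples$stage == s
    rowMeans(dataset$values[, cols, drop = FALSE])
  }, numeric(nrow(dataset$values)))
  if (!is.matrix(out)) out <- matrix(out, nrow = nrow(dataset$values))
  dimnames(out) <- list(rownames(dataset$values), stages)
  out
}

#' Compute log2 fold changes for stage comparisons
#'
#' A fold change here is the difference between mean log2 signal values
#' of the two stages (a log2 ratio): positive means higher in the
#' numerator stage. The returned table carries the per-stage means used,
#' so all downstream selections and plots trace back to one computation.
#'
#' @param dataset An [expression_dataset()].
#' @param comparisons Data frame of comparisons as from
#'   [canonical_comparisons()] (the default).
#' @return Data frame of class `FoldChangeTable`: `gene_id`, one
#'   `mean_<stage>` column per stage, one column per comparison name.
#' @export
compute_fold_changes <- function(dataset, comparisons = canonical_comparisons()) {
  means <- stage_means(dataset,
                       stages = intersect(CX_STAGES,
                                          unique(c(comparisons$numerator,
                                                   comparisons$denominator))))
  tab <- data.frame(gene_id = rownames(means), stringsAsFactors = FALSE)
  for (s in colnames(means)) tab[[paste0("mean_", s)]] <- means[, s]
  for (i in seq_len(nrow(comparisons))) {
    tab[[comparisons$name[i]]] <-
      means[, comparisons$numerator[i]] - means[, comparisons$denominator[i]]
  }
  rownames(tab) <- NULL
  structure(tab,
            species_label = dataset$species_label,
            comparisons = comparisons,
            class = c("FoldChangeTable", "data.frame"))
}

fc_comparisons <- function(fc) attr(fc, "comparisons")$name

check_comparison <- function(fc, comparison) {
  if (!comparison %in% fc_comparisons(fc)) {
    cx_validation_error(sprintf("unknown comparison '%s' (have: %s)",
                                comparison,
                                paste(fc_comparisons(fc), collapse = ", ")))
  }
}

#' Selection parameters for fold-change thresholding
#'
#' @param threshold Positive log2 fold-change threshold. The two
#'   canonical values of the screening design are 1.5 and 3.
#' @param use_absolute Select on `|FC|` (both directions)? Default `TRUE`.
#' @param strict Strict inequality `|FC| > threshold`? Default `TRUE`.
#' @return List of class `SelectionParams`.
#' @export
selection_params <- function(threshold = 1.5, use_absolute = TRUE,
                             strict = TRUE) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    cx_validation_error("threshold must be a positive number")
  }
  structure(list(threshold = threshold, use_absolute = use_absolute,
                 strict = strict),
            class = "SelectionParams")
}

#' Select genes by fold-change threshold
#'
#' Returns the genes whose fold change in one comparison exceeds the
#' threshold (by default on the absolute value, strictly). Output is
#' ordered by `|FC|` descending with ties broken by gene identifier
#' ascending, so selections are deterministic.
#'
#' @param fc A [compute_fold_changes()] table.
#' @param comparison Comparison name, e.g. `"B_vs_M"`.
#' @param params A [selection_params()].
#' @return Data frame with columns `gene_id`, `fc` (signed).
#' @export
select_genes <- function(fc, comparison, params = selection_params()) {
  check_comparison(fc, comparison)
  x <- fc[[comparison]]
  crit <- if (params$use_absolute) abs(x) else x
  keep <- if (params$strict) crit > params$threshold else crit >= params$threshold
  out <- data.frame(gene_id = fc$gene_id[keep], fc = x[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$fc), out$gene_id), ]
  rownames(out) <- NULL
  out
}

#' Three-set Venn region counts
#'
#' Classifies every element of the union of three named gene lists by
#' its membership bit pattern and counts the 7 regions of the Venn
#' diagram.
#'
#' @param lists Named list of exactly three character vectors.
#' @return Data frame with columns `region` (e.g. `"A"`, `"A&B"`,
#'   `"A&B&C"`, using the list names) and `count`, plus a `sets`
#'   attribute with the per-set totals.
#' @export
venn_counts <- function(lists) {
  if (!is.list(lists) || length(lists) != 3L || is.null(names(lists)) ||
      anyDuplicated(names(lists)) || any(!nzchar(names(lists)))) {
    cx_validation_error("lists must be a named list of three distinctly named vectors")
  }
  sets <- lapply(lists, function(x) unique(as.character(x)))
  nm <- names(sets)
  universe <- unique(unlist(sets, use.names = FALSE))
  inA <- universe %in% sets[[1]]
  inB <- universe %in% sets[[2]]
  inC <- universe %in% sets[[3]]
  code <- inA + 2L * inB + 4L * inC
  regions <- c(nm[1], nm[2], paste(nm[1], nm[2], sep = "&"),
               nm[3], paste(nm[1], nm[3], sep = "&"),
               paste(nm[2], nm[3], sep = "&"),
               paste(nm[1], nm[2], nm[3], sep = "&"))
  counts <- vapply(1:7, function(k) sum(code == k), integer(1))
  structure(
    data.frame(region = regions, count = counts, stringsAsFactors = FALSE),
    sets = vapply(sets, length, integer(1)))
}

#' Top-N genes per comparison and their union
#'
#' For each comparison picks the `n` genes of largest absolute fold
#' change (ties broken by gene identifier ascending) and forms their
#' union, preserving first-seen order across the comparisons in table
#' order. This union is the gene selection fed to the clustered heatmap.
#'
#' @param fc A [compute_fold_changes()] table.
#' @param n Number of genes per comparison (default 20, the heatmap
#'   selection of the screening design).
#' @return List with `per_comparison` (named list of gene-id vectors)
#'   and `union` (character vector).
#' @export
top_n_union <- function(fc, n = 20) {
  if (n < 1 || n != round(n)) cx_validation_error("n must be a positive integer")
  if (n > nrow(fc)) {
    cx_validation_error(sprintf("n = %d exceeds gene count %d", n, nrow(fc)))
  }
  per <- lapply(fc_comparisons(fc), function(cmp) {
    x <- fc[[cmp]]
    ord <- order(-abs(x), fc$gene_id)
    fc$gene_id[ord[seq_len(n)]]
  })
  names(per) <- fc_comparisons(fc)
  union <- unique(unlist(per, use.names = FALSE))
  list(per_comparison = per, union = union)
}
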