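#' Pair fold changes across species through the ortholog map
#'
#' Expands every ortholog pair whose genes are measured in both species
#' into one row per comparison carrying the two species' fold changes.
#' Many-to-many orthologs are expanded to all pairs. Pairs with either
#' gene unmeasured are dropped and tallied in the coverage report
#' attached as the `"coverage"` attribute.
#'
#' @param fc_a,fc_b [compute_fold_changes()] tables for species A and B.
#' @param map An [ortholog_map()] keyed (gene_a = species A id,
#'   gene_b = species B id).
#' @param one_to_one Drop pairs whose gene_a or gene_b occurs in more
#'   than one map pair? Default `FALSE` (expansion policy).
#' @return Data frame of class `PairedFoldChanges` with columns
#'   `gene_a`, `gene_b`, `comparison`, `fc_a`, `fc_b`.
#' @export
pair_fold_changes <- function(fc_a, fc_b, map, one_to_one = FALSE) {
  stopifnot(inherits(map, "OrthologMap"))
  shared <- intersect(fc_comparisons(fc_a), fc_comparisons(fc_b))
  if (!length(shared)) {
    cx_validation_error("fold-change tables share no comparison")
  }
  pairs <- as.data.frame(map)
  if (one_to_one) {
    keep <- !(pairs$gene_a %in% pairs$gene_a[duplicated(pairs$gene_a)]) &
            !(pairs$gene_b %in% pairs$gene_b[duplicated(pairs$gene_b)])
    pairs <- pairs[keep, ]
  }
  ia <- match(pairs$gene_a, fc_a$gene_id)
  ib <- match(pairs$gene_b, fc_b$gene_id)
  measured <- !is.na(ia) & !is.na(ib)
  coverage <- data.frame(
    metric = c("map_pairs", "measured_a", "measured_b",
               "paired", "unpaired"),
    count = c(nrow(pairs), sum(!is.na(ia)), sum(!is.na(ib)),
              sum(measured), sum(!measured)),
    stringsAsFactors = FALSE)
  pairs <- pairs[measured, ]
  ia <- ia[measured]
  ib <- ib[measured]
  if (!nrow(pairs)) {
    warning("no ortholog pair is measured in both species")
  }
  rows <- lapply(shared, function(cmp) {
    data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b,
               comparison = rep(cmp, nrow(pairs)),
               fc_a = fc_a[[cmp]][ia], fc_b = fc_b[[cmp]][ib],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(match(out$comparison, shared), out$gene_a, out$gene_b), ]
  rownames(out) <- NULL
  structure(out, coverage = coverage,
            class = c("PairedFoldChanges", "data.frame"))
}

#' Classification parameters for the similar/different heuristic
#'
#' All three thresholds are on the log2 fold-change scale. A pair is
#' *similar* when the two species' fold changes differ by less than
#' `t_similar`; *different* when they differ by more than `t_different`
#' while both fold changes exceed `t_min` in absolute value (this keeps
#' genes off the scatterplot diagonal but excludes genes that are not
#' differentially expressed in one of the species); otherwise *neither*.
#' All inequalities are strict.
#'
#' @param t_similar Gap below which a pair is similar (default 0.2).
#' @param t_different Gap above which a pair can be different (default 0.4).
#' @param t_min Minimum `|FC|` in both species for "different" (default 0.2).
#' @return List of class `ClassificationParams`.
#' @export
classification_params <- function(t_similar = 0.2, t_different = 0.4,
                                  t_min = 0.2) {
  ok <- is.numeric(t_similar) && is.numeric(t_different) && is.numeric(t_min) &&
    length(t_similar) == 1L && length(t_different) == 1L && length(t_min) == 1L
  if (!ok) cx_validation_error("classification thresholds must be numeric scalars")
  if (t_similar < 0 || t_min < 0) {
    cx_validation_error("t_similar and t_min must be >= 0")
  }
  if (t_different < t_similar) {
    cx_validation_error("t_different must be >= t_similar")
  }
  structure(list(t_similar = t_similar, t_different = t_different,
                 t_min = t_min),
            class = "ClassificationParams")
}

#' Classify an ortholog pair's fold changes
#'
#' Vectorized over `fc_a` / `fc_b`. Labels are a partition: every input
#' receives exactly one of `"similar"`, `"different"`, `"neither"`.
#' On the fold-change scatterplots the three labels correspond to red,
#' green and black points respectively.
#'
#' @param fc_a,fc_b Finite numeric vectors of log2 fold changes.
#' @param params A [classification_params()].
#' @return Character vector of labels.
#' @export
classify_pair <- function(fc_a, fc_b, params = classification_params()) {
  if (length(fc_a) != length(fc_b)) {
    cx_validation_error("fc_a and fc_b must have equal length")
  }
  if (any(!is.finite(fc_a)) || any(!is.finite(fc_b))) {
    cx_validation_error("fold changes must be finite")
  }
  gap <- abs(fc_a - fc_b)
  label <- rep("neither", length(gap))
  label[gap > params$t_different &
          abs(fc_a) > params$t_min & abs(fc_b) > params$t_min] <- "different"
  label[gap < params$t_similar] <- "similar"
  label
}

#' Label every row of a paired fold-change table
#'
#' @param paired A [pair_fold_changes()] table.
#' @param params A [classification_params()].
#' @return The table with a `label` column added, class
#'   `PatternLabelTable`; per-comparison label counts in the
#'   `"label_counts"` attribute.
#' @export
classify_table <- function(paired, params = classification_params()) {
  stopifnot(inherits(paired, "PairedFoldChanges"))
  out <- as.data.frame(paired)
  out$label <- if (nrow(out)) classify_pair(out$fc_a, out$fc_b, params) else character(0)
  counts <- as.data.frame(table(
    comparison = factor(out$comparison, levels = unique(out$comparison)),
    label = factor(out$label, levels = CX_LABELS)),
    stringsAsFactors = FALSE)
  names(counts)[3] <- "count"
  structure(out, label_counts = counts, params = params,
            coverage = attr(paired, "coverage"),
            class = c("PatternLabelTable", "PairedFoldChanges", "data.frame"))
}

#' Restrict a paired or labelled table to one gene set
#'
#' Gene sets are defined on species-A identifiers; rows whose `gene_a`
#' belongs to the set are kept. A report of set size, mapped size and
#' measured size is attached as the `"set_report"` attribute.
#'
#' @param x A `PairedFoldChanges` or `PatternLabelTable`.
#' @param set Character vector of species-A gene identifiers.
#' @param map The [ortholog_map()] used for pairing.
#' @return Same class as `x`, restricted.
#' @export
restrict_to_gene_set <- function(x, set, map) {
  stopifnot(inherits(x, "PairedFoldChanges"))
  if (!length(set)) cx_validation_error("gene set is empty")
  set <- unique(as.character(set))
  mapped <- intersect(set, map$gene_a)
  measured <- intersect(set, unique(x$gene_a))
  out <- x[x$gene_a %in% set, ]
  rownames(out) <- NULL
  attr(out, "set_report") <- data.frame(
    metric = c("set_size", "mapped", "measured"),
    count = c(length(set), length(mapped), length(measured)),
    stringsAsFactors = FALSE)
  attr(out, "coverage") <- attr(x, "coverage")
  class(out) <- class(x)
  out
}

#' Per-gene-set summary of pattern labels
#'
#' For every (gene set, comparison) tallies the similar / different /
#' neither ortholog pairs among the set's members and lists the
#' "different" genes, ordered by the inter-species fold-change gap
#' (largest first).
#'
#' @param labels A [classify_table()] result.
#' @param sets A [gene_set_collection()] on species-A identifiers.
#' @param map The [ortholog_map()] used for pairing.
#' @return Data frame: `set`, `comparison`, `n_similar`, `n_different`,
#'   `n_neither`, `different_genes` (semicolon-separated `gene_a` ids).
#' @export
gene_set_summary <- function(labels, sets, map) {
  stopifnot(inherits(labels, "PatternLabelTable"),
            inherits(sets, "GeneSetCollection"))
  comparisons <- unique(labels$comparison)
  rows <- list()
  for (set_name in names(sets)) {
    sub <- restrict_to_gene_set(labels, sets[[set_name]], map)
    for (cmp in comparisons) {
      s <- sub[sub$comparison == cmp, ]
      diff_rows <- s[s$label == "different", ]
      diff_rows <- diff_rows[order(-abs(diff_rows$fc_a - diff_rows$fc_b),
                                   diff_rows$gene_a), ]
      rows[[length(rows) + 1L]] <- data.frame(
        set = set_name, comparison = cmp,
        n_similar = sum(s$label == "similar"),
        n_different = sum(s$label == "different"),
        n_neither = sum(s$label == "neither"),
        different_genes = paste(unique(diff_rows$gene_a), collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
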