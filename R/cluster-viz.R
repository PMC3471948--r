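## Visual outputs. Every figure returns a "spec" object carrying the
## exact numbers drawn, so tests and sidecar TSVs read back the data
## side rather than the image bytes.

#' Deterministic hierarchical clustering of matrix rows
#'
#' Agglomerative clustering with Euclidean distance and average linkage
#' on the rows of a (typically row-centered) matrix. Given the same
#' input row order, the leaf order is deterministic.
#'
#' @param mat Numeric matrix with at least 2 rows.
#' @return List with `order` (leaf order, row indices), `labels`
#'   (row names in leaf order), and `hclust` (the linkage record).
#' @export
hierarchical_order <- function(mat) {
  if (!is.matrix(mat) || nrow(mat) < 2L) {
    cx_validation_error("clustering needs a matrix with at least 2 rows")
  }
  hc <- stats::hclust(stats::dist(mat, method = "euclidean"),
                      method = "average")
  list(order = hc$order,
       labels = if (!is.null(rownames(mat))) rownames(mat)[hc$order] else NULL,
       hclust = hc)
}

heatmap_sample_order <- function(dataset) {
  ord <- order(match(dataset$samples$stage, CX_STAGES),
               dataset$samples$replicate)
  dataset$samples$sample_id[ord]
}

#' Build the top-N fold-change heatmap for one species
#'
#' Selects the union of the top-`n` absolute-fold-change genes of each
#' comparison ([top_n_union()]), row-centers their log2 values (each
#' row mean becomes 0, preserving fold-change magnitudes), clusters the
#' rows and leaves the columns in fixed design order (morula,
#' blastocyst, ICM replicates).
#'
#' @param dataset An [expression_dataset()].
#' @param fc Its [compute_fold_changes()] table; computed if `NULL`.
#' @param n Genes per comparison (default 20).
#' @param file Optional PNG path; if given, the heatmap image is written.
#' @return List of class `HeatmapSpec`: `genes` (selected union),
#'   `gene_order` (leaf order), `sample_order`, `values` (row-centered
#'   matrix), `linkage`.
#' @export
build_heatmap <- function(dataset, fc = NULL, n = 20, file = NULL) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  if (is.null(fc)) fc <- compute_fold_changes(dataset)
  sel <- top_n_union(fc, n)
  cols <- heatmap_sample_order(dataset)
  mat <- dataset$values[sel$union, cols, drop = FALSE]
  mat <- sweep(mat, 1, rowMeans(mat))
  if (nrow(mat) >= 2L) {
    cl <- hierarchical_order(mat)
    gene_order <- rownames(mat)[cl$order]
    linkage <- cl$hclust
  } else {
    gene_order <- rownames(mat)
    linkage <- NULL
  }
  spec <- structure(
    list(genes = sel$union, gene_order = gene_order, sample_order = cols,
         values = mat, linkage = linkage,
         clustering = "euclidean distance, average linkage, row-centered"),
    class = "HeatmapSpec")
  if (!is.null(file)) {
    pheatmap::pheatmap(
      mat,
      cluster_rows = if (is.null(linkage)) FALSE else linkage,
      cluster_cols = FALSE,
      fontsize_row = 6,
      main = sprintf("%s: top %d |log2 FC| genes per comparison",
                     dataset$species_label, n),
      filename = file, silent = TRUE)
  }
  spec
}

#' Build a cross-species fold-change scatterplot
#'
#' One point per ortholog pair for one comparison: species A fold
#' change on x, species B on y. Colors follow the pattern labels:
#' red = similar, green = different, black = neither. A diagonal
#' reference line marks equal fold change; highlighted genes are
#' annotated with text labels.
#'
#' @param labels A [classify_table()] result.
#' @param comparison Comparison name.
#' @param highlight Character vector of `gene_a` identifiers to
#'   annotate; unknown genes produce a warning and are skipped.
#' @param file Optional PNG path.
#' @return List of class `ScatterSpec`: `points` data frame (`gene_a`,
#'   `gene_b`, `fc_a`, `fc_b`, `label`, `color`), `comparison`,
#'   `highlight`.
#' @export
build_scatter <- function(labels, comparison, highlight = character(0),
                          file = NULL) {
  stopifnot(inherits(labels, "PatternLabelTable"))
  if (!comparison %in% unique(labels$comparison)) {
    cx_validation_error(sprintf("comparison '%s' not present", comparison))
  }
  pts <- as.data.frame(labels[labels$comparison == comparison, ])
  palette <- c(similar = "red", different = "green", neither = "black")
  pts$color <- unname(palette[pts$label])
  missing <- setdiff(highlight, pts$gene_a)
  if (length(missing)) {
    warning(sprintf("highlight gene(s) not in table, skipped: %s",
                    paste(missing, collapse = ", ")))
  }
  highlight <- setdiff(highlight, missing)
  rownames(pts) <- NULL
  spec <- structure(
    list(points = pts[, c("gene_a", "gene_b", "fc_a", "fc_b",
                          "label", "color")],
         comparison = comparison, highlight = highlight),
    class = "ScatterSpec")
  if (!is.null(file)) {
    lim <- max(abs(c(pts$fc_a, pts$fc_b, 1))) * 1.05
    p <- ggplot2::ggplot(pts, ggplot2::aes(x = fc_a, y = fc_b)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                           color = "grey60") +
      ggplot2::geom_point(color = pts$color, size = 1.2) +
      ggplot2::coord_cartesian(xlim = c(-lim, lim), ylim = c(-lim, lim)) +
      ggplot2::labs(x = "log2 fold change, species A",
                    y = "log2 fold change, species B",
                    title = comparison) +
      ggplot2::theme_bw()
    if (length(highlight)) {
      hl <- pts[pts$gene_a %in% highlight, ]
      p <- p + ggplot2::geom_text(
        data = hl, ggplot2::aes(label = gene_a),
        vjust = -0.8, size = 2.8)
    }
    ggplot2::ggsave(file, p, width = 5, height = 5, dpi = 150)
  }
  spec
}

#' Build an expression profile plot for one ortholog pair
#'
#' Plots the mean log2 signal of a gene in each species over the stages
#' in figure order morula (MO), ICM, blastocyst (BL). The unit is log2
#' of measured expression.
#'
#' @param gene_a,gene_b Gene identifiers in species A and B.
#' @param dataset_a,dataset_b The two [expression_dataset()]s.
#' @param file Optional PNG path.
#' @return List of class `ProfileSpec`: `stages` (MO/ICM/BL order),
#'   `means_a`, `means_b`, `gene_a`, `gene_b`, species labels.
#' @export
build_profile <- function(gene_a, gene_b, dataset_a, dataset_b, file = NULL) {
  for (check in list(list(gene_a, dataset_a), list(gene_b, dataset_b))) {
    if (!check[[1]] %in% rownames(check[[2]]$values)) {
      cx_validation_error(sprintf("gene '%s' not measured in species '%s'",
                                  check[[1]], check[[2]]$species_label))
    }
  }
  stage_order <- c("morula", "ICM", "blastocyst")
  ma <- stage_means(dataset_a)[gene_a, stage_order]
  mb <- stage_means(dataset_b)[gene_b, stage_order]
  spec <- structure(
    list(stages = stage_order, means_a = ma, means_b = mb,
         gene_a = gene_a, gene_b = gene_b,
         species_a = dataset_a$species_label,
         species_b = dataset_b$species_label),
    class = "ProfileSpec")
  if (!is.null(file)) {
    df <- data.frame(
      stage = factor(rep(stage_order, 2), levels = stage_order),
      mean_log2 = c(ma, mb),
      species = rep(c(dataset_a$species_label, dataset_b$species_label),
                    each = 3))
    p <- ggplot2::ggplot(df, ggplot2::aes(x = stage, y = mean_log2,
                                          group = species, color = species)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::scale_color_manual(
        values = stats::setNames(c("blue", "red"),
                                 c(dataset_a$species_label,
                                   dataset_b$species_label))) +
      ggplot2::labs(title = sprintf("%s / %s", gene_a, gene_b),
                    y = "log2 of measured expression", x = NULL) +
      ggplot2::theme_bw()
    ggplot2::ggsave(file, p, width = 4, height = 3.5, dpi = 150)
  }
  spec
}

#' Write the sidecar TSVs for a figure spec
#'
#' @param spec A `HeatmapSpec`, `ScatterSpec` or `ProfileSpec`.
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
write_figure_data <- function(spec, path) {
  if (inherits(spec, "HeatmapSpec")) {
    df <- data.frame(gene_id = rownames(spec$values),
                     leaf_rank = match(rownames(spec$values), spec$gene_order),
                     spec$values, check.names = FALSE)
    write_table(df, path)
  } else if (inherits(spec, "ScatterSpec")) {
    write_table(spec$points, path)
  } else if (inherits(spec, "ProfileSpec")) {
    df <- data.frame(stage = spec$stages,
                     mean_a = unname(spec$means_a),
                     mean_b = unname(spec$means_b))
    write_table(df, path)
  } else {
    cx_validation_error("unknown figure spec type")
  }
  invisible(path)
}
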