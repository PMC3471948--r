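## File formats (all plain text, tab separated):
##  - expression matrix: header "gene_id<TAB>sample..." one gene per row
##  - sample sheet:      header sample_id, species, stage, replicate
##  - ortholog map:      header row (always skipped), columns gene_a, gene_b
##  - gene sets:         GMT (name, description, members...)

read_tsv_checked <- function(path, what) {
  if (!file.exists(path)) {
    cx_io_error(sprintf("%s file not found: %s", what, path))
  }
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", quote = "",
                    stringsAsFactors = FALSE)
}

#' Load an expression matrix with its sample sheet
#'
#' Reads a genes-by-samples TSV of log2 intensities (first column
#' `gene_id`, remaining columns one per sample) together with a sample
#' sheet (`sample_id`, `species`, `stage`, `replicate`). Every matrix
#' column must appear in the sheet; sheet rows are reordered to the
#' matrix column order. Values are used as-is: the loader assumes
#' upstream log2 summarization and performs no transformation.
#'
#' @param matrix_path Path to the expression matrix TSV.
#' @param sample_sheet_path Path to the sample sheet TSV.
#' @return An [expression_dataset()].
#' @export
load_expression <- function(matrix_path, sample_sheet_path) {
  mat_df <- read_tsv_checked(matrix_path, "expression matrix")
  if (ncol(mat_df) < 2L || names(mat_df)[1] != "gene_id") {
    cx_format_error("expression matrix must start with a gene_id column")
  }
  sample_ids <- names(mat_df)[-1]
  if (anyDuplicated(sample_ids)) {
    cx_format_error(sprintf("duplicate sample_id column(s): %s",
                            paste(unique(sample_ids[duplicated(sample_ids)]),
                                  collapse = ", ")))
  }
  genes <- mat_df$gene_id
  if (any(!nzchar(genes))) cx_parse_error("empty gene_id encountered")

  values <- matrix(NA_real_, nrow = nrow(mat_df), ncol = length(sample_ids),
                   dimnames = list(genes, sample_ids))
  for (j in seq_along(sample_ids)) {
    cell <- mat_df[[j + 1L]]
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(num) | !nzchar(trimws(cell)))
    if (length(bad)) {
      cx_parse_error(sprintf(
        "non-numeric or empty value at gene '%s', sample '%s'",
        genes[bad[1]], sample_ids[j]))
    }
    values[, j] <- num
  }

  sheet <- read_tsv_checked(sample_sheet_path, "sample sheet")
  needed <- c("sample_id", "species", "stage", "replicate")
  if (!all(needed %in% names(sheet))) {
    cx_format_error(sprintf("sample sheet must have columns: %s",
                            paste(needed, collapse = ", ")))
  }
  if (anyDuplicated(sheet$sample_id)) {
    cx_format_error(sprintf("duplicate sample_id in sheet: %s",
                            paste(unique(sheet$sample_id[duplicated(sheet$sample_id)]),
                                  collapse = ", ")))
  }
  missing <- setdiff(sample_ids, sheet$sample_id)
  if (length(missing)) {
    cx_format_error(sprintf("matrix column(s) absent from sample sheet: %s",
                            paste(missing, collapse = ", ")))
  }
  sheet <- sheet[match(sample_ids, sheet$sample_id), ]
  species <- unique(sheet$species)
  if (length(species) != 1L) {
    cx_validation_error(sprintf(
      "sample sheet must describe a single species, found: %s",
      paste(species, collapse = ", ")))
  }
  rep_num <- suppressWarnings(as.integer(sheet$replicate))
  if (any(is.na(rep_num))) cx_parse_error("non-integer replicate in sample sheet")
  expression_dataset(
    species_label = species,
    values = values,
    samples = data.frame(sample_id = sheet$sample_id, stage = sheet$stage,
                         replicate = rep_num, stringsAsFactors = FALSE))
}

#' Load an ortholog translation table
#'
#' Reads a two-column TSV of cross-species gene-identifier pairs
#' (biomart-export style). The first row is a header and is always
#' skipped; columns beyond the second are ignored. Duplicate rows are
#' collapsed to unique pairs, so loading is order-independent.
#'
#' @param path Path to the TSV file.
#' @return An [ortholog_map()].
#' @export
load_ortholog_map <- function(path) {
  if (!file.exists(path)) cx_io_error(sprintf("ortholog map not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) cx_format_error("ortholog map file is empty")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L)) {
    cx_format_error("ortholog map must have at least 2 tab-separated columns")
  }
  fields <- fields[-1L]  # header row: required, always skipped
  if (length(fields) == 0L) {
    cx_format_error("ortholog map has a header but no data rows")
  }
  ortholog_map(vapply(fields, `[[`, "", 1L), vapply(fields, `[[`, "", 2L))
}

#' Load gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name`, `description`, then one or more member identifiers.
#' Duplicate members within a set are collapsed.
#'
#' @param path Path to the GMT file.
#' @return A [gene_set_collection()].
#' @export
load_gene_sets <- function(path) {
  if (!file.exists(path)) cx_io_error(sprintf("gene set file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) cx_format_error("GMT file is empty")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    cx_format_error(sprintf(
      "GMT line %d has fewer than 3 fields (name, description, members...)",
      short[1]))
  }
  nm <- vapply(fields, `[[`, "", 1L)
  desc <- vapply(fields, `[[`, "", 2L)
  members <- lapply(fields, function(f) f[-(1:2)])
  empties <- which(vapply(members, function(m) all(!nzchar(m)), logical(1)))
  if (length(empties)) {
    cx_format_error(sprintf("GMT line %d has an empty member list", empties[1]))
  }
  members <- lapply(members, function(m) m[nzchar(m)])
  names(members) <- nm
  gene_set_collection(members, description = desc)
}

#' Write a result table as TSV
#'
#' Writes any data frame with a header row, tab separators and no
#' quoting. Numeric columns are rendered with 6 significant digits so
#' output is stable across platforms; row order is preserved.
#'
#' @param table A data frame.
#' @param path Output path; the parent directory must exist.
#' @return Invisibly, the path.
#' @export
write_table <- function(table, path) {
  if (!is.data.frame(table)) cx_validation_error("table must be a data frame")
  if (!dir.exists(dirname(path))) {
    cx_io_error(sprintf("output directory does not exist: %s", dirname(path)))
  }
  out <- as.data.frame(table)
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- formatC(out[[j]], digits = 6, format = "g")
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write an expression dataset to matrix + sample sheet files
#'
#' Inverse of [load_expression()]; used by the simulator and in
#' round-trip tests.
#'
#' @param dataset An [expression_dataset()].
#' @param matrix_path,sample_sheet_path Output paths.
#' @return Invisibly, `matrix_path`.
#' @export
write_expression <- function(dataset, matrix_path, sample_sheet_path) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  mat <- data.frame(gene_id = rownames(dataset$values),
                    dataset$values, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write_table(mat, matrix_path)
  sheet <- data.frame(sample_id = dataset$samples$sample_id,
                      species = dataset$species_label,
                      stage = dataset$samples$stage,
                      replicate = dataset$samples$replicate,
                      stringsAsFactors = FALSE)
  write_table(sheet, sample_sheet_path)
  invisible(matrix_path)
}
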