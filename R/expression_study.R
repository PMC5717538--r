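#' Case/control expression study for one disease
#'
#' Container for a single disease's analysis-ready expression data: a
#' genes x samples numeric matrix together with a sample sheet assigning
#' each sample to an arm (`"disease"` or `"control"`) and a batch.
#'
#' @param disease_id single string naming the disease.
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param samples a data frame with columns `sample_id`, `arm`
#'   (values `"disease"`/`"control"`) and `batch`, one row per column of
#'   `values`, in matching order.
#' @return an object of class `expression_study`.
#' @export
expression_study <- function(disease_id, values, samples) {
  stopifnot(is.character(disease_id), length(disease_id) == 1)
  values <- as.matrix(values)
  if (!is.numeric(values)) abort_dganet("`values` must be numeric", "bad_input")
  if (is.null(rownames(values))) abort_dganet("`values` needs gene rownames", "bad_input")
  if (anyDuplicated(rownames(values)))
    abort_dganet("duplicate gene ids in `values`; collapse probes first", "bad_input")
  samples <- tibble::as_tibble(samples)
  req <- c("sample_id", "arm", "batch")
  if (!all(req %in% names(samples)))
    abort_dganet("sample sheet needs columns sample_id, arm, batch", "bad_input")
  if (nrow(samples) != ncol(values))
    abort_dganet("sample sheet rows must match matrix columns", "bad_input")
  if (!all(samples$arm %in% c("disease", "control")))
    abort_dganet("arm must be 'disease' or 'control'", "bad_input")
  if (any(table(samples$arm) < 2) || length(unique(samples$arm)) < 2)
    abort_dganet(
      sprintf("study '%s' needs >= 2 samples in each arm", disease_id),
      "bad_input"
    )
  if (is.null(colnames(values))) colnames(values) <- samples$sample_id
  structure(
    list(disease_id = disease_id, values = values, samples = samples),
    class = "expression_study"
  )
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf(
    "<expression_study> %s: %d genes x %d samples (%d disease / %d control, %d batch%s)\n",
    x$disease_id, nrow(x$values), ncol(x$values),
    sum(x$samples$arm == "disease"), sum(x$samples$arm == "control"),
    length(unique(x$samples$batch)),
    if (length(unique(x$samples$batch)) == 1) "" else "es"
  ))
  invisible(x)
}

#' @export
dim.expression_study <- function(x) dim(x$values)

arm_matrix <- function(study, arm) {
  study$values[, study$samples$arm == arm, drop = FALSE]
}

#' Write / read an expression study as TSV
#'
#' The on-disk dialect is two plain-text files: an expression matrix TSV
#' whose first column is `gene_id` and remaining columns are samples, and a
#' sample sheet TSV with columns `sample_id`, `disease`, `arm`, `batch`.
#'
#' @param study an [expression_study()].
#' @param matrix_path,sheet_path file paths for the matrix and sample sheet.
#' @return `write_expression_study()` returns the study invisibly;
#'   `read_expression_study()` returns an [expression_study()].
#' @export
write_expression_study <- function(study, matrix_path, sheet_path) {
  mat <- tibble::as_tibble(study$values, rownames = "gene_id")
  readr::write_tsv(mat, matrix_path)
  sheet <- dplyr::mutate(study$samples, disease = study$disease_id,
                         .after = "sample_id")
  readr::write_tsv(sheet, sheet_path)
  invisible(study)
}

#' @rdname write_expression_study
#' @export
read_expression_study <- function(matrix_path, sheet_path) {
  mat <- readr::read_tsv(matrix_path, show_col_types = FALSE)
  sheet <- readr::read_tsv(sheet_path, show_col_types = FALSE,
                           col_types = readr::cols(batch = readr::col_character()))
  values <- as.matrix(mat[, -1, drop = FALSE])
  rownames(values) <- as.character(mat[[1]])
  disease <- unique(sheet$disease)
  if (length(disease) != 1)
    abort_dganet("sample sheet must describe exactly one disease", "bad_input")
  expression_study(disease, values,
                   sheet[, c("sample_id", "arm", "batch")])
}

#' Read a GEO-style series matrix text file
#'
#' Minimal reader for the "series matrix" layout: metadata lines prefixed
#' with `!`, and a probe x sample table fenced by
#' `!series_matrix_table_begin` / `!series_matrix_table_end`. Returns the
#' table only; sample annotation must be supplied separately.
#'
#' @param path path to an uncompressed series-matrix text file.
#' @return numeric matrix, probes in rows, samples in columns.
#' @export
read_series_matrix <- function(path) {
  lines <- readr::read_lines(path)
  begin <- which(lines == "!series_matrix_table_begin")
  end <- which(lines == "!series_matrix_table_end")
  if (length(begin) != 1 || length(end) != 1 || end <= begin + 1)
    abort_dganet("no series_matrix_table_begin/end fence found", "bad_format")
  tbl <- readr::read_tsv(I(lines[(begin + 1):(end - 1)]),
                         show_col_types = FALSE)
  values <- as.matrix(tbl[, -1, drop = FALSE])
  rownames(values) <- as.character(tbl[[1]])
  storage.mode(values) <- "double"
  values
}

#' Read a probe-to-gene map
#'
#' @param path two-column TSV (`probe_id`, `gene_symbol`); extra columns
#'   are ignored.
#' @return tibble with columns `probe_id`, `gene_symbol`.
#' @export
read_probe_map <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  if (ncol(tbl) < 2) abort_dganet("probe map needs two columns", "bad_format")
  tibble::tibble(probe_id = as.character(tbl[[1]]),
                 gene_symbol = as.character(tbl[[2]]))
}
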