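# Plain-text IO: cohort and measurement CSVs (RFC 4180, header row),
# expression TSV (genes x samples, first column = gene identifier).

#' Read a cohort CSV
#'
#' Expects columns `sample_id`, `os_time_months`, `os_event`,
#' `pfs_time_months`, `pfs_event`, optional `satb1_positive` /
#' `p16_positive` and free covariate columns.
#'
#' @param path CSV path.
#' @return A tibble, validated.
#' @export
read_cohort_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  validate_records(df)
  df
}

#' Write a cohort CSV
#' @param records Cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(records, path) {
  readr::write_csv(records, path)
  invisible(path)
}

#' Read raw IHC measurements from CSV
#'
#' Expects columns `sample_id`, `marker`, `intensity`,
#' `percent_positive`.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_measurements_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(df, c("sample_id", "marker", "intensity",
                      "percent_positive"), "measurements")
  df
}

#' Read an expression matrix from TSV
#'
#' First column: gene identifiers; remaining columns: one per sample.
#'
#' @param path TSV path.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  genes <- as.character(df[[1L]])
  mat <- as.matrix(df[, -1L, drop = FALSE])
  mode(mat) <- "numeric"
  rownames(mat) <- genes
  mat
}

#' Write an expression matrix to TSV
#' @param mat Genes x samples matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- as_tibble(mat, rownames = "gene")
  readr::write_tsv(df, path)
  invisible(path)
}
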