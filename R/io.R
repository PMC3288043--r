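#' Read a raw expression matrix and its sample sheet
#'
#' Reads a features-by-samples TSV of linear intensities (first column
#' `mirna_id`, one column per sample) together with a CSV sample sheet, joins
#' the metadata, and clips non-positive intensities at a floor of 1 so that
#' log2 transformation is defined. Background-subtracted feature medians can
#' legitimately be negative; the number of clipped cells is reported via a
#' message and stored as an attribute.
#'
#' @param matrix_path Path to the expression TSV.
#' @param samples_path Path to the sample sheet CSV with columns `sample_id`,
#'   `cell_line`, `her2_status`, `treatment`, `dose_ug_ml`, `hours`.
#' @param clip_floor Linear intensity floor (default 1).
#' @return A list with `expression` (long tibble `mirna_id`, `sample_id`,
#'   `intensity`, attribute `n_clipped`) and `samples` (the sample sheet
#'   tibble).
#' @export
read_expression_matrix <- function(matrix_path, samples_path, clip_floor = 1) {
  if (!file.exists(matrix_path)) {
    abort(paste0("Expression matrix not found: ", matrix_path),
          class = "mirscreen_io_error")
  }
  if (!file.exists(samples_path)) {
    abort(paste0("Sample sheet not found: ", samples_path),
          class = "mirscreen_io_error")
  }
  wide <- readr::read_tsv(matrix_path, show_col_types = FALSE)
  if (names(wide)[1] != "mirna_id") {
    abort("First column of the expression TSV must be `mirna_id`.",
          class = "mirscreen_format_error")
  }
  if (anyDuplicated(wide$mirna_id)) {
    abort("Duplicate microRNA IDs in the expression matrix.",
          class = "mirscreen_format_error")
  }
  samples <- readr::read_csv(samples_path, show_col_types = FALSE,
                             col_types = readr::cols(sample_id = "c", cell_line = "c"))
  header_ids <- setdiff(names(wide), "mirna_id")
  missing <- setdiff(header_ids, samples$sample_id)
  extra <- setdiff(samples$sample_id, header_ids)
  if (length(missing) || length(extra)) {
    abort(paste0(
      "Sample sheet and matrix header disagree.",
      if (length(missing)) paste0(" Not in sheet: ", paste(missing, collapse = ", "), "."),
      if (length(extra)) paste0(" Not in matrix: ", paste(extra, collapse = ", "), ".")
    ), class = "mirscreen_metadata_error")
  }
  expression <- tidyr::pivot_longer(wide, -"mirna_id",
                                    names_to = "sample_id", values_to = "intensity")
  n_clipped <- sum(expression$intensity < clip_floor)
  if (n_clipped > 0) {
    inform(sprintf("Clipped %d intensities below %g to the floor.",
                   n_clipped, clip_floor))
    expression$intensity <- pmax(expression$intensity, clip_floor)
  }
  attr(expression, "n_clipped") <- n_clipped
  list(expression = expression, samples = samples)
}

#' Write a simulated array experiment to disk
#'
#' Writes the expression matrix TSV (wide, first column `mirna_id`), the
#' sample sheet CSV and the ground-truth TSV in the dialects that
#' [read_expression_matrix()] reads back.
#'
#' @param sim A `mir_array_sim` from [simulate_array()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the paths written.
#' @export
write_array_data <- function(sim, dir) {
  stopifnot(inherits(sim, "mir_array_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    samples = file.path(dir, "samples.csv"),
    truth = file.path(dir, "truth.tsv")
  )
  wide <- tidyr::pivot_wider(sim$expression, names_from = "sample_id",
                             values_from = "intensity")
  readr::write_tsv(wide, paths["expression"])
  readr::write_csv(sim$samples, paths["samples"])
  readr::write_tsv(sim$truth, paths["truth"])
  invisible(paths)
}

#' Read sequences from a FASTA file
#'
#' Thin wrapper over `Biostrings::readBStringSet()` returning a tidy tibble.
#'
#' @param path FASTA path.
#' @return A tibble with columns `name` (first word of the header) and
#'   `sequence` (uppercase).
#' @export
read_fasta_sequences <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("Reading FASTA requires the Biostrings package.")
  }
  set <- Biostrings::readBStringSet(path)
  tibble(
    name = sub("\\s.*$", "", names(set)),
    sequence = toupper(as.character(set))
  )
}
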