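#' Run the full screen from files to report artifacts
#'
#' Reads the expression matrix and sample sheet, quantile-normalizes and
#' log2-transforms, runs the four-step screen, and writes
#' `screen_report.tsv` (columns `list`, `direction`, `rank`, `mirna`,
#' `cell_line`, `rfc`; RFC to 4 decimals), `screen_report.json` (counts,
#' criteria and both lists) and, optionally, `heatmap.svg`. Stage counts
#' are logged as messages.
#'
#' @param matrix_path Expression TSV path.
#' @param samples_path Sample sheet CSV path.
#' @param out_dir Output directory (created if needed).
#' @param criteria A [screen_criteria()].
#' @param heatmap Write a clustered expression heatmap of the retained
#'   microRNAs (default `FALSE`).
#' @return The `screen_report`, invisibly.
#' @export
run_screen_pipeline <- function(matrix_path, samples_path, out_dir,
                                criteria = screen_criteria(), heatmap = FALSE) {
  loaded <- read_expression_matrix(matrix_path, samples_path)
  norm <- normalize_log2(loaded$expression)
  report <- screen_responsive(norm, loaded$samples, criteria)
  inform(sprintf(
    "screen: %d microRNAs, %d past expression floor, %d after negative-line exclusion, %d up / %d down cross-line",
    report$counts$n_total, report$counts$n_expressed,
    report$counts$n_after_negative_exclusion,
    sum(report$cross_line$direction == "up"),
    sum(report$cross_line$direction == "down")
  ))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_screen_report(report, out_dir)
  if (heatmap) {
    p <- plot_expression_heatmap(norm, mirnas = report$expressed)
    ggplot2::ggsave(file.path(out_dir, "heatmap.svg"), p,
                    width = 7, height = 7)
  }
  invisible(report)
}

#' Write a screen report as TSV and JSON
#'
#' @param report A `screen_report`.
#' @param out_dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_screen_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- dplyr::bind_rows(
    dplyr::mutate(tidy(report, "per_line"), list = "per_line"),
    dplyr::mutate(tidy(report, "cross_line"), list = "cross_line",
                  cell_line = NA_character_)
  ) |>
    dplyr::transmute(
      list = .data$list, direction = .data$direction, rank = .data$rank,
      mirna = .data$mirna_id, cell_line = .data$cell_line, rfc = .data$rfc
    )
  tsv_path <- file.path(out_dir, "screen_report.tsv")
  readr::write_tsv(tsv, tsv_path)
  json_path <- file.path(out_dir, "screen_report.json")
  jsonlite::write_json(
    list(
      criteria = unclass(report$criteria),
      counts = report$counts,
      per_line = tidy(report, "per_line"),
      cross_line = tidy(report, "cross_line")
    ),
    json_path, auto_unbox = TRUE, digits = NA
  )
  invisible(c(tsv = tsv_path, json = json_path))
}

#' Simulate an array experiment from a YAML configuration
#'
#' Reads simulator settings from a YAML file (any subset of the
#' [array_sim_config()] arguments; `planted` as a list of records with
#' `mirna_id`, `cell_line`, `log2_effect`), generates the experiment, and
#' writes the expression TSV, sample sheet CSV and truth TSV.
#'
#' @param config_path YAML path, or `NULL` for the default config.
#' @param seed Overrides the config's `rng_seed` when not `NULL`.
#' @param out_dir Output directory.
#' @return Invisibly, the paths written.
#' @export
run_simulate <- function(config_path = NULL, seed = NULL, out_dir = ".") {
  args <- list()
  if (!is.null(config_path)) {
    raw <- yaml::read_yaml(config_path)
    if (!is.null(raw$planted)) raw$planted <- dplyr::bind_rows(raw$planted)
    if (!is.null(raw$lines)) raw$lines <- dplyr::bind_rows(raw$lines)
    args <- raw
  }
  if (!is.null(seed)) args$rng_seed <- as.integer(seed)
  config <- do.call(array_sim_config, args)
  sim <- simulate_array(config)
  write_array_data(sim, out_dir)
}
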