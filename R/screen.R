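#' Expression filter: keep microRNAs above the log2 floor in every line
#'
#' A microRNA is retained only if, in every cell line, its signal before or
#' after treatment clears the log2 intensity floor. Replicates of a condition
#' are summarized by their mean log2 intensity first; under the default
#' `either_condition` rule the larger of the treated and control summaries
#' must exceed the floor, under `both_conditions` both must.
#'
#' @param norm Normalized long tibble from [normalize_log2()].
#' @param samples Sample sheet tibble.
#' @param criteria A [screen_criteria()].
#' @return Character vector of retained `mirna_id`s.
#' @export
filter_expressed <- function(norm, samples, criteria = screen_criteria()) {
  check_design(samples)
  cond <- dplyr::inner_join(norm, samples, by = "sample_id") |>
    dplyr::group_by(.data$mirna_id, .data$cell_line, .data$treatment) |>
    dplyr::summarise(log2_intensity = mean(.data$log2_intensity), .groups = "drop")
  per_line <- cond |>
    dplyr::group_by(.data$mirna_id, .data$cell_line) |>
    dplyr::summarise(
      stat = if (criteria$expression_rule == "either_condition") {
        max(.data$log2_intensity)
      } else {
        min(.data$log2_intensity)
      },
      .groups = "drop"
    )
  per_line |>
    dplyr::group_by(.data$mirna_id) |>
    dplyr::summarise(keep = all(.data$stat > criteria$intensity_floor_log2)) |>
    dplyr::filter(.data$keep) |>
    dplyr::pull("mirna_id")
}

#' Per-line treated/control fold changes
#'
#' For each microRNA and cell line, the log2 fold change is the mean log2
#' intensity of the treated samples minus that of the control samples
#' (replicates averaged in log2 space); the linear fold change is its
#' antilog.
#'
#' @inheritParams filter_expressed
#' @param line Optional single cell line; default all lines.
#' @return Tibble `mirna_id`, `cell_line`, `her2_status`, `log2_fc`,
#'   `fc_linear`.
#' @export
fold_changes <- function(norm, samples, line = NULL) {
  if (!is.null(line)) samples <- dplyr::filter(samples, .data$cell_line %in% line)
  check_design(samples)
  dplyr::inner_join(norm, samples, by = "sample_id") |>
    dplyr::group_by(.data$mirna_id, .data$cell_line, .data$her2_status) |>
    dplyr::summarise(
      log2_fc = mean(.data$log2_intensity[.data$treatment == "treated"]) -
        mean(.data$log2_intensity[.data$treatment == "control"]),
      .groups = "drop"
    ) |>
    dplyr::mutate(fc_linear = 2^.data$log2_fc)
}

#' Exclude microRNAs that respond in receptor-negative lines
#'
#' A candidate must be specific to the receptor-positive lines: any microRNA
#' whose fold change in ANY negative line exceeds `fc_threshold` or falls
#' below `down_threshold` is removed. Comparisons are strict, so a fold
#' change of exactly 1.5 is kept.
#'
#' @param fc Fold-change tibble from [fold_changes()] (must include the
#'   negative lines).
#' @param criteria A [screen_criteria()].
#' @return Character vector of surviving `mirna_id`s.
#' @export
exclude_negative_responders <- function(fc, criteria = screen_criteria()) {
  neg <- dplyr::filter(fc, .data$her2_status == "negative")
  if (nrow(neg) == 0) {
    abort("No receptor-negative lines in the fold-change table.",
          class = "mirscreen_design_error")
  }
  neg |>
    dplyr::group_by(.data$mirna_id) |>
    dplyr::summarise(changed = any(.data$fc_linear > criteria$fc_threshold |
                                     .data$fc_linear < criteria$down_threshold)) |>
    dplyr::filter(!.data$changed) |>
    dplyr::pull("mirna_id")
}

#' Relative fold change against the receptor-negative background
#'
#' For each microRNA and receptor-positive line, the log2 RFC is the
#' positive line's log2 fold change minus the arithmetic mean of the
#' negative lines' log2 fold changes; on the linear scale this is the
#' positive-line fold change divided by the geometric mean of the
#' negative-line fold changes. Averaging in log space keeps down-regulated
#' RFCs as positive ratios.
#'
#' @param fc Fold-change tibble from [fold_changes()] containing at least one
#'   positive and one negative line.
#' @return Tibble `mirna_id`, `cell_line`, `log2_rfc`, `rfc_linear` with one
#'   row per (microRNA, positive line).
#' @examples
#' fc <- tibble::tibble(
#'   mirna_id = "m", cell_line = c("P", "N1", "N2"),
#'   her2_status = c("positive", "negative", "negative"),
#'   log2_fc = log2(c(3, 1, 4)), fc_linear = c(3, 1, 4)
#' )
#' relative_fold_change(fc) # rfc_linear = 3 / sqrt(1 * 4) = 1.5
#' @export
relative_fold_change <- function(fc) {
  if (nrow(fc) == 0) {
    return(tibble(mirna_id = character(), cell_line = character(),
                  log2_rfc = numeric(), rfc_linear = numeric()))
  }
  if (any(fc$fc_linear <= 0) || any(!is.finite(fc$log2_fc))) {
    abort("Fold changes must be positive and finite.",
          class = "mirscreen_domain_error")
  }
  neg <- dplyr::filter(fc, .data$her2_status == "negative") |>
    dplyr::group_by(.data$mirna_id) |>
    dplyr::summarise(neg_mean_log2_fc = mean(.data$log2_fc))
  if (nrow(neg) == 0) {
    abort("Need at least one receptor-negative line to form an RFC.",
          class = "mirscreen_design_error")
  }
  dplyr::filter(fc, .data$her2_status == "positive") |>
    dplyr::inner_join(neg, by = "mirna_id") |>
    dplyr::transmute(
      mirna_id = .data$mirna_id, cell_line = .data$cell_line,
      log2_rfc = .data$log2_fc - .data$neg_mean_log2_fc,
      rfc_linear = 2^.data$log2_rfc
    )
}

#' Geometric-mean aggregation of per-line relative fold changes
#'
#' The cross-line summary RFC is the geometric mean of the per-positive-line
#' linear RFC values (equivalently the antilog of the mean log2 RFC). For a
#' pair this is `sqrt(x * y)`; reports print it to 4 decimals.
#'
#' @param rfc_values Numeric vector of positive linear RFC values.
#' @return The geometric mean, a single positive number.
#' @examples
#' mean_rfc(c(2.4300, 3.5825)) # 2.9505 to 4 decimals
#' @export
mean_rfc <- function(rfc_values) {
  if (length(rfc_values) == 0) {
    abort("`rfc_values` must be non-empty.", class = "mirscreen_domain_error")
  }
  if (any(rfc_values <= 0) || any(!is.finite(rfc_values))) {
    abort("RFC values must be positive and finite.",
          class = "mirscreen_domain_error")
  }
  2^mean(log2(rfc_values))
}

#' Run the four-step responsive-microRNA screen
#'
#' Applies, in order: (1) the log2 expression floor in every line
#' ([filter_expressed()]); (2) per-line fold changes ([fold_changes()]);
#' (3) exclusion of microRNAs with a more-than-threshold change in any
#' receptor-negative line ([exclude_negative_responders()]); (4) relative
#' fold changes in each receptor-positive line and their cross-line
#' geometric mean, thresholded into ranked up- and down-regulated lists
#' (strict comparisons, ranked by `|log2 RFC|` descending). The cross-line
#' lists admit a microRNA whenever its mean RFC passes the threshold, even
#' if a single per-line RFC does not.
#'
#' @inheritParams filter_expressed
#' @return An object of class `screen_report`; see [tidy.screen_report()]
#'   and [glance.screen_report()].
#' @examples
#' sim <- simulate_array(array_sim_config(
#'   n_mirnas = 50, noise_log2_sd = 0, low_expression_fraction = 0,
#'   planted = tibble::tibble(
#'     mirna_id = "miR-sim-0001",
#'     cell_line = c("SKBR3", "BT474"), log2_effect = 1.2
#'   ),
#'   rng_seed = 1
#' ))
#' rep <- screen_responsive(normalize_log2(sim$expression), sim$samples)
#' rep$cross_line
#' @export
screen_responsive <- function(norm, samples, criteria = screen_criteria()) {
  check_design(samples, require_both_statuses = TRUE)
  n_total <- dplyr::n_distinct(norm$mirna_id)
  expressed <- filter_expressed(norm, samples, criteria)
  fc <- fold_changes(norm, samples)
  survivors <- intersect(expressed,
                         exclude_negative_responders(fc, criteria))
  rfc <- relative_fold_change(dplyr::filter(fc, .data$mirna_id %in% survivors))

  if (nrow(rfc) == 0) {
    return(structure(
      list(
        criteria = criteria,
        counts = list(n_total = n_total, n_expressed = length(expressed),
                      n_after_negative_exclusion = length(survivors)),
        expressed = expressed, survivors = survivors, rfc = rfc,
        per_line = tibble(cell_line = character(), direction = character(),
                          rank = integer(), mirna_id = character(),
                          rfc_linear = numeric(), log2_rfc = numeric()),
        cross_line = tibble(direction = character(), rank = integer(),
                            mirna_id = character(), mean_rfc = numeric(),
                            log2_mean_rfc = numeric())
      ),
      class = "screen_report"
    ))
  }

  classify <- function(x) {
    dplyr::case_when(
      x > criteria$fc_threshold ~ "up",
      x < criteria$down_threshold ~ "down",
      TRUE ~ NA_character_
    )
  }
  per_line <- rfc |>
    dplyr::mutate(direction = classify(.data$rfc_linear)) |>
    dplyr::filter(!is.na(.data$direction)) |>
    dplyr::group_by(.data$cell_line, .data$direction) |>
    dplyr::arrange(dplyr::desc(abs(.data$log2_rfc)), .data$mirna_id,
                   .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("cell_line", "direction", "rank", "mirna_id",
                  "rfc_linear", "log2_rfc")

  cross_line <- rfc |>
    dplyr::group_by(.data$mirna_id) |>
    dplyr::summarise(mean_rfc = mean_rfc(.data$rfc_linear), .groups = "drop") |>
    dplyr::mutate(
      log2_mean_rfc = log2(.data$mean_rfc),
      direction = classify(.data$mean_rfc)
    ) |>
    dplyr::filter(!is.na(.data$direction)) |>
    dplyr::group_by(.data$direction) |>
    dplyr::arrange(dplyr::desc(abs(.data$log2_mean_rfc)), .data$mirna_id,
                   .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("direction", "rank", "mirna_id", "mean_rfc", "log2_mean_rfc")

  structure(
    list(
      criteria = criteria,
      counts = list(
        n_total = n_total,
        n_expressed = length(expressed),
        n_after_negative_exclusion = length(survivors)
      ),
      expressed = expressed,
      survivors = survivors,
      rfc = rfc,
      per_line = per_line,
      cross_line = cross_line
    ),
    class = "screen_report"
  )
}

#' @export
print.screen_report <- function(x, ...) {
  cat("<screen_report>\n")
  cat(sprintf("  %d microRNAs -> %d past expression floor -> %d after negative-line exclusion\n",
              x$counts$n_total, x$counts$n_expressed,
              x$counts$n_after_negative_exclusion))
  up <- dplyr::filter(x$cross_line, .data$direction == "up")
  dn <- dplyr::filter(x$cross_line, .data$direction == "down")
  cat(sprintf("  cross-line lists: %d up, %d down (mean RFC threshold %s)\n",
              nrow(up), nrow(dn), format(x$criteria$fc_threshold)))
  if (nrow(x$cross_line)) {
    print(dplyr::mutate(x$cross_line, mean_rfc = round(.data$mean_rfc, 4)), n = 10)
  }
  invisible(x)
}

check_design <- function(samples, require_both_statuses = FALSE) {
  need <- c("sample_id", "cell_line", "her2_status", "treatment")
  if (!all(need %in% names(samples))) {
    abort(paste0("Sample sheet must have columns: ", paste(need, collapse = ", ")),
          class = "mirscreen_metadata_error")
  }
  if (anyDuplicated(samples$sample_id)) {
    abort("Duplicate sample IDs.", class = "mirscreen_metadata_error")
  }
  by_line <- dplyr::group_by(samples, .data$cell_line) |>
    dplyr::summarise(ok = all(c("treated", "control") %in% .data$treatment))
  if (!all(by_line$ok)) {
    abort(paste0("Lines missing a treated or control sample: ",
                 paste(by_line$cell_line[!by_line$ok], collapse = ", ")),
          class = "mirscreen_design_error")
  }
  if (require_both_statuses &&
      !all(c("positive", "negative") %in% samples$her2_status)) {
    abort("Screening needs at least one positive and one negative line.",
          class = "mirscreen_design_error")
  }
  invisible(samples)
}
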