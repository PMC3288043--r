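#' Tidy a screen report
#'
#' Returns the ranked lists as one tibble, either the per-positive-line
#' lists or the cross-line geometric-mean list, with RFC values rounded to
#' 4 decimals in the `rfc` column (full precision kept alongside).
#'
#' @param x A `screen_report`.
#' @param which `"cross_line"` (default) or `"per_line"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.screen_report <- function(x, which = c("cross_line", "per_line"), ...) {
  which <- match.arg(which)
  if (which == "cross_line") {
    dplyr::transmute(
      x$cross_line,
      direction = .data$direction, rank = .data$rank, mirna_id = .data$mirna_id,
      rfc = round(.data$mean_rfc, 4), rfc_full = .data$mean_rfc
    )
  } else {
    dplyr::transmute(
      x$per_line,
      cell_line = .data$cell_line, direction = .data$direction,
      rank = .data$rank, mirna_id = .data$mirna_id,
      rfc = round(.data$rfc_linear, 4), rfc_full = .data$rfc_linear
    )
  }
}

#' One-row summary of a screen report
#'
#' @param x A `screen_report`.
#' @param ... Unused.
#' @return A one-row tibble with the stage counts and list sizes.
#' @export
glance.screen_report <- function(x, ...) {
  tibble(
    n_total = x$counts$n_total,
    n_expressed = x$counts$n_expressed,
    n_after_negative_exclusion = x$counts$n_after_negative_exclusion,
    n_up_cross_line = sum(x$cross_line$direction == "up"),
    n_down_cross_line = sum(x$cross_line$direction == "down")
  )
}

#' Tidy a cell-cycle fit
#'
#' @param x A `cellcycle_fit`.
#' @param ... Unused.
#' @return Tibble `phase`, `fraction`.
#' @export
tidy.cellcycle_fit <- function(x, ...) {
  tibble(phase = names(x$fractions), fraction = as.numeric(x$fractions))
}

#' One-row summary of a cell-cycle fit
#'
#' @param x A `cellcycle_fit`.
#' @param ... Unused.
#' @return A one-row tibble of the fitted peak parameters and diagnostics.
#' @export
glance.cellcycle_fit <- function(x, ...) {
  tibble(
    g1_mean = x$g1_mean, sigma = x$sigma, g2_broadening = x$g2_broadening,
    loglik = x$loglik, residual_rmse = x$residual_rmse,
    n_events = x$n_events, convergence = x$convergence
  )
}
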