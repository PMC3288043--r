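#' Screening criteria for the responsive-microRNA screen
#'
#' Bundles the thresholds of the four-step screen: the log2 expression floor
#' a microRNA must exceed in every cell line, the fold-change threshold used
#' both to exclude microRNAs that respond in receptor-negative lines and to
#' call up/down regulation on the relative fold change, and the rule deciding
#' whether the floor must be cleared in either or both of the treated and
#' control conditions.
#'
#' All comparisons in the screen are strict (`>` the floor, `>` the up
#' threshold, `<` the down threshold), so a fold change of exactly
#' `fc_threshold` is never excluded and never listed.
#'
#' @param intensity_floor_log2 Expression floor on the log2 scale. A microRNA
#'   is kept only if its signal exceeds this floor in every cell line
#'   (default 6).
#' @param fc_threshold Linear fold-change threshold for up-regulation and for
#'   negative-line exclusion; must be > 1 (default 1.5).
#' @param down_threshold Linear threshold for down-regulation; must be in
#'   (0, 1) (default `1 / fc_threshold`).
#' @param expression_rule `"either_condition"` (default) keeps a microRNA in a
#'   line when `max(treated, control)` clears the floor; `"both_conditions"`
#'   requires `min(treated, control)` to clear it.
#'
#' @return An object of class `screen_criteria` (a named list).
#' @examples
#' screen_criteria()
#' screen_criteria(fc_threshold = 2)
#' @export
screen_criteria <- function(intensity_floor_log2 = 6,
                            fc_threshold = 1.5,
                            down_threshold = 1 / fc_threshold,
                            expression_rule = c("either_condition", "both_conditions")) {
  expression_rule <- match.arg(expression_rule)
  if (!is.numeric(fc_threshold) || fc_threshold <= 1) {
    abort("`fc_threshold` must be a number greater than 1.")
  }
  if (!is.numeric(down_threshold) || down_threshold <= 0 || down_threshold >= 1) {
    abort("`down_threshold` must lie strictly between 0 and 1.")
  }
  structure(
    list(
      intensity_floor_log2 = intensity_floor_log2,
      fc_threshold = fc_threshold,
      down_threshold = down_threshold,
      expression_rule = expression_rule
    ),
    class = "screen_criteria"
  )
}

#' @export
print.screen_criteria <- function(x, ...) {
  cat("<screen_criteria>\n")
  cat("  log2 expression floor :", x$intensity_floor_log2, "\n")
  cat("  up threshold (linear) :", x$fc_threshold, "\n")
  cat("  down threshold        :", signif(x$down_threshold, 6), "\n")
  cat("  expression rule       :", x$expression_rule, "\n")
  invisible(x)
}
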