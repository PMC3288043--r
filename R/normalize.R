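#' Quantile-normalize and log2-transform an expression table
#'
#' Forces every sample to share one empirical intensity distribution by
#' rank-wise replacement with cross-sample rank means (ties receive the mean
#' of the tied ranks' target values), then log2-transforms. Normalization is
#' performed on the linear scale via `limma::normalizeQuantiles()`; with a
#' single sample it is the identity and only the log2 transform applies.
#' Non-positive intensities are clipped at 1 beforehand so the logarithm is
#' defined.
#'
#' After normalization the sorted values of any two samples are identical.
#'
#' @param expression Long tibble with columns `mirna_id`, `sample_id`,
#'   `intensity` (linear scale), e.g. from [simulate_array()] or
#'   [read_expression_matrix()].
#' @return A long tibble `mirna_id`, `sample_id`, `log2_intensity`.
#' @examples
#' raw <- tibble::tibble(
#'   mirna_id = rep(c("a", "b", "c"), 2),
#'   sample_id = rep(c("s1", "s2"), each = 3),
#'   intensity = c(2, 4, 8, 16, 32, 64)
#' )
#' normalize_log2(raw) # both samples become log2(c(9, 18, 36))
#' @export
normalize_log2 <- function(expression) {
  stopifnot(all(c("mirna_id", "sample_id", "intensity") %in% names(expression)))
  if (nrow(expression) == 0) {
    abort("Cannot normalize an empty expression table.",
          class = "mirscreen_format_error")
  }
  wide <- tidyr::pivot_wider(
    expression[, c("mirna_id", "sample_id", "intensity")],
    names_from = "sample_id", values_from = "intensity"
  )
  mat <- as.matrix(wide[, -1, drop = FALSE])
  rownames(mat) <- wide$mirna_id
  mat <- pmax(mat, 1)
  norm <- if (ncol(mat) > 1) limma::normalizeQuantiles(mat, ties = TRUE) else mat
  out <- as_tibble(log2(norm))
  out$mirna_id <- wide$mirna_id
  tidyr::pivot_longer(out, -"mirna_id", names_to = "sample_id",
                      values_to = "log2_intensity")
}
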