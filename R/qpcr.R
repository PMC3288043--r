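#' Relative quantification from Cq values (delta-delta-Cq)
#'
#' Normalizes a target's quantification cycle against one or more reference
#' genes and expresses each sample's quantity relative to a calibrator
#' sample. For each sample, `dCq = mean(target Cq) - mean over references of
#' the per-reference mean Cq`; the quantity ratio is
#' `efficiency^-(dCq_sample - dCq_calibrator)`. Averaging reference Cq means
#' arithmetically is equivalent to a geometric mean of reference quantities.
#' The calibrator's own ratio is exactly 1.
#'
#' @param cq Long tibble with columns `sample_id`, `gene`, `cq` (one row per
#'   replicate well).
#' @param target Target gene name.
#' @param references Character vector of reference gene names.
#' @param calibrator `sample_id` of the calibrator.
#' @param efficiency Amplification efficiency as a fold change per cycle;
#'   2 assumes perfect doubling.
#' @return Tibble `sample_id`, `delta_cq`, `quantity_ratio`, `calibrator_id`.
#' @examples
#' cq <- tibble::tibble(
#'   sample_id = rep(c("s", "cal"), each = 2),
#'   gene = rep(c("T", "R"), 2),
#'   cq = c(20, 22, 24, 22)
#' )
#' relative_quantity(cq, "T", "R", "cal") # ratio 16 for sample "s"
#' @export
relative_quantity <- function(cq, target, references, calibrator, efficiency = 2) {
  stopifnot(all(c("sample_id", "gene", "cq") %in% names(cq)))
  if (any(!is.finite(cq$cq))) {
    abort("All Cq values must be finite.", class = "mirscreen_domain_error")
  }
  if (!calibrator %in% cq$sample_id) {
    abort("Calibrator sample not present in the Cq table.",
          class = "mirscreen_contract_error")
  }
  dcq_one <- function(tbl, who) {
    t_cq <- tbl$cq[tbl$gene == target]
    if (length(t_cq) == 0) {
      abort(paste0("Sample ", who, " has no Cq for target ", target, "."),
            class = "mirscreen_contract_error")
    }
    ref_means <- purrr::map_dbl(references, function(g) {
      r <- tbl$cq[tbl$gene == g]
      if (length(r) == 0) {
        abort(paste0("Sample ", who, " has no Cq for reference ", g, "."),
              class = "mirscreen_contract_error")
      }
      mean(r)
    })
    mean(t_cq) - mean(ref_means)
  }
  dcq <- cq |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::group_modify(~ tibble(delta_cq = dcq_one(.x, .y$sample_id))) |>
    dplyr::ungroup()
  dcq_cal <- dcq$delta_cq[dcq$sample_id == calibrator]
  dplyr::mutate(
    dcq,
    quantity_ratio = efficiency^(-(.data$delta_cq - dcq_cal)),
    calibrator_id = calibrator
  )
}
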