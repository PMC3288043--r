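#' Viability ratio and percent growth inhibition
#'
#' The WST-1 readout of the treated wells is expressed as the ratio of the
#' mean treated absorbance to the mean control absorbance; percent
#' inhibition is `100 * (1 - ratio)`. Replicate absorbances are averaged
#' before the ratio is formed.
#'
#' @param treated,control Numeric vectors of positive A450 replicates.
#' @return One-row tibble `ratio`, `inhibition_pct`, `n_treated`, `n_control`.
#' @examples
#' viability_inhibition(c(0.63, 0.63), c(1, 1)) # 37% inhibition
#' @export
viability_inhibition <- function(treated, control) {
  if (any(treated <= 0) || any(control <= 0)) {
    abort("Absorbances must be positive.", class = "mirscreen_domain_error")
  }
  ratio <- mean(treated) / mean(control)
  tibble(ratio = ratio, inhibition_pct = 100 * (1 - ratio),
         n_treated = length(treated), n_control = length(control))
}

#' Cross-line mean of per-line growth inhibitions
#'
#' Per-line inhibition percentages are combined by their arithmetic mean,
#' e.g. 56% and 24% give 40%.
#'
#' @param inhibition_pcts Numeric vector of per-line percent inhibitions.
#' @return A single number.
#' @export
mean_inhibition <- function(inhibition_pcts) {
  if (length(inhibition_pcts) == 0) {
    abort("Need at least one inhibition value.", class = "mirscreen_domain_error")
  }
  mean(inhibition_pcts)
}

#' Annexin-V positive fraction
#'
#' Fraction of events whose fluorescence intensity strictly exceeds the
#' gating threshold — the percentage of apoptotic cells among all cells,
#' reduced to a single-channel gate.
#'
#' @param intensities Numeric vector of per-event intensities.
#' @param threshold Gate position.
#' @return One-row tibble `positive_fraction`, `n_events`, `threshold`.
#' @export
annexin_fraction <- function(intensities, threshold) {
  if (length(intensities) == 0) {
    abort("No events supplied.", class = "mirscreen_domain_error")
  }
  tibble(
    positive_fraction = mean(intensities > threshold),
    n_events = length(intensities),
    threshold = threshold
  )
}

#' Unpaired pooled-variance Student t test
#'
#' Two-sided Student t test with pooled variance (`df = n_a + n_b - 2`),
#' delegating to `stats::t.test(var.equal = TRUE)`. Degenerate inputs that
#' the underlying routine rejects are resolved by the limit behaviour: zero
#' pooled variance with equal means gives `t = 0, p = 1`; zero pooled
#' variance with unequal means gives the `p -> 0` limit and a warning.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return One-row tibble `t`, `df`, `p_value`.
#' @examples
#' unpaired_t_test(c(1, 2, 3), c(2, 3, 4))
#' @export
unpaired_t_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    abort("Each group needs at least 2 observations.",
          class = "mirscreen_domain_error")
  }
  pooled_var <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  df <- length(a) + length(b) - 2
  if (pooled_var == 0) {
    if (mean(a) == mean(b)) {
      return(tibble(t = 0, df = df, p_value = 1))
    }
    warn("Zero within-group variance with unequal means; p-value is the 0 limit.")
    return(tibble(t = sign(mean(a) - mean(b)) * Inf, df = df, p_value = 0))
  }
  ht <- stats::t.test(a, b, var.equal = TRUE)
  tibble(t = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value)
}

#' Dual-luciferase repression estimate
#'
#' Each replicate's firefly luminescence is normalized against its renilla
#' internal control; the percent repression of the chosen oligo relative to
#' the non-targeting reference oligo on the same construct is
#' `100 * (1 - mean(oligo) / mean(reference))`, with a pooled-variance t
#' test on the normalized activities.
#'
#' @param measurements Tibble with columns `construct`, `oligo`, `firefly`,
#'   `renilla` (one row per replicate), e.g. from [simulate_luciferase()].
#' @param construct Construct to analyse (default `"wt"`).
#' @param oligo Oligo whose repression is estimated (default `"mirna"`).
#' @param reference_oligo Reference group (default `"ncRNA"`).
#' @return One-row tibble `construct`, `oligo`, `percent_repression`,
#'   `p_value`, `n_oligo`, `n_reference`.
#' @export
luciferase_repression <- function(measurements, construct = "wt",
                                  oligo = "mirna", reference_oligo = "ncRNA") {
  stopifnot(all(c("construct", "oligo", "firefly", "renilla") %in% names(measurements)))
  if (any(measurements$firefly <= 0) || any(measurements$renilla <= 0)) {
    abort("Luminescences must be positive.", class = "mirscreen_domain_error")
  }
  on_construct <- dplyr::filter(measurements, .data$construct == !!construct)
  grp <- dplyr::mutate(on_construct, activity = .data$firefly / .data$renilla)
  act_oligo <- grp$activity[grp$oligo == oligo]
  act_ref <- grp$activity[grp$oligo == reference_oligo]
  if (length(act_ref) == 0) {
    abort(paste0("No measurements for reference oligo ", reference_oligo,
                 " on construct ", construct, "."),
          class = "mirscreen_contract_error")
  }
  if (length(act_oligo) == 0) {
    abort(paste0("No measurements for oligo ", oligo, " on construct ",
                 construct, "."), class = "mirscreen_contract_error")
  }
  p <- if (length(act_oligo) >= 2 && length(act_ref) >= 2) {
    unpaired_t_test(act_oligo, act_ref)$p_value
  } else {
    NA_real_
  }
  tibble(
    construct = construct, oligo = oligo,
    percent_repression = 100 * (1 - mean(act_oligo) / mean(act_ref)),
    p_value = p, n_oligo = length(act_oligo), n_reference = length(act_ref)
  )
}
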