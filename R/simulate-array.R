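#' Configuration for the synthetic microRNA array experiment
#'
#' Describes an eight-sample two-factor design: each cell line contributes one
#' treated and one control array (replicates optional), and microRNA log2
#' intensities are built additively from a per-microRNA baseline, a
#' per-(microRNA, line) offset, a treatment effect restricted to the lines it
#' was planted in, and Gaussian measurement noise. Stored intensities are
#' linear (`2^log2`), emulating background-subtracted feature medians.
#'
#' The default design mirrors a trastuzumab-response experiment: two
#' HER2-positive lines (SKBR3, BT474) and two HER2-negative lines (MCF7,
#' MDA-MB-231), treated at 4 ug/ml for 144 h versus vehicle control, one
#' array per condition.
#'
#' @param n_mirnas Number of microRNA features (default 200).
#' @param lines Data frame with columns `cell_line` and `her2_status`
#'   (`"positive"`/`"negative"`); default the four-line design above.
#' @param baseline_log2_mean,baseline_log2_sd Normal distribution of expressed
#'   baselines on the log2 scale (defaults 9 and 1.2).
#' @param noise_log2_sd Measurement noise sd in log2 units (default 0.1).
#' @param line_effect_log2_sd Sd of the per-(microRNA, line) offset shared by
#'   both conditions of a line (default 1). It cancels in fold changes but
#'   makes same-line samples correlate, as real profiles do.
#' @param treatment_effect_log2_sd Sd of a random treatment effect added to
#'   every (microRNA, line) pair on top of planted effects (default 0).
#' @param planted Data frame with columns `mirna_id`, `cell_line`,
#'   `log2_effect` giving deterministic treatment effects, or `NULL`.
#' @param low_expression_fraction Fraction of microRNAs whose baseline is
#'   drawn below the log2 floor of 6 in all samples (default 0.3).
#' @param replicates Arrays per (line, condition); default 1, the published
#'   replicate-free design.
#' @param rng_seed Integer seed; identical configs and seeds give identical
#'   output.
#'
#' @return An object of class `array_sim_config`.
#' @seealso [simulate_array()]
#' @export
array_sim_config <- function(n_mirnas = 200,
                             lines = default_cell_lines(),
                             baseline_log2_mean = 9,
                             baseline_log2_sd = 1.2,
                             noise_log2_sd = 0.1,
                             line_effect_log2_sd = 1,
                             treatment_effect_log2_sd = 0,
                             planted = NULL,
                             low_expression_fraction = 0.3,
                             replicates = 1,
                             rng_seed = 1L) {
  if (!is.numeric(n_mirnas) || n_mirnas < 1) {
    abort("`n_mirnas` must be a positive integer.", class = "mirscreen_config_error")
  }
  lines <- as_tibble(lines)
  if (nrow(lines) == 0 || !all(c("cell_line", "her2_status") %in% names(lines))) {
    abort("`lines` must be a non-empty data frame with columns `cell_line` and `her2_status`.",
          class = "mirscreen_config_error")
  }
  if (!all(lines$her2_status %in% c("positive", "negative"))) {
    abort("`her2_status` must be \"positive\" or \"negative\".",
          class = "mirscreen_config_error")
  }
  for (s in c(baseline_log2_sd, noise_log2_sd, line_effect_log2_sd, treatment_effect_log2_sd)) {
    if (s < 0) abort("Standard deviations must be nonnegative.", class = "mirscreen_config_error")
  }
  if (low_expression_fraction < 0 || low_expression_fraction > 1) {
    abort("`low_expression_fraction` must lie in [0, 1].", class = "mirscreen_config_error")
  }
  if (replicates < 1) {
    abort("`replicates` must be at least 1.", class = "mirscreen_config_error")
  }
  mirna_ids <- sprintf("miR-sim-%04d", seq_len(n_mirnas))
  if (!is.null(planted)) {
    planted <- as_tibble(planted)
    stopifnot(all(c("mirna_id", "cell_line", "log2_effect") %in% names(planted)))
    bad_mir <- setdiff(planted$mirna_id, mirna_ids)
    bad_line <- setdiff(planted$cell_line, lines$cell_line)
    if (length(bad_mir) || length(bad_line)) {
      abort(paste0("Planted effects refer to unknown microRNAs or lines: ",
                   paste(c(bad_mir, bad_line), collapse = ", ")),
            class = "mirscreen_config_error")
    }
    if (any(!is.finite(planted$log2_effect))) {
      abort("Planted effects must be finite.", class = "mirscreen_config_error")
    }
  }
  structure(
    list(
      n_mirnas = as.integer(n_mirnas), mirna_ids = mirna_ids, lines = lines,
      baseline_log2_mean = baseline_log2_mean, baseline_log2_sd = baseline_log2_sd,
      noise_log2_sd = noise_log2_sd, line_effect_log2_sd = line_effect_log2_sd,
      treatment_effect_log2_sd = treatment_effect_log2_sd,
      planted = planted, low_expression_fraction = low_expression_fraction,
      replicates = as.integer(replicates), rng_seed = as.integer(rng_seed)
    ),
    class = "array_sim_config"
  )
}

#' Default four-line HER2-mixed panel
#'
#' @return A tibble with columns `cell_line`, `her2_status`.
#' @export
default_cell_lines <- function() {
  tibble(
    cell_line = c("SKBR3", "BT474", "MCF7", "MDA-MB-231"),
    her2_status = c("positive", "positive", "negative", "negative")
  )
}

#' Simulate a microRNA expression array experiment with planted truth
#'
#' Draws a linear-intensity expression table under the model described in
#' [array_sim_config()] together with the sample sheet and a ground-truth
#' table recording, for every (microRNA, line), the true log2 treatment
#' effect and whether the microRNA is expressed above the floor.
#'
#' @param config An [array_sim_config()].
#' @return A list of class `mir_array_sim` with elements
#'   * `expression`: long tibble `mirna_id`, `sample_id`, `intensity` (linear);
#'   * `samples`: tibble `sample_id`, `cell_line`, `her2_status`, `treatment`,
#'     `dose_ug_ml`, `hours`;
#'   * `truth`: tibble `mirna_id`, `cell_line`, `true_log2_effect`,
#'     `expressed`.
#' @examples
#' sim <- simulate_array(array_sim_config(n_mirnas = 50, rng_seed = 7))
#' dplyr::count(sim$samples, cell_line, treatment)
#' @export
simulate_array <- function(config) {
  stopifnot(inherits(config, "array_sim_config"))
  withr::with_seed(config$rng_seed, simulate_array_impl(config))
}

simulate_array_impl <- function(config) {
  n <- config$n_mirnas
  lines <- config$lines
  mirna_ids <- config$mirna_ids

  n_low <- round(config$low_expression_fraction * n)
  low_idx <- if (n_low > 0) sample.int(n, n_low) else integer(0)
  baseline <- rnorm(n, config$baseline_log2_mean, config$baseline_log2_sd)
  # low-expression features sit safely below the canonical floor of 6
  if (n_low > 0) baseline[low_idx] <- runif(n_low, 2, 5.5)
  expressed <- baseline > 6
  if (n_low > 0) expressed[low_idx] <- FALSE

  n_lines <- nrow(lines)
  line_offset <- matrix(rnorm(n * n_lines, 0, config$line_effect_log2_sd),
                        nrow = n, ncol = n_lines)
  effect <- matrix(rnorm(n * n_lines, 0, config$treatment_effect_log2_sd),
                   nrow = n, ncol = n_lines,
                   dimnames = list(mirna_ids, lines$cell_line))
  if (!is.null(config$planted)) {
    for (k in seq_len(nrow(config$planted))) {
      effect[config$planted$mirna_id[k], config$planted$cell_line[k]] <-
        effect[config$planted$mirna_id[k], config$planted$cell_line[k]] +
        config$planted$log2_effect[k]
    }
  }

  samples <- tidyr::expand_grid(
    lines,
    treatment = c("treated", "control"),
    replicate = seq_len(config$replicates)
  )
  samples$sample_id <- sprintf(
    "%s_%s%s", samples$cell_line,
    ifelse(samples$treatment == "treated", "tras", "ctrl"),
    ifelse(config$replicates > 1, paste0("_r", samples$replicate), "")
  )
  samples <- dplyr::transmute(
    samples,
    sample_id = .data$sample_id, cell_line = .data$cell_line,
    her2_status = .data$her2_status, treatment = .data$treatment,
    dose_ug_ml = ifelse(.data$treatment == "treated", 4, 0),
    hours = 144
  )

  cols <- purrr::pmap(samples, function(sample_id, cell_line, her2_status,
                                        treatment, dose_ug_ml, hours) {
    j <- match(cell_line, lines$cell_line)
    log2_val <- baseline + line_offset[, j] +
      (treatment == "treated") * effect[, j] +
      rnorm(n, 0, config$noise_log2_sd)
    2^log2_val
  })
  expression <- tibble(
    mirna_id = rep(mirna_ids, times = nrow(samples)),
    sample_id = rep(samples$sample_id, each = n),
    intensity = as.numeric(unlist(cols, use.names = FALSE))
  )

  truth <- tidyr::expand_grid(mirna_id = mirna_ids, cell_line = lines$cell_line)
  truth$true_log2_effect <- effect[cbind(truth$mirna_id, truth$cell_line)]
  truth$expressed <- expressed[match(truth$mirna_id, mirna_ids)]

  structure(list(expression = expression, samples = samples, truth = truth),
            class = "mir_array_sim")
}

#' @export
print.mir_array_sim <- function(x, ...) {
  cat("<mir_array_sim> ", dplyr::n_distinct(x$expression$mirna_id),
      " microRNAs x ", nrow(x$samples), " samples\n", sep = "")
  print(x$samples, n = 4)
  invisible(x)
}
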