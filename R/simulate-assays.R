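#' Configuration for the downstream assay simulators
#'
#' One config drives four simulators: dual-luciferase reporter replicates,
#' propidium-iodide cell-cycle histograms, qPCR Cq tables and WST-1
#' viability absorbances, and Annexin-V event labels. Sub-stream seeds are
#' derived deterministically from `rng_seed`, one per assay.
#'
#' @param luciferase_true_repression True fractional repression of the
#'   wild-type reporter by the targeting oligo, in `[0, 1)` (default 0.27).
#' @param luciferase_cv Coefficient of variation of the multiplicative
#'   (log-normal) noise on each luminescence reading (default 0.05).
#' @param replicates Replicates per assay group (default 3).
#' @param cellcycle_true_fractions Length-3 vector `(g1, s, g2m)` summing to 1
#'   (default `c(0.6, 0.3, 0.1)`).
#' @param cellcycle_events Number of cells in the DNA-content histogram
#'   (default 10000).
#' @param cellcycle_g1_mean,cellcycle_cv G1 peak position in DNA-content
#'   units and its coefficient of variation (defaults 200 and 0.03); the G2/M
#'   peak sits at twice the G1 mean.
#' @param cellcycle_g2_broadening Multiplier on the G1 sd for the G2/M peak
#'   (default 1.15).
#' @param viability_true_inhibition True fractional growth inhibition of the
#'   treated wells, in `[0, 1)` (default 0.4).
#' @param viability_cv CV of the multiplicative noise on A450 (default 0.05).
#' @param apoptosis_true_fraction True Annexin-positive fraction (default 0.147).
#' @param apoptosis_events Number of flow events (default 10000).
#' @param cq_true_ratio True target quantity of the sample relative to the
#'   calibrator (default 2).
#' @param cq_noise_sd Additive sd on each Cq replicate, in cycles (default 0.15).
#' @param rng_seed Integer seed.
#'
#' @return An object of class `assay_sim_config`.
#' @export
assay_sim_config <- function(luciferase_true_repression = 0.27,
                             luciferase_cv = 0.05,
                             replicates = 3,
                             cellcycle_true_fractions = c(g1 = 0.6, s = 0.3, g2m = 0.1),
                             cellcycle_events = 10000,
                             cellcycle_g1_mean = 200,
                             cellcycle_cv = 0.03,
                             cellcycle_g2_broadening = 1.15,
                             viability_true_inhibition = 0.4,
                             viability_cv = 0.05,
                             apoptosis_true_fraction = 0.147,
                             apoptosis_events = 10000,
                             cq_true_ratio = 2,
                             cq_noise_sd = 0.15,
                             rng_seed = 1L) {
  if (luciferase_true_repression < 0 || luciferase_true_repression >= 1) {
    abort("`luciferase_true_repression` must lie in [0, 1).",
          class = "mirscreen_config_error")
  }
  if (viability_true_inhibition < 0 || viability_true_inhibition >= 1) {
    abort("`viability_true_inhibition` must lie in [0, 1).",
          class = "mirscreen_config_error")
  }
  if (apoptosis_true_fraction < 0 || apoptosis_true_fraction > 1) {
    abort("`apoptosis_true_fraction` must lie in [0, 1].",
          class = "mirscreen_config_error")
  }
  f <- cellcycle_true_fractions
  if (length(f) != 3 || any(f < 0) || abs(sum(f) - 1) > 1e-9) {
    abort("`cellcycle_true_fractions` must be 3 nonnegative numbers summing to 1.",
          class = "mirscreen_config_error")
  }
  if (replicates < 1) abort("`replicates` must be >= 1.", class = "mirscreen_config_error")
  if (cellcycle_events < 1) {
    abort("`cellcycle_events` must be >= 1.", class = "mirscreen_config_error")
  }
  if (luciferase_cv < 0 || viability_cv < 0 || cq_noise_sd < 0) {
    abort("Noise scales must be nonnegative.", class = "mirscreen_config_error")
  }
  if (cq_true_ratio <= 0) abort("`cq_true_ratio` must be positive.",
                                class = "mirscreen_config_error")
  structure(
    list(
      luciferase_true_repression = luciferase_true_repression,
      luciferase_cv = luciferase_cv,
      replicates = as.integer(replicates),
      cellcycle_true_fractions = setNames(as.numeric(f), c("g1", "s", "g2m")),
      cellcycle_events = as.integer(cellcycle_events),
      cellcycle_g1_mean = cellcycle_g1_mean,
      cellcycle_cv = cellcycle_cv,
      cellcycle_g2_broadening = cellcycle_g2_broadening,
      viability_true_inhibition = viability_true_inhibition,
      viability_cv = viability_cv,
      apoptosis_true_fraction = apoptosis_true_fraction,
      apoptosis_events = as.integer(apoptosis_events),
      cq_true_ratio = cq_true_ratio,
      cq_noise_sd = cq_noise_sd,
      rng_seed = as.integer(rng_seed)
    ),
    class = "assay_sim_config"
  )
}

# log-normal multiplier with unit mean and the requested CV
lnorm_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(rnorm(n, -sdlog^2 / 2, sdlog))
}

#' Simulate dual-luciferase reporter measurements
#'
#' For each construct x oligo cell, draws `replicates` firefly/renilla pairs.
#' Against the non-targeting control oligo, the targeting oligo represses the
#' wild-type construct's expected firefly/renilla ratio by
#' `luciferase_true_repression`; single-site mutants (`mut1`, `mut2`) retain
#' half of that repression, the double mutant (`mut1+2`) and the empty vector
#' none. Noise is multiplicative log-normal with the configured CV on both
#' luminescences.
#'
#' @param config An [assay_sim_config()].
#' @param constructs Construct labels to simulate (default all five).
#' @return A tibble `construct`, `oligo`, `replicate`, `firefly`, `renilla`.
#' @examples
#' simulate_luciferase(assay_sim_config(luciferase_cv = 0, rng_seed = 2))
#' @export
simulate_luciferase <- function(config,
                                constructs = c("wt", "mut1", "mut2", "mut1+2", "empty")) {
  stopifnot(inherits(config, "assay_sim_config"))
  withr::with_seed(config$rng_seed + 11L, {
    r <- config$luciferase_true_repression
    site_frac <- c(wt = 1, mut1 = 0.5, mut2 = 0.5, `mut1+2` = 0, empty = 0)
    unknown <- setdiff(constructs, names(site_frac))
    if (length(unknown)) {
      abort(paste0("Unknown constructs: ", paste(unknown, collapse = ", ")),
            class = "mirscreen_config_error")
    }
    grid <- tidyr::expand_grid(
      construct = constructs,
      oligo = c("ncRNA", "mirna"),
      replicate = seq_len(config$replicates)
    )
    renilla_base <- 1e5
    firefly_base <- 2e5
    grid$renilla <- renilla_base * lnorm_noise(nrow(grid), config$luciferase_cv)
    expected <- firefly_base *
      ifelse(grid$oligo == "mirna", 1 - r * site_frac[grid$construct], 1)
    grid$firefly <- grid$renilla / renilla_base * expected *
      lnorm_noise(nrow(grid), config$luciferase_cv)
    grid[, c("construct", "oligo", "replicate", "firefly", "renilla")]
  })
}

#' Simulate a propidium-iodide DNA-content histogram
#'
#' Events are drawn from a three-component mixture: G1 cells at
#' `Normal(mu, sigma)`, G2/M cells at `Normal(2 mu, sigma * broadening)`, and
#' S-phase cells uniform on `(mu, 2 mu)` convolved with `Normal(0, sigma)` —
#' the same model [fit_cell_cycle()] estimates.
#'
#' @param config An [assay_sim_config()].
#' @param bin_width Histogram bin width in DNA-content units (default
#'   `mu / 50`).
#' @return A tibble of class `cellcycle_histogram` with columns `dna_content`
#'   (bin centers) and `count`; bin counts sum to `cellcycle_events`. The
#'   component draw is stored in attribute `true_fractions`.
#' @export
simulate_cell_cycle <- function(config, bin_width = NULL) {
  stopifnot(inherits(config, "assay_sim_config"))
  withr::with_seed(config$rng_seed + 23L, {
    n <- config$cellcycle_events
    mu <- config$cellcycle_g1_mean
    sigma <- mu * config$cellcycle_cv
    comp <- sample(c("g1", "s", "g2m"), n, replace = TRUE,
                   prob = config$cellcycle_true_fractions)
    x <- numeric(n)
    x[comp == "g1"] <- rnorm(sum(comp == "g1"), mu, sigma)
    x[comp == "g2m"] <- rnorm(sum(comp == "g2m"), 2 * mu,
                              sigma * config$cellcycle_g2_broadening)
    ns <- sum(comp == "s")
    x[comp == "s"] <- runif(ns, mu, 2 * mu) + rnorm(ns, 0, sigma)
    bin_width <- bin_width %||% (mu / 50)
    breaks <- seq(floor(min(x) / bin_width) * bin_width,
                  max(x) + bin_width, by = bin_width)
    h <- graphics::hist(x, breaks = breaks, plot = FALSE)
    out <- tibble(dna_content = h$mids, count = h$counts)
    attr(out, "true_fractions") <- config$cellcycle_true_fractions
    class(out) <- c("cellcycle_histogram", class(out))
    out
  })
}

#' Simulate the qPCR, viability and apoptosis panel
#'
#' Generates (i) a long Cq table for one target and one reference gene in a
#' sample and a calibrator, where the sample's target sits
#' `log2(cq_true_ratio)` cycles below the calibrator's; (ii) treated and
#' control A450 absorbance replicates whose expected ratio is
#' `1 - viability_true_inhibition`; and (iii) Annexin-V fluorescence
#' intensities from a two-component log-normal mixture with the configured
#' positive fraction.
#'
#' @param config An [assay_sim_config()].
#' @return A list with elements `cq` (tibble `sample_id`, `gene`, `role`,
#'   `cq`), `viability` (tibble `condition`, `replicate`, `a450`), and
#'   `apoptosis` (list with `intensities`, `threshold`, `true_fraction`).
#' @export
simulate_assay_panel <- function(config) {
  stopifnot(inherits(config, "assay_sim_config"))
  reps <- config$replicates

  cq <- withr::with_seed(config$rng_seed + 31L, {
    base_target <- 24
    base_ref <- 20
    tidyr::expand_grid(
      sample_id = c("sample", "calibrator"),
      gene = c("TARGET", "REF"),
      replicate = seq_len(reps)
    ) |>
      dplyr::mutate(
        role = ifelse(.data$gene == "TARGET", "target", "reference"),
        cq = dplyr::case_when(
          .data$gene == "TARGET" & .data$sample_id == "sample" ~
            base_target - log2(config$cq_true_ratio),
          .data$gene == "TARGET" ~ base_target,
          TRUE ~ base_ref
        ) + rnorm(dplyr::n(), 0, config$cq_noise_sd)
      ) |>
      dplyr::select("sample_id", "gene", "role", "cq")
  })

  viability <- withr::with_seed(config$rng_seed + 37L, {
    a_ctrl <- 1.2
    tibble(
      condition = rep(c("treated", "control"), each = reps),
      replicate = rep(seq_len(reps), 2),
      a450 = a_ctrl *
        rep(c(1 - config$viability_true_inhibition, 1), each = reps) *
        lnorm_noise(2 * reps, config$viability_cv)
    )
  })

  apoptosis <- withr::with_seed(config$rng_seed + 41L, {
    n <- config$apoptosis_events
    positive <- runif(n) < config$apoptosis_true_fraction
    # well-separated log-normal modes around 10^2 (negative) and 10^4 (positive)
    intensities <- 10^(rnorm(n, ifelse(positive, 4, 2), 0.3))
    list(intensities = intensities, threshold = 10^3,
         true_fraction = config$apoptosis_true_fraction)
  })

  list(cq = cq, viability = viability, apoptosis = apoptosis)
}
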