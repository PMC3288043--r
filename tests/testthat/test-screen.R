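test_that("quantile normalization reproduces hand-computed rank means and log2", {
  raw <- tibble::tibble(
    mirna_id = rep(c("a", "b", "c"), 2),
    sample_id = rep(c("s1", "s2"), each = 3),
    intensity = c(2, 4, 8, 16, 32, 64)
  )
  norm <- normalize_log2(raw)
  expect_equal(norm$log2_intensity[norm$sample_id == "s1"], log2(c(9, 18, 36)))
  expect_equal(norm$log2_intensity[norm$sample_id == "s2"], log2(c(9, 18, 36)))
})

test_that("quantile normalization matches an independent rank-mean oracle on random matrices", {
  set.seed(101)
  for (i in 1:5) {
    mat <- matrix(2^rnorm(60, 8, 2), nrow = 12,
                  dimnames = list(paste0("m", 1:12), paste0("s", 1:5)))
    long <- tibble::tibble(
      mirna_id = rep(rownames(mat), ncol(mat)),
      sample_id = rep(colnames(mat), each = nrow(mat)),
      intensity = as.numeric(mat)
    )
    norm <- tidyr::pivot_wider(normalize_log2(long), names_from = "sample_id",
                               values_from = "log2_intensity")
    expect_equal(as.matrix(norm[, -1]), log2(oracle_quantile_normalize(mat)),
                 ignore_attr = TRUE)
  }
})

test_that("identical columns are a fixed point and single columns pass through", {
  raw <- tibble::tibble(
    mirna_id = rep(c("a", "b"), 2),
    sample_id = rep(c("s1", "s2"), each = 2),
    intensity = c(4, 16, 4, 16)
  )
  norm <- normalize_log2(raw)
  expect_equal(sort(norm$log2_intensity[norm$sample_id == "s1"]), c(2, 4))
  expect_equal(sort(norm$log2_intensity[norm$sample_id == "s2"]), c(2, 4))
  one <- normalize_log2(raw[raw$sample_id == "s1", ])
  expect_equal(one$log2_intensity, c(2, 4))
  expect_error(normalize_log2(raw[0, ]), class = "mirscreen_format_error")
})

test_that("normalization gives every sample identical sorted values and commutes with column permutation", {
  sim <- simulate_array(array_sim_config(n_mirnas = 60, rng_seed = 13))
  norm <- normalize_log2(sim$expression)
  by_sample <- split(norm$log2_intensity, norm$sample_id)
  sorted <- lapply(by_sample, sort)
  for (k in seq_along(sorted)[-1]) expect_equal(sorted[[k]], sorted[[1]], ignore_attr = TRUE)

  perm <- sim$expression[sample(nrow(sim$expression)), ]
  norm_perm <- normalize_log2(perm)
  joined <- dplyr::inner_join(norm, norm_perm, by = c("mirna_id", "sample_id"))
  expect_equal(joined$log2_intensity.x, joined$log2_intensity.y)
})

test_that("the expression floor is applied per line with the either-condition rule", {
  samples <- tidyr::expand_grid(default_cell_lines(), treatment = c("treated", "control"))
  samples$sample_id <- paste(samples$cell_line, samples$treatment, sep = "_")
  samples$dose_ug_ml <- 0; samples$hours <- 144
  norm <- tidyr::expand_grid(mirna_id = c("hi", "edge", "lowline"),
                             sample_id = samples$sample_id)
  norm$log2_intensity <- dplyr::case_when(
    norm$mirna_id == "hi" ~ 8,
    norm$mirna_id == "edge" & grepl("treated", norm$sample_id) ~ 6.5,
    norm$mirna_id == "edge" ~ 5.0,
    norm$mirna_id == "lowline" & grepl("^SKBR3", norm$sample_id) ~ 5.9,
    TRUE ~ 7.5
  )
  kept <- filter_expressed(norm, samples)
  expect_setequal(kept, c("hi", "edge"))     # 6.5/5.0 passes "before or after"
  # under the both-conditions rule the 6.5/5.0 microRNA fails
  kept_both <- filter_expressed(norm, samples,
                                screen_criteria(expression_rule = "both_conditions"))
  expect_setequal(kept_both, "hi")
  # all-zero matrix retains nothing
  zero <- dplyr::mutate(norm, log2_intensity = 0)
  expect_length(filter_expressed(zero, samples), 0)
})

test_that("negative-line exclusion uses strict thresholds in any negative line", {
  fc <- tibble::tibble(
    mirna_id = rep(c("kept", "removed", "boundary"), each = 2),
    cell_line = rep(c("MCF7", "MDA-MB-231"), 3),
    her2_status = "negative",
    fc_linear = c(1.4, 0.8, 1.6, 1.0, 1.5, 1 / 1.5),
    log2_fc = log2(fc_linear)
  )
  survivors <- exclude_negative_responders(fc)
  expect_setequal(survivors, c("kept", "boundary"))
  expect_error(
    exclude_negative_responders(dplyr::mutate(fc, her2_status = "positive")),
    class = "mirscreen_design_error"
  )
})

test_that("relative fold change divides by the geometric mean of negative-line fold changes", {
  mk <- function(fcp, fcn) tibble::tibble(
    mirna_id = "m",
    cell_line = c("P", paste0("N", seq_along(fcn))),
    her2_status = c("positive", rep("negative", length(fcn))),
    log2_fc = log2(c(fcp, fcn)), fc_linear = c(fcp, fcn)
  )
  expect_equal(relative_fold_change(mk(1.5, c(1.5, 1.5)))$rfc_linear, 1)
  expect_equal(relative_fold_change(mk(3, c(1, 4)))$rfc_linear, 1.5)
  expect_equal(relative_fold_change(mk(0.5, c(1, 1)))$rfc_linear, 0.5)
  suppressWarnings(expect_error(relative_fold_change(mk(-1, c(1, 1))),
                                class = "mirscreen_domain_error"))
})

test_that("mean RFC is the geometric mean and reproduces printed cross-line values", {
  expect_equal(round(mean_rfc(c(2.4300, 3.5825)), 4), 2.9505)
  expect_equal(round(mean_rfc(c(1.5730, 1.6897)), 4), 1.6303)
  expect_equal(mean_rfc(c(3, 3)), 3)              # idempotent on equal inputs
  expect_equal(mean_rfc(2.5), 2.5)
  expect_error(mean_rfc(c(1, -2)), class = "mirscreen_domain_error")
  expect_error(mean_rfc(numeric()), class = "mirscreen_domain_error")
})

test_that("zero-noise screen recovers a planted responder at the closed-form RFC", {
  sim <- simulate_array(array_sim_config(
    n_mirnas = 200, noise_log2_sd = 0, line_effect_log2_sd = 0,
    low_expression_fraction = 0,
    planted = tibble::tibble(mirna_id = "miR-sim-0001",
                             cell_line = c("SKBR3", "BT474"),
                             log2_effect = 1.2),
    rng_seed = 21
  ))
  rep <- screen_responsive(normalize_log2(sim$expression), sim$samples)
  up <- dplyr::filter(rep$cross_line, direction == "up")
  expect_equal(up$mirna_id, "miR-sim-0001")
  expect_equal(nrow(dplyr::filter(rep$cross_line, direction == "down")), 0)
  # quantile normalization only redistributes rank gaps, so 2^1.2 within 2%
  per_line <- dplyr::filter(rep$rfc, mirna_id == "miR-sim-0001")
  expect_equal(per_line$rfc_linear, rep(2^1.2, 2), tolerance = 0.02)
})

test_that("a matrix entirely below the floor yields an empty report", {
  sim <- tiny_sim(baseline_log2_mean = 3, baseline_log2_sd = 0.2)
  rep <- screen_responsive(normalize_log2(sim$expression), sim$samples)
  expect_equal(rep$counts$n_expressed, 0)
  expect_equal(rep$counts$n_after_negative_exclusion, 0)
  expect_equal(nrow(rep$cross_line), 0)
  expect_equal(nrow(rep$per_line), 0)
})

test_that("screen equals the brute-force reimplementation on small random instances", {
  set.seed(77)
  for (i in 1:50) {
    n <- sample(3:10, 1)
    sim <- simulate_array(array_sim_config(
      n_mirnas = n, noise_log2_sd = 0.5, line_effect_log2_sd = 0.5,
      baseline_log2_mean = 7, baseline_log2_sd = 1.5,
      low_expression_fraction = 0.3, rng_seed = 1000 + i
    ))
    norm <- normalize_log2(sim$expression)
    rep <- screen_responsive(norm, sim$samples)
    orc <- oracle_screen(norm, sim$samples)
    expect_setequal(rep$expressed, orc$expressed)
    expect_setequal(rep$survivors, orc$survivors)
    expect_setequal(
      rep$cross_line$mirna_id[rep$cross_line$direction == "up"], orc$cross_up)
    expect_setequal(
      rep$cross_line$mirna_id[rep$cross_line$direction == "down"], orc$cross_down)
    for (l in c("SKBR3", "BT474")) {
      got <- rep$per_line[rep$per_line$cell_line == l, ]
      expect_setequal(got$mirna_id[got$direction == "up"], orc$up_per_line[[l]])
      expect_setequal(got$mirna_id[got$direction == "down"], orc$down_per_line[[l]])
    }
  }
})

test_that("raising the fold-change threshold never adds to an up list", {
  # effects planted in positive lines only, so the negative-line exclusion
  # stage is inert and the threshold acts purely on the RFC listing
  planted <- tidyr::expand_grid(
    mirna_id = sprintf("miR-sim-%04d", 1:20),
    cell_line = c("SKBR3", "BT474")
  )
  planted$log2_effect <- rep(seq(0.2, 2, length.out = 20), each = 2)
  sim <- simulate_array(array_sim_config(
    n_mirnas = 80, noise_log2_sd = 0.05, low_expression_fraction = 0,
    planted = planted, rng_seed = 31
  ))
  norm <- normalize_log2(sim$expression)
  up_at <- function(thr) {
    rep <- screen_responsive(norm, sim$samples, screen_criteria(fc_threshold = thr))
    rep$cross_line$mirna_id[rep$cross_line$direction == "up"]
  }
  u1 <- up_at(1.2); u2 <- up_at(1.5); u3 <- up_at(2)
  expect_gt(length(u1), length(u3))
  expect_true(all(u2 %in% u1))
  expect_true(all(u3 %in% u2))
})

test_that("screen report tidiers expose ranked lists and stage counts", {
  sim <- tiny_sim(planted = tibble::tibble(
    mirna_id = c("miR-sim-0003", "miR-sim-0003"),
    cell_line = c("SKBR3", "BT474"), log2_effect = -1.5
  ))
  rep <- screen_responsive(normalize_log2(sim$expression), sim$samples)
  td <- tidy(rep)
  expect_true(all(c("direction", "rank", "mirna_id", "rfc") %in% names(td)))
  expect_equal(td$mirna_id[td$direction == "down"][1], "miR-sim-0003")
  gl <- glance(rep)
  expect_equal(gl$n_total, 30)
  expect_equal(gl$n_down_cross_line, 1)
})
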