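test_that("zero-noise, no-effect arrays give fold change exactly 1 everywhere", {
  sim <- tiny_sim()
  norm <- normalize_log2(sim$expression)
  fc <- fold_changes(norm, sim$samples)
  expect_equal(fc$fc_linear, rep(1, nrow(fc)))
})

test_that("a planted +1 log2 effect appears as a linear fold change of 2 in the planted lines only", {
  sim <- tiny_sim(planted = tibble::tibble(
    mirna_id = "miR-sim-0002", cell_line = c("SKBR3", "BT474"), log2_effect = 1
  ))
  # raw (un-normalized) intensities carry the effect exactly
  raw_log2 <- dplyr::mutate(sim$expression, log2_intensity = log2(intensity))
  fc <- fold_changes(raw_log2[, c("mirna_id", "sample_id", "log2_intensity")],
                     sim$samples)
  planted <- dplyr::filter(fc, mirna_id == "miR-sim-0002")
  expect_equal(planted$fc_linear[planted$cell_line %in% c("SKBR3", "BT474")],
               c(2, 2))
  expect_equal(planted$fc_linear[planted$cell_line %in% c("MCF7", "MDA-MB-231")],
               c(1, 1))
})

test_that("array simulation is seed-deterministic and seed-sensitive", {
  cfg <- array_sim_config(n_mirnas = 40, rng_seed = 7)
  a <- simulate_array(cfg)
  b <- simulate_array(cfg)
  expect_identical(a, b)
  c <- simulate_array(array_sim_config(n_mirnas = 40, rng_seed = 8))
  expect_false(identical(a$expression$intensity, c$expression$intensity))
})

test_that("array config validation rejects bad inputs", {
  expect_error(array_sim_config(n_mirnas = 0), class = "mirscreen_config_error")
  expect_error(array_sim_config(lines = data.frame()), class = "mirscreen_config_error")
  expect_error(array_sim_config(noise_log2_sd = -1), class = "mirscreen_config_error")
  expect_error(
    array_sim_config(planted = tibble::tibble(
      mirna_id = "nope", cell_line = "SKBR3", log2_effect = 1
    )),
    class = "mirscreen_config_error"
  )
})

test_that("low-expression features fall below the floor in all samples at zero noise", {
  sim <- simulate_array(array_sim_config(
    n_mirnas = 100, noise_log2_sd = 0, line_effect_log2_sd = 0,
    low_expression_fraction = 0.4, rng_seed = 11
  ))
  low_ids <- unique(sim$truth$mirna_id[!sim$truth$expressed])
  expect_equal(length(low_ids), 40)
  low_vals <- sim$expression$intensity[sim$expression$mirna_id %in% low_ids]
  expect_true(all(log2(low_vals) < 6))
})

test_that("noise-free luciferase simulation yields the exact configured repression", {
  m0 <- simulate_luciferase(assay_sim_config(
    luciferase_true_repression = 0, luciferase_cv = 0, rng_seed = 5
  ))
  act <- m0$firefly / m0$renilla
  expect_equal(act, rep(act[1], length(act)))

  m <- simulate_luciferase(assay_sim_config(
    luciferase_true_repression = 0.27, luciferase_cv = 0, rng_seed = 5
  ))
  est <- suppressWarnings(luciferase_repression(m))  # zero variance at cv = 0
  expect_equal(est$percent_repression, 27)
  # the double mutant loses all repression, the single mutants half
  expect_equal(luciferase_repression(m, construct = "mut1+2")$percent_repression, 0)
  expect_equal(
    suppressWarnings(luciferase_repression(m, construct = "mut1"))$percent_repression,
    13.5
  )
})

test_that("luciferase repression estimator is unbiased over many noisy replicates", {
  ests <- vapply(1:500, function(s) {
    m <- simulate_luciferase(assay_sim_config(
      luciferase_true_repression = 0.27, luciferase_cv = 0.05,
      replicates = 3, rng_seed = s
    ), constructs = "wt")
    luciferase_repression(m)$percent_repression
  }, numeric(1))
  expect_lt(abs(mean(ests) - 27), 2)
})

test_that("cell-cycle event draws respect the configured fractions and event count", {
  h <- simulate_cell_cycle(assay_sim_config(
    cellcycle_true_fractions = c(0.6, 0.3, 0.1), cellcycle_events = 10000,
    rng_seed = 9
  ))
  expect_equal(sum(h$count), 10000)
  mu <- 200; sigma <- 6
  near_g1 <- sum(h$count[abs(h$dna_content - mu) <= 2 * sigma]) / sum(h$count)
  # G1 events essentially all fall in mu +/- 2 sigma; S contributes a sliver
  expect_lt(abs(near_g1 - 0.6), 0.04)
  expect_error(simulate_cell_cycle(assay_sim_config(cellcycle_events = 0)),
               class = "mirscreen_config_error")
  expect_error(assay_sim_config(cellcycle_true_fractions = c(0.5, 0.4, 0.4)),
               class = "mirscreen_config_error")
})

test_that("assay panel honors its planted truths at zero / small noise", {
  cfg <- assay_sim_config(cq_true_ratio = 4, cq_noise_sd = 0,
                          viability_true_inhibition = 0.4, viability_cv = 0,
                          apoptosis_true_fraction = 0.147,
                          apoptosis_events = 10000, rng_seed = 3)
  panel <- simulate_assay_panel(cfg)

  # target Cq exactly 2 cycles lower than the calibrator's at equal reference Cqs
  cq <- panel$cq
  t_s <- mean(cq$cq[cq$sample_id == "sample" & cq$role == "target"])
  t_c <- mean(cq$cq[cq$sample_id == "calibrator" & cq$role == "target"])
  r_s <- mean(cq$cq[cq$sample_id == "sample" & cq$role == "reference"])
  r_c <- mean(cq$cq[cq$sample_id == "calibrator" & cq$role == "reference"])
  expect_equal(t_c - t_s, 2)
  expect_equal(r_s, r_c)

  v <- panel$viability
  expect_equal(mean(v$a450[v$condition == "treated"]) /
                 mean(v$a450[v$condition == "control"]), 0.6)

  apo <- panel$apoptosis
  frac <- annexin_fraction(apo$intensities, apo$threshold)$positive_fraction
  expect_lt(abs(frac - 0.147), 0.01)
})
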