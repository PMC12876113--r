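test_that("the default cultivation reproduces the batch structure", {
  p <- simulation_params(seed = 1)
  tc <- simulate_cultivation(p, "producer")
  # glucose is monotone non-increasing and reaches depletion before the horizon
  expect_true(all(diff(tc$glucose_g_l) <= 0))
  expect_lt(min(tc$glucose_g_l), p$depletion_glucose)
  expect_lt(depletion_time(tc, p$depletion_glucose), p$horizon)
  # biomass approaches the carrying capacity at the horizon
  expect_equal(tc$biomass_g_l[nrow(tc)], p$x_max, tolerance = 0.01)
  # the reporter signal peaks and then decays
  i_peak <- which.max(tc$rfu_cell)
  expect_gt(i_peak, 1)
  expect_lt(i_peak, nrow(tc))
  expect_true(all(diff(tc$rfu_cell[i_peak:nrow(tc)]) < 0))
})

test_that("substrate consumption balances biomass formation", {
  p <- simulation_params(seed = 1)
  tc <- simulate_cultivation(p, "producer")
  consumed <- p$glucose0 - tc$glucose_g_l
  formed <- tc$biomass_g_l - p$x0
  expect_equal(consumed * p$yield_xs, formed, tolerance = 1e-9)
})

test_that("control-strain background stays below 4% of the producer signal", {
  p <- simulation_params(seed = 1)
  producer <- simulate_cultivation(p, "producer")
  control <- simulate_cultivation(p, "control")
  expect_true(all(control$conc_true_mg_l == 0))
  expect_true(all(control$rfu_cell / producer$rfu_cell <= 0.04))
})

test_that("identical parameters give byte-identical time courses", {
  p <- simulation_params(seed = 99)
  a <- simulate_cultivation(p, "producer")
  b <- simulate_cultivation(p, "producer")
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  oa <- observe_timecourse(a, cv = 0.02, seed = 5)
  ob <- observe_timecourse(b, cv = 0.02, seed = 5)
  expect_identical(oa, ob)
})

test_that("an unreachable carrying capacity triggers a consistency warning", {
  expect_warning(
    simulate_cultivation(simulation_params(glucose0 = 2), "producer"),
    "cannot sustain")
})

test_that("plate readings are unbiased lognormal observations", {
  exact <- simulate_plate_readings(c(100, 2000), cv = 0, blank_mean = 30,
                                   seed = 1)
  expect_equal(exact$rfu, exact$true_value + 30)

  many <- simulate_plate_readings(1000, cv = 0.05, seed = 2,
                                  n_replicates = 10000)
  expect_equal(mean(many$rfu), 1000, tolerance = 0.01)

  r1 <- simulate_plate_readings(c(10, 100), cv = 0.02, seed = 7, n_replicates = 3)
  r2 <- simulate_plate_readings(c(10, 100), cv = 0.02, seed = 7, n_replicates = 3)
  expect_identical(r1, r2)
  r3 <- simulate_plate_readings(c(10, 100), cv = 0.02, seed = 8, n_replicates = 3)
  expect_false(identical(r1$rfu, r3$rfu))
})

test_that("seeded generators leave the caller's RNG state untouched", {
  set.seed(123)
  expected <- runif(3)
  set.seed(123)
  invisible(simulate_plate_readings(100, cv = 0.1, seed = 42))
  expect_identical(runif(3), expected)
})

test_that("noise-free gels invert exactly through the lane calculation", {
  p <- simulation_params(seed = 1, cv_gel = 0, cv_hcp = 0)
  tc <- simulate_cultivation(p, "producer")
  sim <- simulate_gel(tc, p, seed = 1)
  lanes <- quantify_gel(sim$gel, sim$hcp)
  truth <- tc$conc_true_mg_l[match(lanes$timepoint_h, tc$time_h)]
  expect_equal(lanes$target_mg_l, truth, tolerance = 1e-9)
  expect_true(all(lanes$lane_pct >= 0 & lanes$lane_pct <= 100))
})

test_that("noisy gel triplicates recover the peak concentration within 15%", {
  p <- simulation_params(seed = 1)          # cv_gel 0.05, cv_hcp 0.05
  tc <- simulate_cultivation(p, "producer")
  t_peak <- tc$time_h[which.max(tc$conc_true_mg_l)]
  truth <- max(tc$conc_true_mg_l)
  ests <- vapply(1:3, function(k) {
    sim <- simulate_gel(tc, p, seed = 100 + k, timepoints = t_peak)
    quantify_gel(sim$gel, sim$hcp)$target_mg_l
  }, numeric(1))
  expect_lt(abs(mean(ests) - truth) / truth, 0.15)
  expect_true(all(vapply(seq_along(ests), function(i) {
    sim <- simulate_gel(tc, p, seed = 100 + i, timepoints = t_peak)
    all(quantify_gel(sim$gel, sim$hcp)$lane_pct <= 100)
  }, logical(1))))
})

test_that("spike experiments have no built-in matrix effect", {
  clean <- simulate_spike_experiment(6.3, c(12.6, 31.5), cv = 0, seed = 1)
  rec <- recovery_from_spikes(clean)
  expect_equal(rec$recovery_pct, c(100, 100))

  suppressed <- simulate_spike_experiment(6.3, c(12.6, 31.5), cv = 0, seed = 1,
                                          matrix_effect = 0.8)
  expect_equal(recovery_from_spikes(suppressed)$recovery_pct, c(80, 80))

  a <- simulate_spike_experiment(6.3, c(12.6, 31.5), cv = 0.02, seed = 3)
  b <- simulate_spike_experiment(6.3, c(12.6, 31.5), cv = 0.02, seed = 3)
  expect_identical(a, b)
  expect_warning(simulate_spike_experiment(10, c(12, 40), cv = 0, seed = 1),
                 "twice the background")
})

test_that("precision studies produce day-structured replicates", {
  df <- simulate_precision_study(c(6.3, 63), cv = 0.02, cv_day = 0.03, seed = 1)
  expect_equal(nrow(df), 2 * 3 * 3)
  expect_setequal(unique(df$day), 1:3)
  ps <- precision_summary(df)
  expect_true(all(ps$rsd_pct >= 0))
  expect_identical(df, simulate_precision_study(c(6.3, 63), cv = 0.02,
                                                cv_day = 0.03, seed = 1))
})

test_that("CFU counts reflect density, dilution and lysis survival", {
  p <- simulation_params(seed = 1)
  ctrl <- simulate_cfu(p, "control", seed = 1)
  lys <- simulate_cfu(p, "lysed", seed = 2)
  eff <- lysis_efficiency(ctrl, lys)
  expect_gt(eff, 99.99)                     # survival 1e-5 -> ~99.999%
  expect_lt(eff, 100)

  p_all_survive <- simulation_params(seed = 1, lysis_survival = 1)
  eff0 <- lysis_efficiency(simulate_cfu(p_all_survive, "control", seed = 3),
                           simulate_cfu(p_all_survive, "lysed", seed = 4))
  expect_lt(abs(eff0), 35)                  # Poisson scatter around 0%

  # expected counts scale linearly with the plated volume
  lam <- function(vol) {
    mean(vapply(1:100, function(s) {
      simulate_cfu(p, "control", seed = s, plated_volume_ml = vol,
                   dilution_factor = 1e8)$colonies
    }, numeric(1)))
  }
  expect_equal(lam(0.2) / lam(0.1), 2, tolerance = 0.2)
})

test_that("auto-selected dilutions land in or below the countable window", {
  p <- simulation_params(seed = 1)
  counts <- vapply(1:20, function(s) {
    simulate_cfu(p, "control", seed = s)$colonies
  }, numeric(1))
  expect_true(all(counts <= 400))
  expect_true(all(counts >= 10))
})
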