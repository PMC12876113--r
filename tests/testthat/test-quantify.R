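test_that("lane percentage apportions HCP to the target protein", {
  # 15.27% of 1275.2 mg/L HCP -> ~194.7 mg/L target protein
  expect_equal(target_conc_from_lane(15.27, 1275.2), 194.7, tolerance = 1e-3)
  expect_equal(target_conc_from_lane(0, 1275.2), 0)
  expect_equal(target_conc_from_lane(100, 1275.2), 1275.2)
  expect_error(target_conc_from_lane(120, 100), class = "fluoquant_invalid_input")
  expect_error(target_conc_from_lane(50, -1), class = "fluoquant_invalid_input")
})

test_that("lane-derived concentration never exceeds the HCP concentration", {
  set.seed(3)
  pct <- runif(50, 0, 100)
  hcp <- runif(50, 10, 3000)
  expect_true(all(target_conc_from_lane(pct, hcp) <= hcp))
})

test_that("target band is matched within a +/-2 kDa window", {
  mw <- c(15, 26.5, 50, 75)
  intensity <- c(10, 30, 40, 20)
  expect_equal(lane_intensity_pct(mw, intensity), 30)       # 26.5 within 27 +/- 2
  expect_equal(lane_intensity_pct(mw, intensity, window = 0.4), 0)
  expect_equal(lane_intensity_pct(27, 55), 100)
  expect_error(lane_intensity_pct(numeric(0), numeric(0)),
               class = "fluoquant_invalid_input")
})

test_that("gel tables quantify per lane in both layouts", {
  gel <- data.frame(lane_id = rep("L1", 3), timepoint_h = 19,
                    band_mw_kda = c(27, 50, 75),
                    band_intensity = c(30, 50, 20))
  hcp <- data.frame(timepoint_h = 19, hcp_mg_l = 1000)
  out <- quantify_gel(gel, hcp)
  expect_equal(out$lane_pct, 30)
  expect_equal(out$target_mg_l, 300)
  pre <- data.frame(lane_id = "L1", timepoint_h = 19, lane_intensity_pct = 30)
  expect_equal(quantify_gel(pre, hcp)$target_mg_l, 300)
})

test_that("lysate concentrations rescale to the culture-volume basis", {
  expect_equal(lysate_to_culture_basis(100, 510, 1000), 51)
  expect_equal(lysate_to_culture_basis(42, 700, 700), 42)
  # scalar commutativity with the lane calculation
  a <- lysate_to_culture_basis(target_conc_from_lane(20, 800), 510, 1000)
  b <- target_conc_from_lane(20, lysate_to_culture_basis(800, 510, 1000))
  expect_equal(a, b)
  expect_error(lysate_to_culture_basis(1, 0, 100), class = "fluoquant_invalid_input")
})

test_that("in-cell vs lysate correlation recovers attenuation exactly", {
  lysate <- c(2e4, 1e5, 3e5, 6e5, 9e5)
  ident <- fit_incell_vs_lysate(lysate, lysate)
  expect_equal(ident$slope, 1)
  expect_equal(ident$intercept, 0, tolerance = 1e-9)
  expect_equal(ident$max_abs_dev_pct, 0)
  expect_true(ident$negligible)

  atten <- fit_incell_vs_lysate(0.95 * lysate, lysate)
  expect_equal(atten$slope, 0.95)
  expect_equal(atten$max_abs_dev_pct, 5, tolerance = 1e-9)

  expect_error(fit_incell_vs_lysate(1:2, 1:2),
               class = "fluoquant_degenerate_design")
})

test_that("low-signal timepoints are excluded from the deviation metric", {
  lysate <- c(10, 2e5, 4e5, 8e5)
  cell <- c(100, 0.95 * lysate[-1])       # wild relative deviation at 10 RFU
  fit <- fit_incell_vs_lysate(cell, lysate, min_lysate = 1000)
  expect_equal(fit$n_dev, 3)
  expect_equal(fit$max_abs_dev_pct, 5, tolerance = 1e-9)
})

test_that("conversion fit recovers noise-free coefficients", {
  conc <- c(0, 5, 20, 60, 120, 200)
  rfu <- 4837.0 * conc + 8697.6
  model <- fit_conversion(conc, rfu)
  expect_equal(model$slope_a, 4837.0, tolerance = 1e-9)
  expect_equal(model$intercept_b, 8697.6, tolerance = 1e-9)
  expect_equal(model$r_squared, 1)
  expect_equal(model$rfu_valid_max, max(rfu))
  expect_equal(model$conc_valid_max, 200, tolerance = 1e-9)
  # weighting makes no difference on noise-free data
  wls <- fit_conversion(conc, rfu, weighting = "inverse_response_sq")
  expect_equal(wls$slope_a, model$slope_a, tolerance = 1e-9)
})

test_that("conversion fit matches the closed-form least-squares oracle", {
  set.seed(4)
  conc <- rep(c(2, 10, 50, 120, 200), each = 2)
  rfu <- 4837 * conc + 8697.6 + rnorm(length(conc), sd = 5000)
  model <- fit_conversion(conc, rfu)
  oracle <- ols_oracle(conc, rfu)
  expect_equal(model$slope_a, unname(oracle["slope"]), tolerance = 1e-10)
  expect_equal(model$intercept_b, unname(oracle["intercept"]), tolerance = 1e-10)
})

test_that("degenerate conversion inputs are rejected", {
  expect_error(fit_conversion(c(5, 5, 5), c(1, 2, 3)),
               class = "fluoquant_degenerate_design")
  expect_error(fit_conversion(c(1, 2), c(10, 20)),
               class = "fluoquant_degenerate_design")
  expect_error(fit_conversion(c(1, 2, 3, 4), c(100, 80, 50, 20)),
               class = "fluoquant_degenerate_design")  # decreasing response
})

test_that("RFU to concentration inverts the model inside its range", {
  conc <- c(0, 5, 20, 60, 120, 200)
  model <- fit_conversion(conc, 4837.0 * conc + 8697.6)
  expect_equal(as.numeric(rfu_to_conc(model, 8697.6)), 0)
  expect_equal(as.numeric(rfu_to_conc(model, 492397.6)), 100.0, tolerance = 1e-9)
  # round trip across the whole valid range
  grid <- seq(0, model$conc_valid_max, length.out = 101)
  back <- as.numeric(rfu_to_conc(model, conc_to_rfu(model, grid)))
  expect_equal(back, grid, tolerance = 1e-9)
})

test_that("readings below the intercept clamp to zero with a flag", {
  conc <- c(0, 5, 20, 60)
  model <- fit_conversion(conc, 4837.0 * conc + 8697.6)
  res <- rfu_to_conc(model, c(100, 8697.6 + 4837))
  expect_equal(as.numeric(res), c(0, 1))
  expect_equal(attr(res, "below_calibration"), c(TRUE, FALSE))
})

test_that("extrapolation beyond the validity range raises the guard", {
  conc <- c(0, 5, 20, 60, 120, 200)
  model <- fit_conversion(conc, 4837.0 * conc + 8697.6)
  expect_error(rfu_to_conc(model, model$rfu_valid_max + 1),
               class = "fluoquant_range_error")
  err <- tryCatch(rfu_to_conc(model, 4 * model$rfu_valid_max),
                  fluoquant_range_error = identity)
  expect_gte(err$suggested_dilution, 4)
  expect_lte(4 * model$rfu_valid_max / err$suggested_dilution,
             model$rfu_valid_max)
  # the vectorised wrapper flags instead of throwing
  q <- quantify_rfu(model, c(1e5, 4 * model$rfu_valid_max))
  expect_false(q$out_of_range[1])
  expect_true(q$out_of_range[2])
  expect_true(is.na(q$conc_mg_l[2]))
})

test_that("quantification is dilution invariant on noise-free readings", {
  conc <- c(0, 5, 20, 60, 120, 200)
  model <- fit_conversion(conc, 4837.0 * conc + 8697.6)
  for (k in c(2, 5, 10)) {
    c_true <- 150
    diluted_reading <- conc_to_rfu(model, c_true / k)
    expect_equal(k * as.numeric(rfu_to_conc(model, diluted_reading)), c_true,
                 tolerance = 1e-9)
  }
})

test_that("conversion models persist to JSON and back unrounded", {
  conc <- c(0, 5, 20, 60, 120, 200)
  model <- fit_conversion(conc, 4837.0 * conc + 8697.6)
  path <- withr::local_tempfile(fileext = ".json")
  write_conversion_model(model, path)
  back <- read_conversion_model(path)
  expect_equal(back$slope_a, model$slope_a, tolerance = 1e-12)
  expect_equal(back$intercept_b, model$intercept_b, tolerance = 1e-12)
  expect_equal(back$rfu_valid_max, model$rfu_valid_max, tolerance = 1e-12)
  expect_s3_class(back, "conversion_model")
})

test_that("background assessment handles the limiting cases", {
  tc <- function(rfu) {
    data.frame(time_h = c(0, 4, 8, 12, 16), biomass_g_l = c(1, 2, 3, 3, 3),
               rfu_cell = rfu)
  }
  s <- c(1e4, 1e5, 5e5, 8e5, 7e5)
  same <- assess_background(tc(s), tc(s), depletion_time = 10)
  expect_equal(same$background_fraction_max, 100)
  expect_equal(unname(same$sbr_by_phase), c(1, 1))

  zero <- assess_background(tc(s), tc(rep(0, 5)), depletion_time = 10)
  expect_equal(zero$background_fraction_max, 0)

  expect_error(
    assess_background(tc(s), tc(s)[-1, ], depletion_time = 10),
    class = "fluoquant_alignment_error")
})

test_that("phase means are invariant to timepoint ordering within a phase", {
  prod <- data.frame(time_h = c(0, 2, 4, 12, 14, 16),
                     biomass_g_l = c(1, 2, 3, 3.2, 3.2, 3.2),
                     rfu_cell = c(1e4, 5e4, 2e5, 8e5, 7e5, 6e5))
  ctrl <- data.frame(time_h = prod$time_h,
                     biomass_g_l = prod$biomass_g_l,
                     rfu_cell = c(500, 900, 1500, 4000, 4500, 5000))
  base_bg <- assess_background(prod, ctrl, depletion_time = 6)
  perm <- c(3, 1, 2, 6, 4, 5)            # shuffles within each phase only
  perm_bg <- assess_background(prod[perm, ], ctrl[perm, ], depletion_time = 6)
  expect_equal(perm_bg$sbr_by_phase, base_bg$sbr_by_phase)
  expect_equal(perm_bg$autofl_per_biomass_by_phase,
               base_bg$autofl_per_biomass_by_phase)
  expect_equal(perm_bg$background_fraction_max, base_bg$background_fraction_max)
})

test_that("CFU records and lysis efficiency follow plate arithmetic", {
  ctrl <- cfu_count(100, plated_volume_ml = 0.1, dilution_factor = 1e4)
  expect_equal(cfu_per_ml(ctrl), 1e7)
  expect_true(ctrl$countable)
  lysed <- cfu_count(100, plated_volume_ml = 0.1, dilution_factor = 0.1 * 1e3)
  expect_equal(cfu_per_ml(lysed), 1e5)

  ctrl2 <- cfu_count(100, 0.1, 1e4)       # 1e7 CFU/mL
  lysed2 <- cfu_count(100, 0.1, 1)        # 1e3 CFU/mL
  expect_equal(lysis_efficiency(ctrl2, lysed2), 100 * (1 - 1e-4))
  zero <- cfu_count(0, 0.1, 1)
  expect_equal(suppressWarnings(lysis_efficiency(ctrl2, zero)), 100)
})

test_that("counts outside 30-300 are flagged non-countable but usable", {
  big <- cfu_count(500, 0.1, 100)
  expect_false(big$countable)
  ctrl <- cfu_count(100, 0.1, 1e4)
  expect_warning(eff <- lysis_efficiency(ctrl, big),
                 "countable")
  expect_true(is.finite(eff))
  expect_error(
    suppressWarnings(lysis_efficiency(cfu_count(0, 0.1, 1), cfu_count(0, 0.1, 1))),
    class = "fluoquant_undefined_efficiency")
  expect_error(cfu_count(-1, 0.1, 1), class = "fluoquant_invalid_input")
})
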