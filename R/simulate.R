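#' Parameters of the synthetic batch-cultivation generator
#'
#' Defines the study conditions the generator emulates: a 24-h batch
#' *E. coli* culture on 10 g/L glucose with growth-coupled reporter
#' expression, glucose depletion, post-depletion first-order signal decay, a
#' plasmid-free control strain contributing only autofluorescence, and
#' scale-proportional (lognormal) observation noise for plate reader, gel
#' densitometry and protein assay.
#'
#' Defaults are anchored to the measured study conditions: peak biomass
#' 3.23 g/L, OD-to-biomass factor 0.334 g/L per OD, target protein
#' ~15.27% of a 40% HCP-per-biomass pool, cell-suspension conversion line
#' rfu = 4837.0 * conc + 8697.6, and a standard-curve response of
#' 778.5 RFU per mg/L (49,043.8 RFU at 63.0 mg/L standard).
#'
#' @param seed Integer seed; every generator draws through it.
#' @param x0 Inoculum biomass, g/L (0.0334 = OD 0.1).
#' @param x_max Carrying-capacity biomass, g/L.
#' @param mu Specific growth rate, 1/h.
#' @param glucose0 Initial glucose, g/L.
#' @param yield_xs Biomass yield on glucose, g/g.
#' @param hcp_fraction Soluble host-cell protein as fraction of biomass.
#' @param target_fraction Target protein as fraction of HCP.
#' @param conv_slope,conv_intercept Cell-suspension RFU per mg/L and offset.
#' @param quench_incell In-cell signal attenuation relative to the lysate
#'   signal, in (0, 1].
#' @param autofl_per_biomass Control-strain autofluorescence, RFU per g/L.
#' @param decay_rate Post-depletion first-order product decay, 1/h.
#' @param cv_rfu,cv_gel,cv_hcp Observation CVs (fractions) for plate reader,
#'   gel band intensities and HCP assay.
#' @param cv_day Between-day lognormal CV for interday precision studies.
#' @param sampling_interval Sampling interval, h.
#' @param horizon Cultivation horizon, h.
#' @param lysis_survival Fraction of cells surviving lysis.
#' @param od_biomass_factor g/L biomass per OD unit.
#' @param depletion_glucose Glucose level (g/L) below which the substrate
#'   counts as depleted and production stops.
#' @param std_slope Standard-curve response, RFU per mg/L (cell-free basis).
#' @param blank_rfu Mean blank (buffer) RFU added to plate readings.
#' @param cells_per_ml_per_od Viable cells per mL per OD unit (CFU model).
#' @return A validated `simulation_params` list.
#' @export
simulation_params <- function(seed = 1L,
                              x0 = 0.0334, x_max = 3.23, mu = 0.40,
                              glucose0 = 10, yield_xs = 0.323,
                              hcp_fraction = 0.40, target_fraction = 0.1527,
                              conv_slope = 4837.0, conv_intercept = 8697.6,
                              quench_incell = 0.95,
                              autofl_per_biomass = 1.5e3,
                              decay_rate = 0.02,
                              cv_rfu = 0.02, cv_gel = 0.05, cv_hcp = 0.05,
                              cv_day = 0.03,
                              sampling_interval = 2, horizon = 24,
                              lysis_survival = 1e-5,
                              od_biomass_factor = 0.334,
                              depletion_glucose = 0.5,
                              std_slope = 778.5, blank_rfu = 50,
                              cells_per_ml_per_od = 8e8) {
  p <- list(seed = as.integer(seed), x0 = x0, x_max = x_max, mu = mu,
            glucose0 = glucose0, yield_xs = yield_xs,
            hcp_fraction = hcp_fraction, target_fraction = target_fraction,
            conv_slope = conv_slope, conv_intercept = conv_intercept,
            quench_incell = quench_incell,
            autofl_per_biomass = autofl_per_biomass,
            decay_rate = decay_rate, cv_rfu = cv_rfu, cv_gel = cv_gel,
            cv_hcp = cv_hcp, cv_day = cv_day,
            sampling_interval = sampling_interval, horizon = horizon,
            lysis_survival = lysis_survival,
            od_biomass_factor = od_biomass_factor,
            depletion_glucose = depletion_glucose,
            std_slope = std_slope, blank_rfu = blank_rfu,
            cells_per_ml_per_od = cells_per_ml_per_od)
  with(p, {
    stopifnot(x0 > 0, x_max > x0, mu > 0, glucose0 > 0, yield_xs > 0,
              hcp_fraction > 0, hcp_fraction <= 1,
              target_fraction > 0, target_fraction <= 1,
              conv_slope > 0, quench_incell > 0, quench_incell <= 1,
              autofl_per_biomass >= 0, decay_rate >= 0,
              cv_rfu >= 0, cv_gel >= 0, cv_hcp >= 0, cv_day >= 0,
              sampling_interval > 0, horizon > 0,
              lysis_survival >= 0, lysis_survival <= 1,
              od_biomass_factor > 0, std_slope > 0, blank_rfu >= 0)
  })
  structure(p, class = "simulation_params")
}

#' Simulate a noise-free batch-cultivation time course
#'
#' Exponential growth capped at the carrying capacity, with glucose consumed
#' stoichiometrically (`glucose = glucose0 - (X - x0)/yield_xs`, floored at
#' 0). The target protein tracks biomass while glucose remains above the
#' depletion level, then decays first-order. Cell-suspension (in-cell) RFU
#' follows the conversion line `conv_slope * conc + conv_intercept` plus
#' biomass-proportional autofluorescence; the lysate RFU is the de-quenched
#' signal `(conv_slope / quench_incell) * conc + conv_intercept`. The control
#' strain carries no target protein, only autofluorescence.
#'
#' Output is deterministic: observation noise is layered on separately by
#' [observe_timecourse()] / [simulate_plate_readings()].
#'
#' @param params A [simulation_params()] object.
#' @param strain `"producer"` or `"control"`.
#' @return A `time_course` data.frame: `time_h`, `strain`, `od600`,
#'   `biomass_g_l`, `glucose_g_l`, `conc_true_mg_l`, `rfu_cell`,
#'   `rfu_lysate`.
#' @export
simulate_cultivation <- function(params = simulation_params(),
                                 strain = c("producer", "control")) {
  strain <- match.arg(strain)
  p <- params
  cap <- min(p$x_max, p$x0 + p$glucose0 * p$yield_xs)
  if (cap < p$x_max) {
    warning("glucose0 * yield_xs cannot sustain x_max; biomass caps at ",
            signif(cap, 4), " g/L")
  }
  time_h <- seq(0, p$horizon, by = p$sampling_interval)
  x <- pmin(p$x0 * exp(p$mu * time_h), cap)
  glucose <- pmax(p$glucose0 - (x - p$x0) / p$yield_xs, 0)

  conc <- p$target_fraction * p$hcp_fraction * x * 1000  # mg/L culture basis
  depleted <- glucose < p$depletion_glucose
  if (any(depleted)) {
    i_dep <- which(depleted)[1]
    t_dep <- time_h[i_dep]
    conc[depleted] <- conc[i_dep] * exp(-p$decay_rate * (time_h[depleted] - t_dep))
  }
  if (strain == "control") conc[] <- 0

  autofl <- p$autofl_per_biomass * x
  rfu_cell <- p$conv_slope * conc + p$conv_intercept + autofl
  rfu_lysate <- (p$conv_slope / p$quench_incell) * conc + p$conv_intercept
  if (strain == "control") rfu_cell <- autofl

  out <- data.frame(time_h = time_h, strain = strain,
                    od600 = x / p$od_biomass_factor, biomass_g_l = x,
                    glucose_g_l = glucose, conc_true_mg_l = conc,
                    rfu_cell = rfu_cell, rfu_lysate = rfu_lysate)
  class(out) <- c("time_course", "data.frame")
  out
}

#' First sampled time at which glucose counts as depleted
#'
#' @param tc A [simulate_cultivation()] / [read_timecourse()] time course.
#' @param threshold Depletion level in g/L (default 0.5).
#' @return Time in h, or `NA` if glucose never falls below the threshold.
#' @export
depletion_time <- function(tc, threshold = 0.5) {
  i <- which(tc$glucose_g_l < threshold)
  if (!length(i)) return(NA_real_)
  tc$time_h[i[1]]
}

#' Simulate noisy plate-reader readings
#'
#' Applies multiplicative lognormal noise with coefficient of variation `cv`
#' to each true value (so replicate means converge to the truth) and adds the
#' blank signal. Deterministic under a fixed seed.
#'
#' @param true_values True signal values (RFU, blank-free).
#' @param cv Noise CV as a fraction (>= 0).
#' @param blank_mean Additive blank RFU.
#' @param seed Integer seed.
#' @param n_replicates Technical replicates per true value.
#' @param sample_id Optional sample identifiers (recycled).
#' @return Data.frame `sample_id`, `index`, `replicate`, `true_value`, `rfu`.
#' @export
simulate_plate_readings <- function(true_values, cv, blank_mean = 0, seed = 1L,
                                    n_replicates = 1L, sample_id = NULL) {
  if (cv < 0) fq_stop("fluoquant_invalid_input", "cv must be >= 0")
  n <- length(true_values)
  if (is.null(sample_id)) sample_id <- sprintf("s%02d", seq_len(n))
  grid <- expand.grid(index = seq_len(n), replicate = seq_len(n_replicates))
  grid <- grid[order(grid$index, grid$replicate), ]
  noisy <- with_seed(seed, rlnorm_cv(nrow(grid), true_values[grid$index], cv))
  data.frame(sample_id = rep_len(sample_id, n)[grid$index],
             index = grid$index, replicate = grid$replicate,
             true_value = true_values[grid$index],
             rfu = noisy + blank_mean,
             row.names = NULL)
}

#' Overlay observation noise on a simulated time course
#'
#' Replaces the noise-free `rfu_cell` / `rfu_lysate` columns by the mean of
#' `n_replicates` noisy technical replicates each (the measurement protocol
#' reads every sample as technical duplicates).
#'
#' @param tc A [simulate_cultivation()] time course.
#' @param cv Plate-reader CV (fraction).
#' @param seed Integer seed.
#' @param n_replicates Technical replicates averaged per timepoint.
#' @return The time course with noisy `rfu_cell` and `rfu_lysate`.
#' @export
observe_timecourse <- function(tc, cv, seed = 1L, n_replicates = 2L) {
  rep_mean <- function(truth, s) {
    r <- simulate_plate_readings(truth, cv = cv, blank_mean = 0, seed = s,
                                 n_replicates = n_replicates)
    vapply(split(r$rfu, r$index), mean, numeric(1))
  }
  tc$rfu_cell <- unname(rep_mean(tc$rfu_cell, seed))
  tc$rfu_lysate <- unname(rep_mean(tc$rfu_lysate, seed + 1L))
  tc
}

#' Simulate SDS-PAGE lanes with paired HCP measurements
#'
#' For each requested timepoint, emits a lane whose 27-kDa target band holds
#' the true target fraction of the lane's total intensity, alongside fixed
#' background bands sharing the remaining host-protein intensity; band
#' intensities get lognormal noise with CV `cv_gel`, and the paired
#' (Bradford-basis) HCP concentration gets CV `cv_hcp`.
#'
#' @param tc A producer [simulate_cultivation()] time course.
#' @param params A [simulation_params()] object.
#' @param seed Integer seed.
#' @param timepoints Timepoints (h) to lane out; defaults to all sampled
#'   timepoints.
#' @return List with `gel` (long data.frame `lane_id`, `timepoint_h`,
#'   `band_mw_kda`, `band_intensity`) and `hcp` (`timepoint_h`, `hcp_mg_l`,
#'   `assay`).
#' @export
simulate_gel <- function(tc, params = simulation_params(), seed = 1L,
                         timepoints = NULL) {
  p <- params
  if (is.null(timepoints)) timepoints <- tc$time_h
  idx <- match(timepoints, tc$time_h)
  if (anyNA(idx)) {
    fq_stop("fluoquant_invalid_input", "timepoints must be sampled timepoints")
  }
  bg_mw <- c(15, 37, 50, 75)          # housekeeping-protein band positions, kDa
  bg_w <- c(0.35, 0.30, 0.20, 0.15)   # background mass split
  gel <- list(); hcp <- list()
  with_seed(seed, {
    for (k in seq_along(idx)) {
      i <- idx[k]
      hcp_true <- p$hcp_fraction * tc$biomass_g_l[i] * 1000
      conc <- tc$conc_true_mg_l[i]
      # intensity scale is arbitrary; 1 unit per mg/L keeps the split exact
      target_int <- rlnorm_cv(1, conc, p$cv_gel)
      bg_int <- rlnorm_cv(length(bg_mw), (hcp_true - conc) * bg_w, p$cv_gel)
      gel[[k]] <- data.frame(
        lane_id = sprintf("L%02d", k),
        timepoint_h = tc$time_h[i],
        band_mw_kda = c(27, bg_mw),
        band_intensity = c(target_int, bg_int))
      hcp[[k]] <- data.frame(
        timepoint_h = tc$time_h[i],
        hcp_mg_l = rlnorm_cv(1, hcp_true, p$cv_hcp),
        assay = "bradford_595")
    }
  })
  list(gel = do.call(rbind, gel), hcp = do.call(rbind, hcp))
}

#' Simulate a spike-recovery experiment
#'
#' Paired spiked/unspiked readings of a cell-suspension background spiked
#' with known standard concentrations, with zero built-in matrix effect by
#' default (`matrix_effect = 1`); set `matrix_effect < 1` to emulate signal
#' suppression for negative tests. Readings are reported on the
#' concentration scale.
#'
#' @param base_conc Background (unspiked) concentration-equivalent signal.
#' @param spike_concs Spiked amounts, same units; each should be at least
#'   twice `base_conc` (warned otherwise).
#' @param cv Plate-reader CV (fraction).
#' @param seed Integer seed.
#' @param n_replicates Replicates per level (default 3).
#' @param matrix_effect Multiplier on the spike's contribution.
#' @return Data.frame `level_label`, `expected_added`, `replicate`,
#'   `measured_unspiked`, `measured_spiked`.
#' @export
simulate_spike_experiment <- function(base_conc, spike_concs, cv, seed = 1L,
                                      n_replicates = 3L, matrix_effect = 1) {
  if (any(spike_concs < 2 * base_conc)) {
    warning("spike levels below twice the background; ",
            "recovery estimates will be noisy")
  }
  rows <- list()
  with_seed(seed, {
    for (i in seq_along(spike_concs)) {
      unspiked <- rlnorm_cv(n_replicates, base_conc, cv)
      spiked <- rlnorm_cv(n_replicates,
                          base_conc + matrix_effect * spike_concs[i], cv)
      rows[[i]] <- data.frame(
        level_label = sprintf("spike_%g", spike_concs[i]),
        expected_added = spike_concs[i],
        replicate = seq_len(n_replicates),
        measured_unspiked = unspiked,
        measured_spiked = spiked)
    }
  })
  do.call(rbind, rows)
}

#' Per-level recovery from a spike experiment table
#'
#' Averages replicates within each level and applies [recovery_pct()].
#'
#' @param spikes A [simulate_spike_experiment()]-shaped data.frame.
#' @return Data.frame `level_label`, `expected_added`, `recovery_pct`.
#' @export
recovery_from_spikes <- function(spikes) {
  parts <- split(spikes, spikes$level_label)
  out <- do.call(rbind, lapply(parts, function(d) {
    data.frame(level_label = d$level_label[1],
               expected_added = d$expected_added[1],
               recovery_pct = recovery_pct(mean(d$measured_spiked),
                                           mean(d$measured_unspiked),
                                           d$expected_added[1]))
  }))
  rownames(out) <- NULL
  out[order(out$expected_added), ]
}

#' Simulate a multi-day precision study
#'
#' Same-day replicates share a lognormal day effect (CV `cv_day`) on top of
#' per-reading noise (CV `cv`), producing intraday and interday variability
#' for [precision_summary()].
#'
#' @param levels Nominal concentrations of the tested levels.
#' @param cv Within-day (plate-reader) CV.
#' @param cv_day Between-day CV.
#' @param seed Integer seed.
#' @param n_replicates Replicates per level per day.
#' @param n_days Number of days.
#' @return Data.frame `level_label`, `nominal_conc`, `day`, `replicate`,
#'   `value`.
#' @export
simulate_precision_study <- function(levels, cv, cv_day = 0.03, seed = 1L,
                                     n_replicates = 3L, n_days = 3L) {
  rows <- list()
  with_seed(seed, {
    for (d in seq_len(n_days)) {
      day_factor <- rlnorm_cv(1, 1, cv_day)
      for (i in seq_along(levels)) {
        vals <- rlnorm_cv(n_replicates, levels[i] * day_factor, cv)
        rows[[length(rows) + 1L]] <- data.frame(
          level_label = sprintf("level_%g", levels[i]),
          nominal_conc = levels[i], day = d,
          replicate = seq_len(n_replicates), value = vals)
      }
    }
  })
  do.call(rbind, rows)
}

#' Simulate a CFU plating observation
#'
#' Poisson colony counts with mean `density * plated_volume /
#' dilution_factor`; the lysed-stage density is the control density times
#' `lysis_survival`. When `dilution_factor` is `NULL` the smallest decade
#' dilution keeping the expected count at or below 300 is chosen, mimicking
#' picking the countable plate from a dilution series.
#'
#' @param params A [simulation_params()] object.
#' @param stage `"control"` or `"lysed"`.
#' @param seed Integer seed.
#' @param plated_volume_ml Plated volume (default 0.1 mL).
#' @param dilution_factor Decade dilution, or `NULL` to auto-select.
#' @param density_per_ml Cell density of the undiluted control suspension;
#'   defaults to `cells_per_ml_per_od * od` at peak biomass.
#' @return A [cfu_count()].
#' @export
simulate_cfu <- function(params = simulation_params(),
                         stage = c("control", "lysed"), seed = 1L,
                         plated_volume_ml = 0.1, dilution_factor = NULL,
                         density_per_ml = NULL) {
  stage <- match.arg(stage)
  p <- params
  if (is.null(density_per_ml)) {
    density_per_ml <- p$cells_per_ml_per_od * (p$x_max / p$od_biomass_factor)
  }
  if (stage == "lysed") density_per_ml <- density_per_ml * p$lysis_survival
  expected_undiluted <- density_per_ml * plated_volume_ml
  if (is.null(dilution_factor)) {
    dilution_factor <- 10^max(0, ceiling(log10(max(expected_undiluted, 1) / 300)))
  }
  lambda <- expected_undiluted / dilution_factor
  colonies <- with_seed(seed, stats::rpois(1, lambda))
  cfu_count(colonies, plated_volume_ml, dilution_factor)
}
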