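#' Measure with saturation gating and blank correction
#'
#' Emulates the bench rule for saturated wells: take a reading; if it exceeds
#' the gate, re-measure after the [saturation_plan()] power-of-two dilution
#' and scale back. Returned values are blank-corrected and
#' dilution-corrected.
#'
#' @param true_rfu True blank-free signals.
#' @param cv Plate-reader CV.
#' @param blank_mean Blank RFU added to each raw reading.
#' @param threshold Saturation gate (default 49000 RFU).
#' @param seed Integer seed.
#' @param n_replicates Technical replicates per sample.
#' @return Data.frame `index`, `replicate`, `dilution_factor`, `rfu_raw`,
#'   `rfu_corrected`.
#' @export
measure_with_gating <- function(true_rfu, cv, blank_mean = 0,
                                threshold = 49000, seed = 1L,
                                n_replicates = 1L) {
  first <- simulate_plate_readings(true_rfu, cv = cv, blank_mean = blank_mean,
                                   seed = seed, n_replicates = n_replicates)
  plan <- saturation_plan(first$rfu, threshold = threshold)
  out <- data.frame(index = first$index, replicate = first$replicate,
                    dilution_factor = plan$factor, rfu_raw = first$rfu,
                    rfu_corrected = NA_real_)
  ok <- !plan$remeasure
  out$rfu_corrected[ok] <- as.numeric(blank_correct(first$rfu[ok], blank_mean))
  if (any(!ok)) {
    redo <- simulate_plate_readings(
      first$true_value[!ok] / plan$factor[!ok], cv = cv,
      blank_mean = blank_mean, seed = seed + 1L)
    out$rfu_corrected[!ok] <-
      as.numeric(blank_correct(redo$rfu, blank_mean)) * plan$factor[!ok]
  }
  out
}

#' Run the full quantification and validation pipeline on synthetic data
#'
#' Executes, in order: standard-curve measurement with blank correction and
#' saturation gating; linear calibration with LOD/LOQ; spike-recovery and
#' multi-day precision studies; producer/control cultivation with observation
#' noise; gel lane quantification against Bradford-basis HCP; conversion-model
#' fit over the window from inoculation to the RFU maximum; in-cell vs.
#' lysate correlation; background assessment; and the validation battery.
#'
#' The conversion model is fitted on points pooled from `n_cultures`
#' replicate cultivations (each with its own observation and gel noise),
#' mirroring a triplicate-cultivation study design, with
#' inverse-squared-response weights (constant-CV noise).
#'
#' @param params A [simulation_params()] object; its `seed` drives every
#'   stochastic stage (each stage uses a distinct derived sub-seed).
#' @param thresholds A [validation_thresholds()] object.
#' @param n_cultures Replicate cultivations pooled into the conversion fit.
#' @param saturation_threshold Saturation gate for standard readings, RFU.
#' @param out_dir Optional directory: writes `report.json`, `report.md`,
#'   `conversion_model.json` and `timecourse_quantified.tsv`.
#' @return A `pipeline_result` list: `report` (validation report),
#'   `conversion` (conversion model), `paired` (in-cell vs. lysate),
#'   `background`, `timecourse` (producer time course with `conc_est_mg_l`),
#'   `calibration`, `depletion_time_h`, `exit_code` (0 pass, 2 validation
#'   failure).
#' @examples
#' \donttest{
#' res <- run_pipeline(simulation_params(seed = 7))
#' res$report$verdict
#' res$conversion
#' }
#' @export
run_pipeline <- function(params = simulation_params(),
                         thresholds = validation_thresholds(),
                         n_cultures = 3L,
                         saturation_threshold = 49000,
                         out_dir = NULL) {
  p <- params
  seed <- p$seed

  # -- standard calibration (cell-free EmGFP standard dilution series) -----
  stock_mg_l <- 12600
  factors <- c(100, 200, 267, 400, 667, 1000, 1250, 2000)
  conc_levels <- dilute(stock_mg_l, factors)
  conc <- rep(conc_levels, each = 3L)
  meas <- measure_with_gating(p$std_slope * conc, cv = p$cv_rfu,
                              blank_mean = p$blank_rfu,
                              threshold = saturation_threshold,
                              seed = seed + 101L)
  if (all(meas$dilution_factor > 1)) {
    fq_stop("fluoquant_saturation_error", paste0(
      "[calibration] every standard reading exceeds the saturation gate (",
      saturation_threshold, " RFU); raise the gate or lower the detector ",
      "gain before quantifying"))
  }
  curve <- fit_linear_calibration(conc, meas$rfu_corrected, conc_unit = "mg/L")

  # -- accuracy / recovery -------------------------------------------------
  spikes <- simulate_spike_experiment(
    base_conc = min(conc_levels), spike_concs = dilute(stock_mg_l, c(1000, 667, 400, 200)),
    cv = p$cv_rfu, seed = seed + 103L, n_replicates = 3L)
  recoveries <- recovery_from_spikes(spikes)

  # -- precision -----------------------------------------------------------
  precision_raw <- simulate_precision_study(
    levels = dilute(stock_mg_l, c(2000, 1000, 400, 200)),
    cv = p$cv_rfu, cv_day = p$cv_day, seed = seed + 104L)
  precisions <- precision_summary(precision_raw)

  # -- cultivation, observation, gel quantification ------------------------
  producer <- simulate_cultivation(p, "producer")
  control <- simulate_cultivation(p, "control")
  dep_t <- depletion_time(producer, p$depletion_glucose)
  producer_obs <- observe_timecourse(producer, cv = p$cv_rfu, seed = seed + 105L)
  control_obs <- observe_timecourse(control, cv = p$cv_rfu, seed = seed + 106L)

  # -- conversion fit: replicate cultures, inoculation through RFU max -----
  conc_pool <- numeric(0); rfu_pool <- numeric(0); lanes <- NULL
  for (k in seq_len(n_cultures)) {
    obs_k <- if (k == 1L) producer_obs else {
      observe_timecourse(producer, cv = p$cv_rfu, seed = seed + 105L + 10L * k)
    }
    gel_k <- simulate_gel(producer, p, seed = seed + 107L + 10L * k)
    lanes_k <- quantify_gel(gel_k$gel, gel_k$hcp)
    if (k == 1L) lanes <- lanes_k
    i_peak <- which.max(obs_k$rfu_cell)
    window <- obs_k$time_h <= obs_k$time_h[i_peak]
    conc_pool <- c(conc_pool,
                   lanes_k$target_mg_l[match(obs_k$time_h[window],
                                             lanes_k$timepoint_h)])
    rfu_pool <- c(rfu_pool, obs_k$rfu_cell[window])
  }
  conversion <- fit_conversion(conc_pool, rfu_pool,
                               weighting = "inverse_response_sq")

  # -- in-cell vs. lysate and background -----------------------------------
  paired <- fit_incell_vs_lysate(producer_obs$rfu_cell,
                                 producer_obs$rfu_lysate)
  background <- assess_background(producer_obs, control_obs,
                                  depletion_time = dep_t)

  # -- validation battery and quantified time course -----------------------
  report <- validate_method(curve, recoveries, precisions, thresholds)
  quant <- quantify_rfu(conversion, producer_obs$rfu_cell)
  producer_obs$conc_est_mg_l <- quant$conc_mg_l
  producer_obs$out_of_range <- quant$out_of_range

  result <- structure(
    list(report = report, conversion = conversion, paired = paired,
         background = background, timecourse = producer_obs,
         control_timecourse = control_obs, calibration = curve,
         lanes = lanes, recoveries = recoveries, precisions = precisions,
         depletion_time_h = dep_t,
         exit_code = if (report$verdict == "pass") 0L else 2L),
    class = "pipeline_result"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    report_json(report, file.path(out_dir, "report.json"))
    report_markdown(report, file.path(out_dir, "report.md"))
    write_conversion_model(conversion, file.path(out_dir, "conversion_model.json"))
    write_timecourse(producer_obs, file.path(out_dir, "timecourse_quantified.tsv"))
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  validation verdict: %s (exit code %d)\n",
              x$report$verdict, x$exit_code))
  cat(sprintf("  conversion: rfu = %.5g * conc + %.5g (R^2 %.4f)\n",
              x$conversion$slope_a, x$conversion$intercept_b,
              x$conversion$r_squared))
  cat(sprintf("  in-cell vs lysate max deviation: %.2f%%\n",
              x$paired$max_abs_dev_pct))
  cat(sprintf("  max background fraction: %.2f%%\n",
              x$background$background_fraction_max))
  invisible(x)
}
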