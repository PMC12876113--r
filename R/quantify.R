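#' Densitometric lane fraction of the target band
#'
#' Fraction (in percent) of a lane's total band intensity attributable to the
#' target protein band, identified by apparent molecular weight within a
#' +/- `window` kDa window around `target_mw` (default 27 kDa, the apparent
#' size of EmGFP on a gel).
#'
#' @param band_mw_kda Apparent molecular weights of the lane's bands in kDa.
#' @param intensity Densitometry intensities (arbitrary units), same length.
#' @param target_mw Target band apparent MW in kDa.
#' @param window Matching half-window in kDa.
#' @return Lane intensity percentage in `[0, 100]`.
#' @export
lane_intensity_pct <- function(band_mw_kda, intensity, target_mw = 27, window = 2) {
  if (length(band_mw_kda) == 0L || length(band_mw_kda) != length(intensity)) {
    fq_stop("fluoquant_invalid_input", "bands must be non-empty and aligned")
  }
  if (any(intensity < 0)) {
    fq_stop("fluoquant_invalid_input", "band intensities must be >= 0")
  }
  total <- sum(intensity)
  if (total <= 0) return(0)
  hit <- abs(band_mw_kda - target_mw) <= window
  100 * sum(intensity[hit]) / total
}

#' Absolute target-protein concentration from a gel lane
#'
#' Apportions the paired host-cell-protein (HCP) concentration to the target
#' protein by its densitometric lane fraction:
#' `conc = (lane_intensity_pct / 100) * hcp_conc`. Both quantities must refer
#' to the same (culture-volume) basis; load volume and sample-to-buffer ratio
#' cancel when they do, and enter only as consistency metadata.
#'
#' @param lane_pct Target-band lane intensity in percent, in `[0, 100]`.
#' @param hcp_conc Paired HCP concentration in mg/L (culture basis).
#' @return Target-protein concentration in mg/L; never exceeds `hcp_conc`.
#' @examples
#' target_conc_from_lane(15.27, 1275.2)  # ~194.7 mg/L
#' @export
target_conc_from_lane <- function(lane_pct, hcp_conc) {
  if (any(lane_pct < 0 | lane_pct > 100, na.rm = TRUE)) {
    fq_stop("fluoquant_invalid_input", "lane_pct must lie in [0, 100]")
  }
  if (any(hcp_conc < 0, na.rm = TRUE)) {
    fq_stop("fluoquant_invalid_input", "hcp_conc must be >= 0")
  }
  (lane_pct / 100) * hcp_conc
}

#' Quantify a long-format gel table against paired HCP values
#'
#' Joins a per-band densitometry table with per-timepoint HCP concentrations
#' and returns the target-band lane percentage and absolute concentration per
#' lane. Pre-summarised tables (with a `lane_intensity_pct` column) are
#' accepted as-is.
#'
#' @param gel Long data.frame `lane_id`, `timepoint_h`, `band_mw_kda`,
#'   `band_intensity`, or pre-summarised `lane_id`, `timepoint_h`,
#'   `lane_intensity_pct`.
#' @param hcp Data.frame `timepoint_h`, `hcp_mg_l`.
#' @param target_mw,window Passed to [lane_intensity_pct()].
#' @return Data.frame `lane_id`, `timepoint_h`, `lane_pct`, `hcp_mg_l`,
#'   `target_mg_l`.
#' @export
quantify_gel <- function(gel, hcp, target_mw = 27, window = 2) {
  if (!"lane_intensity_pct" %in% names(gel)) {
    need <- c("lane_id", "timepoint_h", "band_mw_kda", "band_intensity")
    if (!all(need %in% names(gel))) {
      fq_stop("fluoquant_schema_error",
              "gel table needs lane_id, timepoint_h, band_mw_kda, band_intensity")
    }
    parts <- split(gel, gel$lane_id)
    gel <- do.call(rbind, lapply(parts, function(d) {
      data.frame(lane_id = d$lane_id[1], timepoint_h = d$timepoint_h[1],
                 lane_intensity_pct = lane_intensity_pct(
                   d$band_mw_kda, d$band_intensity, target_mw, window))
    }))
  }
  if (!all(c("timepoint_h", "hcp_mg_l") %in% names(hcp))) {
    fq_stop("fluoquant_schema_error", "hcp table needs timepoint_h, hcp_mg_l")
  }
  merged <- merge(gel, hcp[, c("timepoint_h", "hcp_mg_l")], by = "timepoint_h")
  data.frame(
    lane_id = merged$lane_id,
    timepoint_h = merged$timepoint_h,
    lane_pct = merged$lane_intensity_pct,
    hcp_mg_l = merged$hcp_mg_l,
    target_mg_l = target_conc_from_lane(merged$lane_intensity_pct, merged$hcp_mg_l)
  )
}

#' Rescale a lysate concentration to the culture-volume basis
#'
#' A pellet from `culture_volume` of culture resuspended in
#' `resuspension_volume` of lysis buffer concentrates (or dilutes) the
#' analyte by the volume ratio; this maps the lysate measurement back to
#' mg per L of culture. The default ratio 510/1000 reflects a 1-mL culture
#' pellet taken up in 500 uL buffer plus 10 uL protease-inhibitor reagent.
#'
#' @param conc_lysate Concentration measured in the lysate, mg/L.
#' @param resuspension_volume_ul Lysate volume in uL (default 510).
#' @param culture_volume_ul Original culture volume in uL (default 1000).
#' @return Concentration on the culture basis, mg/L.
#' @export
lysate_to_culture_basis <- function(conc_lysate, resuspension_volume_ul = 510,
                                    culture_volume_ul = 1000) {
  if (any(resuspension_volume_ul <= 0) || any(culture_volume_ul <= 0)) {
    fq_stop("fluoquant_invalid_input", "volumes must be positive")
  }
  conc_lysate * resuspension_volume_ul / culture_volume_ul
}

#' Correlate in-cell and post-lysis fluorescence
#'
#' Least-squares line of the in-cell (cell suspension) RFU on the lysate
#' (soluble protein fraction) RFU across matched timepoints, plus the maximum
#' relative deviation `100 * |cell - lysate| / lysate`. Timepoints whose
#' lysate RFU falls below `min_lysate` (a low-signal/LOQ-equivalent floor)
#' are excluded from the deviation to avoid division blow-up. The in-cell
#' measurement is declared interchangeable with the lysate measurement
#' (`negligible = TRUE`) when the maximum deviation stays at or below
#' `neglect_threshold` (default 12%).
#'
#' @param rfu_cell,rfu_lysate Matched RFU vectors, >= 3 pairs.
#' @param min_lysate Low-signal floor on the lysate RFU for the deviation
#'   metric (default 0 = use all positive-lysate pairs).
#' @param neglect_threshold Percent deviation below which the in-cell signal
#'   is treated as equivalent.
#' @return A `paired_correlation`: `slope`, `intercept`, `r_squared`,
#'   `max_abs_dev_pct`, `negligible`, `n`, `n_dev`.
#' @export
fit_incell_vs_lysate <- function(rfu_cell, rfu_lysate, min_lysate = 0,
                                 neglect_threshold = 12) {
  if (length(rfu_cell) != length(rfu_lysate) || length(rfu_cell) < 3L) {
    fq_stop("fluoquant_degenerate_design",
            "need >= 3 matched (cell, lysate) RFU pairs")
  }
  fit <- stats::lm(rfu_cell ~ rfu_lysate)
  keep <- rfu_lysate > max(min_lysate, 0)
  dev <- 100 * abs(rfu_cell[keep] - rfu_lysate[keep]) / rfu_lysate[keep]
  max_dev <- if (length(dev)) max(dev) else NA_real_
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = r_squared_of(fit, rfu_cell),
         max_abs_dev_pct = max_dev,
         negligible = isTRUE(max_dev <= neglect_threshold),
         n = length(rfu_cell), n_dev = sum(keep)),
    class = "paired_correlation"
  )
}

#' @export
print.paired_correlation <- function(x, ...) {
  cat(sprintf(
    "<paired_correlation> cell = %.5g * lysate + %.5g (R^2 %.4f)\n",
    x$slope, x$intercept, x$r_squared))
  cat(sprintf("  max |cell - lysate|/lysate = %.2f%% over %d timepoints (%s)\n",
              x$max_abs_dev_pct, x$n_dev,
              if (x$negligible) "negligible" else "not negligible"))
  invisible(x)
}

#' Fit the RFU-to-concentration conversion model
#'
#' Affine least-squares fit of cell-suspension RFU on absolute target-protein
#' concentration, `rfu = slope_a * conc + intercept_b`, over the expression
#' window from inoculation to the RFU maximum. The model carries a hard
#' validity range: `rfu_valid_max` is the largest calibration RFU seen, and
#' extrapolation beyond it is refused by [rfu_to_conc()].
#'
#' Plate-reader noise is scale-proportional (roughly constant CV), so the
#' pipeline fits with inverse-squared-response weights
#' (`weighting = "inverse_response_sq"`), the usual weighting for
#' bioanalytical calibration over a wide dynamic range; the unweighted fit
#' remains the default for plain least-squares use.
#'
#' @param conc_mg_l Absolute concentrations (mg/L, culture basis).
#' @param rfu_cell Matched cell-suspension RFU values.
#' @param weighting `"none"` (ordinary least squares) or
#'   `"inverse_response_sq"` (weights `1 / rfu^2`).
#' @return A `conversion_model`: `slope_a`, `intercept_b`, `r_squared`,
#'   `rfu_valid_max`, `conc_valid_max`, `n`.
#' @export
fit_conversion <- function(conc_mg_l, rfu_cell,
                           weighting = c("none", "inverse_response_sq")) {
  weighting <- match.arg(weighting)
  keep <- is.finite(conc_mg_l) & is.finite(rfu_cell)
  conc_mg_l <- conc_mg_l[keep]; rfu_cell <- rfu_cell[keep]
  if (length(conc_mg_l) < 3L || length(unique(conc_mg_l)) < 3L) {
    fq_stop("fluoquant_degenerate_design",
            "conversion fit needs >= 3 points with distinct concentrations")
  }
  w <- if (weighting == "inverse_response_sq") {
    1 / pmax(rfu_cell, .Machine$double.eps)^2
  } else {
    rep(1, length(rfu_cell))
  }
  fit <- stats::lm(rfu_cell ~ conc_mg_l, weights = w)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (!is.finite(slope) || slope <= 0) {
    fq_stop("fluoquant_degenerate_design",
            "conversion response is not increasing with concentration")
  }
  # plain (unweighted) coefficient of determination, whatever the weighting
  r2 <- 1 - sum((rfu_cell - stats::fitted(fit))^2) /
    sum((rfu_cell - mean(rfu_cell))^2)
  rfu_max <- max(rfu_cell)
  structure(
    list(slope_a = slope, intercept_b = intercept,
         r_squared = r2,
         rfu_valid_max = rfu_max,
         conc_valid_max = (rfu_max - intercept) / slope,
         n = length(conc_mg_l)),
    class = "conversion_model"
  )
}

#' @export
print.conversion_model <- function(x, ...) {
  cat(sprintf("<conversion_model> rfu = %.5g * conc + %.5g (R^2 %.4f)\n",
              x$slope_a, x$intercept_b, x$r_squared))
  cat(sprintf("  valid up to %.5g RFU (= %.5g mg/L), n = %d\n",
              x$rfu_valid_max, x$conc_valid_max, x$n))
  invisible(x)
}

#' Convert RFU readings to absolute concentrations
#'
#' Inverts the conversion model: `conc = (rfu - intercept_b) / slope_a`.
#' Readings below the intercept map to 0 mg/L and are flagged via the
#' `"below_calibration"` attribute. Readings above `rfu_valid_max` are a hard
#' error (`fluoquant_range_error`): the model must not be extrapolated, and
#' the error condition carries the [saturation_plan()] dilution factor that
#' would bring the reading back into range.
#'
#' @param model A [fit_conversion()] result.
#' @param rfu RFU value(s) to convert.
#' @return Concentration(s) in mg/L with a logical `"below_calibration"`
#'   attribute.
#' @seealso [quantify_rfu()] for a non-throwing vectorised wrapper.
#' @export
rfu_to_conc <- function(model, rfu) {
  stopifnot(inherits(model, "conversion_model"))
  over <- rfu > model$rfu_valid_max
  if (any(over, na.rm = TRUE)) {
    plan <- saturation_plan(max(rfu[over]), threshold = model$rfu_valid_max)
    fq_stop("fluoquant_range_error",
            sprintf(paste0(
              "RFU %.5g exceeds the conversion model's validity range ",
              "(max %.5g); re-measure after a %d-fold dilution"),
              max(rfu[over]), model$rfu_valid_max, as.integer(plan$factor)),
            suggested_dilution = plan$factor)
  }
  conc <- (rfu - model$intercept_b) / model$slope_a
  below <- conc < 0
  conc[below] <- 0
  attr(conc, "below_calibration") <- below
  conc
}

#' @rdname rfu_to_conc
#' @param conc_mg_l Concentration(s) to map to expected RFU.
#' @export
conc_to_rfu <- function(model, conc_mg_l) {
  stopifnot(inherits(model, "conversion_model"))
  model$slope_a * conc_mg_l + model$intercept_b
}

#' Vectorised, non-throwing RFU quantification
#'
#' Applies [rfu_to_conc()] per reading, converting out-of-range readings into
#' rows flagged `out_of_range` (with the suggested dilution factor) instead
#' of aborting; for pipeline use on noisy series.
#'
#' @inheritParams rfu_to_conc
#' @return Data.frame `rfu`, `conc_mg_l`, `below_calibration`,
#'   `out_of_range`, `suggested_dilution`.
#' @export
quantify_rfu <- function(model, rfu) {
  out <- data.frame(rfu = rfu, conc_mg_l = NA_real_,
                    below_calibration = FALSE, out_of_range = FALSE,
                    suggested_dilution = 1)
  for (i in seq_along(rfu)) {
    res <- tryCatch(rfu_to_conc(model, rfu[i]), fluoquant_range_error = identity)
    if (inherits(res, "condition")) {
      out$out_of_range[i] <- TRUE
      out$suggested_dilution[i] <- res$suggested_dilution
    } else {
      out$conc_mg_l[i] <- as.numeric(res)
      out$below_calibration[i] <- attr(res, "below_calibration")
    }
  }
  out
}

#' Persist / restore a conversion model as JSON
#'
#' Numbers are written unrounded, together with provenance metadata
#' (timestamp and, when input files are named, their MD5 digests).
#'
#' @param model A [fit_conversion()] result.
#' @param path JSON file path.
#' @param inputs Optional character vector of input files to digest.
#' @return `write_conversion_model()` the path; `read_conversion_model()`
#'   the restored `conversion_model`.
#' @export
write_conversion_model <- function(model, path, inputs = character()) {
  stopifnot(inherits(model, "conversion_model"))
  payload <- c(unclass(model), list(
    provenance = list(
      written_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      input_digests = if (length(inputs)) as.list(tools::md5sum(inputs)) else NULL
    )))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_conversion_model
#' @export
read_conversion_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(payload[c("slope_a", "intercept_b", "r_squared",
                      "rfu_valid_max", "conc_valid_max", "n")],
            class = "conversion_model")
}

#' Assess background and autofluorescence against a control strain
#'
#' Compares the producer-strain cell-suspension signal S with the
#' plasmid-free control strain's autofluorescence F' on a matched time grid.
#' Reports per-phase (growth vs. stationary, split at the glucose-depletion
#' time) means of the signal-to-background ratio S/F', the raw background
#' RFU, and the biomass-specific autofluorescence F'/X', plus the maximum
#' background fraction `100 * F'/S` over all timepoints.
#'
#' @param producer,control Time-course data.frames (see
#'   [simulate_cultivation()] / [read_timecourse()]) sharing an identical
#'   `time_h` grid; the control's `rfu_cell` is the background F' and its
#'   `biomass_g_l` is X'.
#' @param depletion_time Glucose-depletion time in h; timepoints at or before
#'   it form the growth phase.
#' @return A `background_assessment`: `sbr_by_phase`,
#'   `background_fraction_max`, `autofl_per_biomass_by_phase`,
#'   `background_mean_by_phase`, and the per-timepoint table.
#' @export
assess_background <- function(producer, control, depletion_time) {
  if (length(producer$time_h) != length(control$time_h) ||
      any(producer$time_h != control$time_h)) {
    fq_stop("fluoquant_alignment_error",
            "producer and control time grids must match exactly")
  }
  phase <- ifelse(producer$time_h <= depletion_time, "growth", "stationary")
  s <- producer$rfu_cell
  f <- control$rfu_cell
  x <- control$biomass_g_l
  per_tp <- data.frame(time_h = producer$time_h, phase = phase,
                       signal = s, background = f,
                       sbr = s / f, background_pct = 100 * f / s,
                       autofl_per_biomass = f / x)
  by_phase <- function(v) vapply(split(v, phase), mean, numeric(1))
  structure(
    list(sbr_by_phase = by_phase(per_tp$sbr),
         background_fraction_max = max(per_tp$background_pct),
         autofl_per_biomass_by_phase = by_phase(per_tp$autofl_per_biomass),
         background_mean_by_phase = by_phase(f),
         per_timepoint = per_tp),
    class = "background_assessment"
  )
}

#' @export
print.background_assessment <- function(x, ...) {
  cat("<background_assessment>\n")
  cat(sprintf("  SBR: growth %.3g, stationary %.3g\n",
              x$sbr_by_phase["growth"], x$sbr_by_phase["stationary"]))
  cat(sprintf("  max background fraction F'/S: %.2f%%\n",
              x$background_fraction_max))
  cat(sprintf("  F'/X': growth %.3g, stationary %.3g RFU per g/L\n",
              x$autofl_per_biomass_by_phase["growth"],
              x$autofl_per_biomass_by_phase["stationary"]))
  invisible(x)
}

#' Colony-count record from a plating experiment
#'
#' @param colonies Colony count on the plate (integer >= 0).
#' @param plated_volume_ml Plated volume in mL.
#' @param dilution_factor Total dilution of the suspension before plating.
#' @return A `cfu_count`; `countable` is TRUE for 30-300 colonies, the
#'   accepted counting window.
#' @export
cfu_count <- function(colonies, plated_volume_ml, dilution_factor = 1) {
  if (colonies < 0 || colonies != round(colonies)) {
    fq_stop("fluoquant_invalid_input", "colonies must be a non-negative integer")
  }
  if (plated_volume_ml <= 0 || dilution_factor < 1) {
    fq_stop("fluoquant_invalid_input",
            "plated_volume_ml must be > 0 and dilution_factor >= 1")
  }
  structure(
    list(colonies = as.integer(colonies), plated_volume_ml = plated_volume_ml,
         dilution_factor = dilution_factor,
         countable = colonies >= 30 && colonies <= 300),
    class = "cfu_count"
  )
}

#' @rdname cfu_count
#' @param x A `cfu_count`.
#' @export
cfu_per_ml <- function(x) {
  stopifnot(inherits(x, "cfu_count"))
  x$colonies * x$dilution_factor / x$plated_volume_ml
}

#' Cell-lysis efficiency from colony counts
#'
#' `100 * (1 - CFU/mL after lysis / CFU/mL before lysis)`. Counts outside the
#' 30-300 countable window are still used but trigger a warning.
#'
#' @param control A [cfu_count()] from the untreated suspension.
#' @param lysed A [cfu_count()] from the lysed suspension.
#' @return Lysis efficiency in percent.
#' @export
lysis_efficiency <- function(control, lysed) {
  stopifnot(inherits(control, "cfu_count"), inherits(lysed, "cfu_count"))
  if (!control$countable || !lysed$countable) {
    warning("colony count outside the countable 30-300 window; ",
            "efficiency estimate may be unreliable")
  }
  ctrl_density <- cfu_per_ml(control)
  if (ctrl_density == 0) {
    fq_stop("fluoquant_undefined_efficiency",
            "control CFU/mL is zero; lysis efficiency undefined")
  }
  100 * (1 - cfu_per_ml(lysed) / ctrl_density)
}
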