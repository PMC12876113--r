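#' Fit a linear calibration curve
#'
#' Ordinary least-squares fit of instrument response against nominal
#' concentration, the basis for linearity assessment and LOD/LOQ estimation.
#' The low-level response SD `sigma_low` is, by default, the sample standard
#' deviation (n-1 denominator) of the replicate responses at the lowest
#' non-blank concentration level; set `sigma_mode = "residual"` to use the
#' residual standard deviation of the regression instead.
#'
#' @param conc Nominal concentrations, one per response (replicates repeat the
#'   level), or a data.frame with columns `nominal_conc` and `value`.
#' @param response Instrument responses (RFU or absorbance); ignored when
#'   `conc` is a data.frame.
#' @param sigma_mode `"replicate"` (default) or `"residual"`.
#' @param conc_unit Concentration unit label carried into reports.
#'
#' @return A `calibration_curve` with elements `slope`, `intercept`,
#'   `r_squared`, `sigma_low`, `n_levels`, `n_replicates` (at the lowest
#'   non-blank level), `response_range`, `conc_unit`, `sigma_mode`.
#' @examples
#' conc <- rep(c(6.3, 12.6, 31.5, 63), each = 3)
#' rfu  <- 778.5 * conc + rnorm(length(conc), sd = 30)
#' fit_linear_calibration(conc, rfu, conc_unit = "mg/L")
#' @export
fit_linear_calibration <- function(conc, response = NULL,
                                   sigma_mode = c("replicate", "residual"),
                                   conc_unit = "mg/L") {
  sigma_mode <- match.arg(sigma_mode)
  if (is.data.frame(conc)) {
    if (!all(c("nominal_conc", "value") %in% names(conc))) {
      fq_stop("fluoquant_schema_error",
              "data.frame input needs columns nominal_conc and value")
    }
    response <- conc$value
    conc <- conc$nominal_conc
  }
  keep <- is.finite(conc) & is.finite(response)
  conc <- conc[keep]; response <- response[keep]
  levels_ <- sort(unique(conc))
  if (length(levels_) < 3L || diff(range(conc)) <= 0) {
    fq_stop("fluoquant_degenerate_design",
            "calibration needs >= 3 distinct concentration levels with spread")
  }
  fit <- stats::lm(response ~ conc)
  coefs <- stats::coef(fit)
  r2 <- r_squared_of(fit, response)

  low <- min(levels_[levels_ > 0])
  low_resp <- response[conc == low]
  n_rep <- length(low_resp)
  if (sigma_mode == "replicate" && n_rep >= 2L) {
    sigma_low <- stats::sd(low_resp)
  } else {
    if (sigma_mode == "replicate") {
      warning("fewer than 2 replicates at the lowest non-blank level; ",
              "using residual SD for sigma_low")
    }
    sigma_low <- sqrt(sum(stats::resid(fit)^2) / fit$df.residual)
    sigma_mode <- "residual"
  }

  structure(
    list(slope = unname(coefs["conc"]), intercept = unname(coefs["(Intercept)"]),
         r_squared = r2, sigma_low = sigma_low,
         n_levels = length(levels_), n_replicates = n_rep,
         conc_unit = conc_unit, response_range = range(response),
         lowest_level = low, sigma_mode = sigma_mode),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> response = %.4g * conc + %.4g  (R^2 %.4f)\n",
    x$slope, x$intercept, x$r_squared))
  cat(sprintf("  %d levels, sigma_low %.4g (%s, n = %d at %.4g %s)\n",
              x$n_levels, x$sigma_low, x$sigma_mode, x$n_replicates,
              x$lowest_level, x$conc_unit))
  invisible(x)
}

#' Limits of detection and quantification
#'
#' `LOD = 3.3 * sigma / S` and `LOQ = 10 * sigma / S`, where `sigma` is the
#' low-level response SD and `S` the calibration slope; both are returned in
#' the curve's concentration units. `loq(x)` is exactly `(10 / 3.3) * lod(x)`.
#'
#' @param curve A [fit_linear_calibration()] result (or any list with
#'   `slope` and `sigma_low`).
#' @return Concentration in the curve's units.
#' @export
lod <- function(curve) {
  if (!is.numeric(curve$slope) || curve$slope <= 0) {
    fq_stop("fluoquant_nonquantitative",
            "calibration slope must be positive for LOD/LOQ")
  }
  3.3 * curve$sigma_low / curve$slope
}

#' @rdname lod
#' @export
loq <- function(curve) {
  if (!is.numeric(curve$slope) || curve$slope <= 0) {
    fq_stop("fluoquant_nonquantitative",
            "calibration slope must be positive for LOD/LOQ")
  }
  10 * curve$sigma_low / curve$slope
}

#' Spike recovery
#'
#' `100 * (measured_spiked - measured_unspiked) / expected_added`, the
#' standard-addition recovery used to assess matrix effects of the cell
#' suspension background.
#'
#' @param measured_spiked,measured_unspiked Measured concentrations (same
#'   units as `expected_added`); vectorised.
#' @param expected_added Known spiked amount; must be positive.
#' @param ph_mismatch Flag spike pairs measured at a different pH than the
#'   matrix (e.g. fluorescein at pH 13 into pH 7 suspensions); such
#'   recoveries are computed but carried with a `"ph_mismatch"` attribute so
#'   reports can set them aside.
#' @return Recovery in percent.
#' @export
recovery_pct <- function(measured_spiked, measured_unspiked, expected_added,
                         ph_mismatch = FALSE) {
  if (any(expected_added <= 0)) {
    fq_stop("fluoquant_invalid_input", "expected_added must be > 0")
  }
  out <- 100 * (measured_spiked - measured_unspiked) / expected_added
  if (any(ph_mismatch)) attr(out, "ph_mismatch") <- rep_len(ph_mismatch, length(out))
  out
}

#' Relative standard deviation
#'
#' `100 * sd(x) / mean(x)` with the n-1 sample SD; the precision metric for
#' intraday (repeatability) and interday (reproducibility) assessment.
#'
#' @param values Numeric vector, length >= 2, with non-zero mean.
#' @return RSD in percent.
#' @export
rsd_pct <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) {
    fq_stop("fluoquant_invalid_input", "RSD needs at least 2 values")
  }
  m <- mean(values)
  if (m == 0) {
    fq_stop("fluoquant_undefined_rsd", "RSD undefined for zero mean")
  }
  100 * stats::sd(values) / m
}

#' Summarise a precision study into per-level RSDs
#'
#' Takes raw replicate readings from a precision study and computes, per
#' concentration level, the intraday RSD (replicates within each day; the
#' worst day is reported) and the interday RSD (all readings across days).
#'
#' @param df A data.frame with columns `level_label`, `day`, `value`.
#' @return A data.frame with columns `level_label`, `mode`
#'   (`"intraday"`/`"interday"`), `rsd_pct`, `n`.
#' @export
precision_summary <- function(df) {
  need <- c("level_label", "day", "value")
  if (!all(need %in% names(df))) {
    fq_stop("fluoquant_schema_error",
            "precision table needs columns level_label, day, value")
  }
  out <- list()
  for (lev in unique(df$level_label)) {
    d <- df[df$level_label == lev, ]
    intraday <- vapply(split(d$value, d$day), rsd_pct, numeric(1))
    out[[length(out) + 1L]] <- data.frame(
      level_label = lev, mode = "intraday",
      rsd_pct = max(intraday), n = max(table(d$day)))
    if (length(unique(d$day)) >= 2L) {
      out[[length(out) + 1L]] <- data.frame(
        level_label = lev, mode = "interday",
        rsd_pct = rsd_pct(d$value), n = nrow(d))
    }
  }
  do.call(rbind, out)
}
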