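#' Validation acceptance thresholds
#'
#' Defaults follow the analytical-method validation guidance the workflow is
#' assessed against: calibration R^2 >= 0.99, spike recovery within +/- 15%
#' of 100%, intraday RSD <= 10%, interday RSD <= 20%. All are configurable.
#'
#' @param min_r_squared Minimum calibration R^2.
#' @param max_recovery_dev_pct Maximum |recovery - 100| in percent.
#' @param max_intraday_rsd_pct Maximum intraday (repeatability) RSD in percent.
#' @param max_interday_rsd_pct Maximum interday (reproducibility) RSD in percent.
#' @return A `validation_thresholds` list.
#' @export
validation_thresholds <- function(min_r_squared = 0.99,
                                  max_recovery_dev_pct = 15,
                                  max_intraday_rsd_pct = 10,
                                  max_interday_rsd_pct = 20) {
  vals <- c(min_r_squared, max_recovery_dev_pct,
            max_intraday_rsd_pct, max_interday_rsd_pct)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    fq_stop("fluoquant_invalid_input", "all thresholds must be positive")
  }
  structure(
    list(min_r_squared = min_r_squared,
         max_recovery_dev_pct = max_recovery_dev_pct,
         max_intraday_rsd_pct = max_intraday_rsd_pct,
         max_interday_rsd_pct = max_interday_rsd_pct),
    class = "validation_thresholds"
  )
}

#' Run the analytical validation battery
#'
#' Evaluates linearity, LOD/LOQ, spike-recovery accuracy and
#' intraday/interday precision against configured thresholds and returns a
#' report with per-criterion pass flags. Missing criterion data yields an NA
#' flag and an overall `"incomplete"` verdict; otherwise the verdict is
#' `"pass"` iff every evaluated criterion passes.
#'
#' @param curve A [fit_linear_calibration()] result.
#' @param recoveries Optional data.frame with either a `recovery_pct` column
#'   or the columns `level_label`, `measured_spiked`, `measured_unspiked`,
#'   `expected_added` from which recoveries are computed.
#' @param precisions Optional data.frame: either a [precision_summary()]
#'   result (`level_label`, `mode`, `rsd_pct`, `n`) or a raw replicate table
#'   (`level_label`, `day`, `value`), which is summarised first.
#' @param thresholds A [validation_thresholds()] object.
#' @return A `validation_report` with elements `curve`, `lod`, `loq`,
#'   `recoveries`, `precisions`, `pass` (named logical, NA = not evaluated),
#'   `thresholds`, `verdict`.
#' @export
validate_method <- function(curve, recoveries = NULL, precisions = NULL,
                            thresholds = validation_thresholds()) {
  stopifnot(inherits(curve, "calibration_curve"))
  lod_ <- lod(curve)
  loq_ <- loq(curve)

  pass <- c(linearity = curve$r_squared >= thresholds$min_r_squared,
            accuracy = NA, intraday = NA, interday = NA)

  if (!is.null(recoveries)) {
    if (!"recovery_pct" %in% names(recoveries)) {
      recoveries$recovery_pct <- recovery_pct(
        recoveries$measured_spiked, recoveries$measured_unspiked,
        recoveries$expected_added)
    }
    dev <- abs(recoveries$recovery_pct - 100)
    pass["accuracy"] <- all(dev <= thresholds$max_recovery_dev_pct)
  }

  if (!is.null(precisions)) {
    if (!"rsd_pct" %in% names(precisions)) {
      precisions <- precision_summary(precisions)
    }
    intr <- precisions$rsd_pct[precisions$mode == "intraday"]
    intr_day <- precisions$rsd_pct[precisions$mode == "interday"]
    if (length(intr)) pass["intraday"] <- all(intr <= thresholds$max_intraday_rsd_pct)
    if (length(intr_day)) pass["interday"] <- all(intr_day <= thresholds$max_interday_rsd_pct)
  }

  verdict <- if (anyNA(pass)) {
    "incomplete"
  } else if (all(pass)) "pass" else "fail"

  structure(
    list(curve = curve, lod = lod_, loq = loq_,
         recoveries = recoveries, precisions = precisions,
         pass = pass, thresholds = thresholds, verdict = verdict),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  cat(sprintf("  R^2 %.4f | LOD %.3g %s | LOQ %.3g %s\n",
              x$curve$r_squared, x$lod, x$curve$conc_unit,
              x$loq, x$curve$conc_unit))
  for (nm in names(x$pass)) {
    flag <- x$pass[[nm]]
    cat(sprintf("  %-9s %s\n", nm,
                if (is.na(flag)) "not evaluated" else if (flag) "pass" else "FAIL"))
  }
  cat("  verdict:", x$verdict, "\n")
  invisible(x)
}

#' Render a validation report as Markdown
#'
#' Produces a compact summary table (concentration basis, R^2, LOD, LOQ per
#' the standard-overview layout) followed by the per-criterion verdicts.
#' Numbers are displayed at 3 significant figures; machine-readable output
#' ([report_json()]) stays unrounded.
#'
#' @param report A [validate_method()] result.
#' @param path Optional file to write to.
#' @return The Markdown lines, invisibly when `path` is given.
#' @export
report_markdown <- function(report, path = NULL) {
  stopifnot(inherits(report, "validation_report"))
  cu <- report$curve$conc_unit
  lines <- c(
    "# Method validation summary",
    "",
    sprintf("| Quantity | Value (%s) |", cu),
    "|---|---|",
    sprintf("| Lowest calibration level | %s |", signif(report$curve$lowest_level, 3)),
    sprintf("| R^2 | %s |", signif(report$curve$r_squared, 3)),
    sprintf("| LOD | %s |", signif(report$lod, 3)),
    sprintf("| LOQ | %s |", signif(report$loq, 3)),
    "",
    "| Criterion | Result |",
    "|---|---|",
    vapply(names(report$pass), function(nm) {
      flag <- report$pass[[nm]]
      sprintf("| %s | %s |", nm,
              if (is.na(flag)) "not evaluated" else if (flag) "pass" else "fail")
    }, character(1)),
    "",
    sprintf("Overall verdict: **%s**", report$verdict)
  )
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Serialise a validation report to JSON
#'
#' All numbers are written unrounded; display rounding is the Markdown
#' renderer's job.
#'
#' @param report A [validate_method()] result.
#' @param path File to write.
#' @return The path, invisibly.
#' @export
report_json <- function(report, path) {
  stopifnot(inherits(report, "validation_report"))
  payload <- list(
    curve = unclass(report$curve),
    lod = report$lod, loq = report$loq,
    recoveries = report$recoveries,
    precisions = report$precisions,
    pass = as.list(report$pass),
    thresholds = unclass(report$thresholds),
    verdict = report$verdict
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
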