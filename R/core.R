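#' Describe a fluorescence calibration standard
#'
#' Bundles the physico-chemical parameters of a calibration standard (in-house
#' EmGFP, commercial GFP, sodium fluorescein, ...) used for unit conversion
#' and calibration bookkeeping.
#'
#' @param name Standard name, e.g. `"Na-F*"`.
#' @param molar_mass Molar mass in g/mol; must be positive.
#' @param stock_conc Stock concentration in mg/L; non-negative.
#' @param purity Mass fraction in (0, 1].
#' @param excitation,emission Excitation/emission maxima in nm (optional).
#' @param solvent Solvent description, e.g. `"100 mM NaOH"`.
#' @param ph Solution pH.
#'
#' @return An object of class `standard_spec`.
#' @examples
#' naf <- standard_spec("Na-F*", molar_mass = 376.27, stock_conc = 0.752,
#'                      solvent = "100 mM NaOH", ph = 13)
#' molar_to_mass_conc(1, naf)
#' @export
standard_spec <- function(name, molar_mass, stock_conc = 0, purity = 1,
                          excitation = NA_real_, emission = NA_real_,
                          solvent = NA_character_, ph = NA_real_) {
  if (!is.numeric(molar_mass) || length(molar_mass) != 1L || !is.finite(molar_mass) ||
      molar_mass <= 0) {
    fq_stop("fluoquant_invalid_input", "molar_mass must be a single positive number")
  }
  if (!is.numeric(stock_conc) || stock_conc < 0) {
    fq_stop("fluoquant_invalid_input", "stock_conc must be >= 0")
  }
  if (!is.numeric(purity) || purity <= 0 || purity > 1) {
    fq_stop("fluoquant_invalid_input", "purity must lie in (0, 1]")
  }
  structure(
    list(name = as.character(name), molar_mass = molar_mass,
         stock_conc = stock_conc, purity = purity,
         excitation = excitation, emission = emission,
         solvent = solvent, ph = ph),
    class = "standard_spec"
  )
}

#' @export
print.standard_spec <- function(x, ...) {
  cat(sprintf("<standard_spec> %s: %.5g g/mol, stock %.5g mg/L, purity %.0f%%\n",
              x$name, x$molar_mass, x$stock_conc, 100 * x$purity))
  invisible(x)
}

#' Convert a molar concentration to a mass concentration
#'
#' Converts micromolar concentrations to mg/L via the standard's molar mass:
#' `conc_umol_l * molar_mass / 1000`. For sodium fluorescein (disodium salt,
#' 376.27 g/mol) this reproduces 1 uM = 0.376 mg/L. Values are returned
#' unrounded; report renderers display 3 significant figures.
#'
#' @param conc_umol_l Concentration in umol/L; vectorised, must be >= 0.
#' @param standard A [standard_spec()] or a bare molar mass in g/mol.
#' @return Mass concentration(s) in mg/L.
#' @export
molar_to_mass_conc <- function(conc_umol_l, standard) {
  molar_mass <- if (inherits(standard, "standard_spec")) standard$molar_mass else standard
  if (!is.numeric(molar_mass) || any(molar_mass <= 0)) {
    fq_stop("fluoquant_invalid_input", "molar mass must be positive")
  }
  if (!is.numeric(conc_umol_l) || any(conc_umol_l < 0, na.rm = TRUE)) {
    fq_stop("fluoquant_invalid_input", "molar concentration must be >= 0")
  }
  conc_umol_l * molar_mass / 1000
}

#' Parse a dilution label
#'
#' Interprets labels of the form `"1:n"` as an n-fold *total* dilution
#' (stock/n), the convention under which a 12.6 g/L stock diluted 1:100 gives
#' 126 mg/L. Plain numbers pass through unchanged.
#'
#' @param label Character label(s) like `"1:200"`, or numeric factor(s).
#' @return Numeric dilution factor(s).
#' @export
parse_dilution_label <- function(label) {
  if (is.numeric(label)) return(label)
  m <- regmatches(label, regexec("^\\s*1\\s*:\\s*([0-9]*\\.?[0-9]+)\\s*$", label))
  out <- vapply(seq_along(label), function(i) {
    if (length(m[[i]]) == 2L) return(as.numeric(m[[i]][2]))
    suppressWarnings(as.numeric(label[i]))
  }, numeric(1))
  if (anyNA(out)) {
    fq_stop("fluoquant_invalid_input",
            sprintf("cannot parse dilution label(s): %s",
                    paste(label[is.na(out)], collapse = ", ")))
  }
  out
}

#' Dilute a stock concentration
#'
#' @param stock_conc Stock concentration (any unit); vectorised.
#' @param factor Dilution factor >= 1, or a `"1:n"` label.
#' @return `stock_conc / factor`, in the stock's units.
#' @examples
#' dilute(12600, 100)   # 12.6 g/L as mg/L, 1:100 -> 126 mg/L
#' dilute(2, "1:20")    # 2.00 uM, 1:20 -> 0.10 uM
#' @export
dilute <- function(stock_conc, factor) {
  factor <- parse_dilution_label(factor)
  if (any(factor < 1)) {
    fq_stop("fluoquant_invalid_input", "dilution factor must be >= 1")
  }
  stock_conc / factor
}

#' Convert optical density to dry biomass concentration
#'
#' `biomass = factor * od600`, with the empirically determined factor in
#' g/L per OD unit (default 0.334).
#'
#' @param od600 Optical density at 600 nm; vectorised, >= 0.
#' @param factor Conversion factor in g dry biomass per L per OD unit.
#' @return Biomass concentration(s) in g/L.
#' @seealso [biomass_to_od()]
#' @export
od_to_biomass <- function(od600, factor = 0.334) {
  if (!is.numeric(od600) || any(od600 < 0, na.rm = TRUE)) {
    fq_stop("fluoquant_invalid_input", "OD600 must be >= 0")
  }
  if (!is.numeric(factor) || any(factor <= 0)) {
    fq_stop("fluoquant_invalid_input", "conversion factor must be positive")
  }
  factor * od600
}

#' @rdname od_to_biomass
#' @param biomass_g_l Biomass concentration(s) in g/L.
#' @export
biomass_to_od <- function(biomass_g_l, factor = 0.334) {
  if (!is.numeric(factor) || any(factor <= 0)) {
    fq_stop("fluoquant_invalid_input", "conversion factor must be positive")
  }
  biomass_g_l / factor
}

#' Plan a re-measurement dilution for saturated readings
#'
#' Readings above the saturation gate (default 49,000 RFU) cannot be used
#' quantitatively and must be re-measured after dilution in PBS. The plan
#' assigns the smallest power-of-two dilution factor (2, 4, 8, ...) that
#' brings the expected signal at or below the gate.
#'
#' @param rfu Observed RFU value(s); >= 0.
#' @param threshold Saturation gate in RFU (default 49000).
#' @return A data.frame with columns `rfu`, `factor` and `remeasure`
#'   (TRUE where a diluted re-measurement is required).
#' @export
saturation_plan <- function(rfu, threshold = 49000) {
  if (!is.numeric(rfu) || any(rfu < 0, na.rm = TRUE)) {
    fq_stop("fluoquant_invalid_input", "rfu must be >= 0")
  }
  if (!is.numeric(threshold) || threshold <= 0) {
    fq_stop("fluoquant_invalid_input", "threshold must be positive")
  }
  factor <- vapply(rfu, function(r) {
    f <- 1
    while (r / f > threshold) f <- f * 2
    f
  }, numeric(1))
  data.frame(rfu = rfu, factor = factor, remeasure = factor > 1)
}

#' Subtract a blank (background) reading
#'
#' Corrected values are clamped at zero: a reading below its blank yields 0
#' and is flagged via the `"clamped"` attribute rather than reported as a
#' negative RFU.
#'
#' @param rfu Raw RFU reading(s); >= 0.
#' @param blank_rfu Blank/background RFU (matrix control); >= 0.
#' @return Corrected RFU values with a logical `"clamped"` attribute marking
#'   below-blank readings.
#' @export
blank_correct <- function(rfu, blank_rfu) {
  if (any(rfu < 0, na.rm = TRUE) || any(blank_rfu < 0, na.rm = TRUE)) {
    fq_stop("fluoquant_invalid_input", "rfu and blank_rfu must be >= 0")
  }
  corrected <- pmax(rfu - blank_rfu, 0)
  attr(corrected, "clamped") <- (rfu - blank_rfu) < 0
  corrected
}
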