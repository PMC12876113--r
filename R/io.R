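#' Read a long-format plate-reader measurement table
#'
#' Expects comma-separated, UTF-8, header row mandatory, with columns `well`,
#' `sample_id`, `matrix`, `analyte`, `timepoint_h`, `dilution_factor`,
#' `replicate`, `value`, `value_type` (`rfu` or `absorbance`). Malformed rows
#' (non-numeric value, dilution factor < 1, negative RFU) are dropped and
#' collected, with their file line numbers, into the `"problems"` attribute.
#'
#' @param path CSV file path.
#' @return Typed data.frame of the valid rows; attribute `"problems"` holds a
#'   data.frame `line`, `issue` for rejected rows.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) {
    fq_stop("fluoquant_io_error", paste("file not found:", path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", fileEncoding = "UTF-8")
  required <- c("well", "sample_id", "matrix", "analyte", "timepoint_h",
                "dilution_factor", "replicate", "value", "value_type")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    fq_stop("fluoquant_schema_error",
            paste("missing mandatory column(s):",
                  paste(missing_cols, collapse = ", ")))
  }
  if (nrow(df) == 0L) {
    warning("measurement file has a header but no data rows")
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  df$timepoint_h <- num(df$timepoint_h)
  df$dilution_factor <- num(df$dilution_factor)
  df$replicate <- suppressWarnings(as.integer(df$replicate))
  df$value <- num(df$value)

  issues <- character(nrow(df))
  issues[is.na(df$value)] <- "non-numeric value"
  issues[!is.na(df$dilution_factor) & df$dilution_factor < 1] <-
    "dilution_factor < 1"
  issues[is.na(df$dilution_factor)] <- "non-numeric dilution_factor"
  issues[df$value_type == "rfu" & !is.na(df$value) & df$value < 0] <-
    "negative RFU"
  bad <- issues != ""
  problems <- data.frame(line = which(bad) + 1L,  # +1 for the header row
                         issue = issues[bad])
  out <- df[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "problems") <- problems
  out
}

#' @rdname read_measurements
#' @param df Measurement data.frame to write.
#' @export
write_measurements <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a cultivation time-course table
#'
#' Tab-separated with columns `time_h`, `strain`, `od600`, `glucose_g_l`,
#' `rfu_cell`, `rfu_lysate`; `biomass_g_l` and `conc_true_mg_l` are carried
#' through when present, and biomass is otherwise derived from OD via
#' `od_factor`.
#'
#' @param path TSV file path.
#' @param od_factor OD-to-biomass factor used when `biomass_g_l` is absent.
#' @return A `time_course` data.frame.
#' @export
read_timecourse <- function(path, od_factor = 0.334) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("time_h", "strain", "od600", "glucose_g_l", "rfu_cell")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    fq_stop("fluoquant_schema_error",
            paste("missing mandatory column(s):",
                  paste(missing_cols, collapse = ", ")))
  }
  if (is.unsorted(df$time_h, strictly = TRUE)) {
    fq_stop("fluoquant_invalid_input", "time_h must be strictly increasing")
  }
  if (!"biomass_g_l" %in% names(df)) {
    df$biomass_g_l <- od_to_biomass(df$od600, od_factor)
  }
  if (!"rfu_lysate" %in% names(df)) df$rfu_lysate <- NA_real_
  class(df) <- c("time_course", "data.frame")
  df
}

#' @rdname read_timecourse
#' @param tc Time-course data.frame to write.
#' @export
write_timecourse <- function(tc, path) {
  utils::write.table(as.data.frame(tc), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a gel densitometry table
#'
#' Accepts the long per-band layout (`lane_id`, `timepoint_h`,
#' `band_mw_kda`, `band_intensity`) or the pre-summarised layout (`lane_id`,
#' `timepoint_h`, `lane_intensity_pct`).
#'
#' @param path CSV file path.
#' @return Data.frame in whichever of the two layouts the file uses.
#' @export
read_gel_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  long <- all(c("lane_id", "timepoint_h", "band_mw_kda", "band_intensity")
              %in% names(df))
  summarised <- all(c("lane_id", "timepoint_h", "lane_intensity_pct")
                    %in% names(df))
  if (!long && !summarised) {
    fq_stop("fluoquant_schema_error",
            "gel table must be per-band (band_mw_kda, band_intensity) or pre-summarised (lane_intensity_pct)")
  }
  df
}

#' Read a paired HCP concentration table
#'
#' @param path CSV with columns `timepoint_h`, `hcp_mg_l` (and optionally
#'   `assay`).
#' @return Data.frame.
#' @export
read_hcp_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("timepoint_h", "hcp_mg_l") %in% names(df))) {
    fq_stop("fluoquant_schema_error", "hcp table needs timepoint_h, hcp_mg_l")
  }
  df
}

#' Read a run configuration from YAML
#'
#' Merges the file's entries over the built-in defaults (saturation gate
#' 49,000 RFU, OD-to-biomass factor 0.334, default validation thresholds).
#' Standards blocks become [standard_spec()] objects and a `thresholds` block
#' becomes a [validation_thresholds()] object.
#'
#' @param path YAML file path.
#' @return A `run_config` list with elements `standards`, `thresholds`,
#'   `saturation_threshold`, `od_biomass_factor`, `depletion_time`, `seed`,
#'   `paths`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(saturation_threshold = 49000, od_biomass_factor = 0.334,
                   depletion_time = NA_real_, seed = 1L, paths = list())
  out <- utils::modifyList(defaults, cfg[setdiff(names(cfg),
                                                 c("standards", "thresholds"))])
  out$thresholds <- do.call(validation_thresholds,
                            if (is.null(cfg$thresholds)) list() else cfg$thresholds)
  out$standards <- lapply(cfg$standards, function(s) {
    standard_spec(name = s$name,
                  molar_mass = s$molar_mass_g_per_mol,
                  stock_conc = if (is.null(s$stock_conc)) 0 else s$stock_conc,
                  purity = if (is.null(s$purity)) 1 else s$purity,
                  excitation = if (is.null(s$excitation_nm)) NA_real_ else s$excitation_nm,
                  emission = if (is.null(s$emission_nm)) NA_real_ else s$emission_nm,
                  solvent = if (is.null(s$solvent)) NA_character_ else s$solvent,
                  ph = if (is.null(s$ph)) NA_real_ else s$ph)
  })
  structure(out, class = "run_config")
}
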