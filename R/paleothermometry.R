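#' Oxygen-isotope thermometer parameters
#'
#' Parameters of the linear calcite palaeothermometer
#' \deqn{T(\degree C) = a + b\,(\delta^{18}O_{calcite} - \delta^{18}O_{seawater}
#'   - Mg_{calcite})}
#' with the published brachiopod calibration `a = 16.192` degC and
#' `b = -3.468` degC per permil. The ambient-water composition defaults to
#' -1 permil V-SMOW, the conventional value for the studied basin and
#' interval. `mg_term` is a pass-through permil-equivalent offset for the Mg
#' content of the shell calcite; because the thermometer is linear, both
#' constants cancel in any temperature *difference*, which is the analysis
#' quantity (see [aggregate_isotopes()]).
#'
#' @param d18O_seawater Ambient seawater composition, permil V-SMOW.
#' @param mg_term Mg correction, permil-equivalent (default 0; the nominal
#'   0.4 wt% MgCO3 of the shells has minimal effect on temperature).
#' @param intercept,slope Calibration constants, degC and degC/permil.
#' @return A `thermometer_params` list.
#' @export
thermometer_params <- function(d18O_seawater = -1.0, mg_term = 0.0,
                               intercept = 16.192, slope = -3.468) {
  stopifnot(is.finite(d18O_seawater), is.finite(mg_term),
            is.finite(intercept), is.finite(slope))
  structure(list(d18O_seawater = d18O_seawater, mg_term = mg_term,
                 intercept = intercept, slope = slope),
            class = "thermometer_params")
}

#' Calcite temperature from d18O
#'
#' Applies the linear thermometer in [thermometer_params()]. A decrease of
#' 1 permil in calcite d18O corresponds to +3.468 degC of warming under the
#' default calibration.
#'
#' @param d18O_calcite Calcite composition, permil V-PDB. Vectorised.
#' @param params A [thermometer_params()] object.
#' @return Temperature in degC.
#' @examples
#' calcite_temperature(-1)                       # 16.192 at default seawater
#' calcite_temperature(-2) - calcite_temperature(-1)  # +3.468 per -1 permil
#' @export
calcite_temperature <- function(d18O_calcite, params = thermometer_params()) {
  if (any(!is.finite(d18O_calcite))) stop("d18O must be finite", call. = FALSE)
  params$intercept +
    params$slope * (d18O_calcite - params$d18O_seawater - params$mg_term)
}

#' Screen isotope measurements for diagenetic alteration
#'
#' Shell calcite with elevated Mn/Ca or Fe/Ca is interpreted as
#' diagenetically altered and excluded from palaeotemperature estimation.
#' A measurement is rejected iff `mn_ca > mn_max` or `fe_ca > fe_max`
#' ("exceeding" is strict: values at the threshold pass). Measurements
#' without element ratios pass by default (`missing_pass`), covering data
#' screened upstream.
#'
#' @param measurements Isotope data frame (see [read_isotopes()]).
#' @param mn_max Mn/Ca threshold, mmol/mol (default 0.1).
#' @param fe_max Fe/Ca threshold, mmol/mol (default 1.0).
#' @param missing_pass Accept rows with absent ratios (default `TRUE`).
#' @return Measurements with the `accepted` flag set.
#' @export
screen_measurements <- function(measurements, mn_max = 0.1, fe_max = 1.0,
                                missing_pass = TRUE) {
  mn <- measurements$mn_ca
  fe <- measurements$fe_ca
  if (any(mn < 0, na.rm = TRUE) || any(fe < 0, na.rm = TRUE))
    stop("negative element/Ca ratio", call. = FALSE)
  bad_mn <- !is.na(mn) & mn > mn_max
  bad_fe <- !is.na(fe) & fe > fe_max
  missing <- is.na(mn) & is.na(fe)
  measurements$accepted <- !(bad_mn | bad_fe) & (missing_pass | !missing)
  measurements
}

#' Aggregate screened isotope measurements into a per-sample series
#'
#' Pools accepted measurements per sampled level (rhynchonellid and oyster
#' substrates together, both being essentially free of vital effects),
#' reporting the mean and double standard error (`2*sd/sqrt(n)`, `NA` when
#' `n = 1`; sd uses the n-1 denominator) for d18O and d13C, the temperature
#' implied by the sample-mean d18O, and the temperature change `delta_T`
#' relative to the lowermost sample of the profile. Levels without any
#' accepted measurement are omitted.
#'
#' @param measurements Screened isotope data frame.
#' @param levels Level table (`sample_id,strat_height`), e.g. from
#'   [sample_levels()] or the simulator.
#' @param params Thermometer parameters.
#' @return An `isotope_series` data frame: `sample_id,strat_height,
#'   d18O_mean,d18O_2se,d13C_mean,d13C_2se,n,temperature,delta_T`, ordered by
#'   `strat_height`.
#' @export
aggregate_isotopes <- function(measurements, levels,
                               params = thermometer_params()) {
  acc <- measurements[measurements$accepted, , drop = FALSE]
  lv <- levels[order(levels$strat_height), , drop = FALSE]
  rows <- lapply(seq_len(nrow(lv)), function(i) {
    sub <- acc[acc$sample_id == lv$sample_id[i], , drop = FALSE]
    n <- nrow(sub)
    if (n == 0) return(NULL)
    two_se <- function(x) if (n > 1) 2 * stats::sd(x) / sqrt(n) else NA_real_
    data.frame(sample_id = lv$sample_id[i], strat_height = lv$strat_height[i],
               d18O_mean = mean(sub$d18O), d18O_2se = two_se(sub$d18O),
               d13C_mean = mean(sub$d13C), d13C_2se = two_se(sub$d13C),
               n = n, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no accepted measurements in any sample", call. = FALSE)
  out <- do.call(rbind, rows)
  out$temperature <- calcite_temperature(out$d18O_mean, params)
  out$delta_T <- out$temperature - out$temperature[1]
  rownames(out) <- NULL
  structure(out, class = c("isotope_series", "data.frame"))
}

#' @export
print.isotope_series <- function(x, ...) {
  cat(sprintf("<isotope_series: %d levels, delta_T range [%.2f, %.2f] degC>\n",
              nrow(x), min(x$delta_T), max(x$delta_T)))
  print.data.frame(x, ...)
  invisible(x)
}
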