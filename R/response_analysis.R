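#' Replicated response measurement
#'
#' Container for replicate dF/F0 readouts of one sensor/analyte/concentration
#' combination; mean is the arithmetic replicate mean, sd the sample (n-1)
#' standard deviation (0 for a single replicate).
#'
#' @param sensor sensor name or sequence string.
#' @param analyte analyte name.
#' @param conc_uM concentration in uM.
#' @param replicates numeric vector of dF/F0 values (length >= 1).
#' @return object of class `response_measurement`.
#' @export
response_measurement <- function(sensor, analyte, conc_uM, replicates) {
  if (length(replicates) < 1L) {
    stop(sensevo_error("empty_replicates", "at least one replicate required"))
  }
  stopifnot(all(is.finite(replicates)))
  structure(
    list(sensor = sensor, analyte = analyte, conc_uM = conc_uM,
         replicates = replicates,
         mean = mean(replicates),
         sd = if (length(replicates) > 1L) stats::sd(replicates) else 0),
    class = "response_measurement")
}

#' Intensity at a wavelength (nearest grid sample)
#'
#' Reads a spectrum at the requested wavelength using the nearest-sample
#' convention (the assay reads a fixed wavelength; no peak fitting).
#'
#' @param spectrum a `fluor_spectrum`.
#' @param wavelength_nm query wavelength; must lie within the grid range.
#' @return intensity in arbitrary units.
#' @export
intensity_at <- function(spectrum, wavelength_nm) {
  wl <- spectrum$wavelengths
  if (wavelength_nm < min(wl) || wavelength_nm > max(wl)) {
    stop(sensevo_error("wavelength_out_of_range",
      sprintf("wavelength %g nm outside grid [%g, %g]",
              wavelength_nm, min(wl), max(wl))))
  }
  spectrum$intensities[which.min(abs(wl - wavelength_nm))]
}

#' Relative fluorescence change dF/F0
#'
#' `(F - F0) / F0`, where `F0` is the baseline (DI-water control) intensity
#' and `F` the intensity after analyte addition, both at the readout
#' wavelength.
#'
#' @param f intensity after analyte addition.
#' @param f0 baseline intensity; must be > 0.
#' @return dimensionless dF/F0.
#' @export
delta_f_over_f0 <- function(f, f0) {
  if (any(f0 <= 0)) {
    stop(sensevo_error("nonpositive_baseline",
      "baseline intensity F0 must be positive"))
  }
  (f - f0) / f0
}

#' Serotonin/dopamine selectivity ratio
#'
#' `ratio = dFF0_5HT / dFF0_DA`; values above 1 mean the sensor responds
#' more to serotonin than dopamine. A zero dopamine response leaves the
#' ratio undefined and raises an error rather than returning infinity.
#'
#' @param dff0_5ht dF/F0 for serotonin.
#' @param dff0_da dF/F0 for dopamine (nonzero).
#' @param sensor optional sensor name carried in the result.
#' @return object of class `selectivity_result` with fields `sensor`,
#'   `ratio_5HT_DA`, `dFF0_5HT`, `dFF0_DA`.
#' @export
selectivity_ratio <- function(dff0_5ht, dff0_da, sensor = "") {
  if (dff0_da == 0) {
    stop(sensevo_error("undefined_ratio",
      "dopamine response is zero; selectivity ratio undefined"))
  }
  structure(
    list(sensor = sensor, ratio_5HT_DA = dff0_5ht / dff0_da,
         dFF0_5HT = dff0_5ht, dFF0_DA = dff0_da),
    class = "selectivity_result")
}

#' Fold improvement between two responses
#'
#' Plain ratio `new / old`, used for round-over-round comparisons (e.g.
#' 2.366 / 0.949 = 2.5-fold sensitivity gain).
#'
#' @param new,old dimensionless responses or ratios; `old` nonzero.
#' @return `new / old`.
#' @export
fold_change <- function(new, old) {
  if (old == 0) {
    stop(sensevo_error("undefined_ratio", "reference value is zero"))
  }
  new / old
}

#' Replicate summary
#'
#' @param replicates numeric vector of dF/F0 values (length >= 1).
#' @return named list `mean` (arithmetic mean) and `sd` (sample n-1 sd; 0
#'   for a single replicate).
#' @export
summarize_replicates <- function(replicates) {
  if (length(replicates) < 1L) {
    stop(sensevo_error("empty_replicates", "at least one replicate required"))
  }
  list(mean = mean(replicates),
       sd = if (length(replicates) > 1L) stats::sd(replicates) else 0)
}

#' Protocol concentration for a panel analyte
#'
#' 100 uM for every analyte except uric acid (UA), measured at 10 uM due to
#' its low stock solubility.
#'
#' @param analyte analyte name.
#' @return concentration in uM.
#' @export
protocol_concentration <- function(analyte) {
  if (analyte == "UA") 10 else 100
}

#' Multi-analyte selectivity panel
#'
#' One replicated measurement per analyte at its protocol concentration
#' (100 uM; 10 uM for UA), plus the DI-water baseline row (dF/F0 = 0 by
#' construction). Each (sensor, analyte) measurement is independently
#' seeded, so the panel is identical regardless of analyte ordering.
#'
#' @param model a calibrated `landscape`.
#' @param noise a `noise_model`.
#' @param sensor a `sensor_seq`.
#' @param analytes analytes to test (subset of the landscape panel).
#' @return data.frame: sensor, analyte, conc_uM, rep1..repN, mean_dFF0,
#'   sd_dFF0; first row is the DI-water baseline.
#' @export
analyte_panel <- function(model, noise, sensor,
                          analytes = model$analytes) {
  for (an in analytes) check_analyte(model, an)
  rows <- lapply(analytes, function(an) {
    m <- simulate_measurement(model, noise, sensor, an,
                              protocol_concentration(an))
    measurement_row(m)
  })
  base <- simulate_measurement(model, noise, sensor, analytes[[1]], 0)
  base$analyte <- "DI-water"
  out <- do.call(rbind, c(list(measurement_row(base)), rows))
  rownames(out) <- NULL
  out
}

measurement_row <- function(m) {
  reps <- as.list(m$replicates)
  names(reps) <- paste0("rep", seq_along(reps))
  cbind(data.frame(sensor = m$sensor, analyte = m$analyte,
                   conc_uM = m$conc_uM, stringsAsFactors = FALSE),
        as.data.frame(reps),
        data.frame(mean_dFF0 = m$mean, sd_dFF0 = m$sd))
}

#' Measurement table for a set of measurements
#'
#' @param measurements list of `response_measurement` objects.
#' @return data.frame, one row per measurement (see [analyte_panel()] for
#'   columns).
#' @export
measurement_table <- function(measurements) {
  out <- do.call(rbind, lapply(measurements, measurement_row))
  rownames(out) <- NULL
  out
}
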