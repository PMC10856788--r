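PROTOCOL_CONCENTRATIONS <- c(0.1, 1, 5, 10, 30, 70, 100)

#' Hill binding model
#'
#' Saturating dose-response: `dFF0_max * conc^n / (kd^n + conc^n)` (standard
#' form, default). The literal variant `dFF0_max * conc^n / (kd + conc^n)`
#' — K_d not raised to the cooperativity — is available behind
#' `form = "literal"`; the two coincide at `n = 1`, the regime of all fits
#' reported here, and the standard form is dimensionally consistent.
#'
#' @param conc concentration in uM (>= 0), vectorised.
#' @param kd dissociation constant in uM (> 0).
#' @param n Hill cooperativity (> 0).
#' @param dff0_max maximal response.
#' @param form `"standard"` (K_d^n) or `"literal"` (bare K_d).
#' @return dF/F0 at each concentration.
#' @export
hill_model <- function(conc, kd, n, dff0_max, form = c("standard", "literal")) {
  form <- match.arg(form)
  if (any(conc < 0)) stop(sensevo_error("invalid_concentration",
                                        "concentrations must be >= 0"))
  if (kd <= 0) stop(sensevo_error("invalid_parameter", "kd must be > 0"))
  if (n <= 0) stop(sensevo_error("invalid_parameter", "n must be > 0"))
  denom <- if (form == "standard") kd^n + conc^n else kd + conc^n
  dff0_max * conc^n / denom
}

#' Dose-response curve container
#'
#' @param concentrations strictly positive, distinct uM values (protocol
#'   default 0.1, 1, 5, 10, 30, 70, 100); pairs are stored sorted by
#'   concentration, so fits are invariant to input ordering.
#' @param responses dF/F0 (possibly normalized) per concentration.
#' @param sensor sensor name.
#' @return object of class `dose_response_curve`.
#' @export
dose_response_curve <- function(concentrations, responses, sensor = "") {
  stopifnot(length(concentrations) == length(responses))
  ord <- order(concentrations)
  concentrations <- concentrations[ord]
  responses <- responses[ord]
  if (any(concentrations <= 0) || any(diff(concentrations) <= 0)) {
    stop(sensevo_error("invalid_concentration",
      "concentrations must be strictly positive and distinct"))
  }
  structure(list(concentrations = concentrations, responses = responses,
                 sensor = sensor),
            class = "dose_response_curve")
}

#' Normalize a dose-response curve to its maximum
#'
#' Divides all responses by the maximum observed response, so values lie in
#' [0, 1] when responses are nonnegative. Normalization rescales only
#' `dFF0_max` in a subsequent Hill fit; K_d and n are unchanged.
#'
#' @param curve a `dose_response_curve` (max response must be > 0).
#' @return normalized `dose_response_curve`.
#' @export
normalize_curve <- function(curve) {
  stopifnot(inherits(curve, "dose_response_curve"))
  mx <- max(curve$responses)
  if (mx <= 0) {
    stop(sensevo_error("degenerate_curve",
      "maximum response must be positive to normalize"))
  }
  dose_response_curve(curve$concentrations, curve$responses / mx, curve$sensor)
}

#' Fit the Hill equation by bounded nonlinear least squares
#'
#' Levenberg-Marquardt least squares (via `minpack.lm::nlsLM`) of
#' [hill_model()] to a dose-response curve, with positivity bounds
#' K_d in (0, 1e4] uM, n in (0, 10], dFF0_max in (0, 1e3]. Initialisation:
#' K_d at the concentration whose response is nearest half-maximum, n = 1,
#' dFF0_max = max response. Non-convergence is reported through the
#' `converged` flag and message, never silently.
#'
#' @param curve a `dose_response_curve` with >= 3 distinct concentrations.
#' @param init optional named list overriding initial values (`kd`, `n`,
#'   `dff0_max`).
#' @param lower,upper optional named numeric bounds (same names).
#' @param form Hill denominator variant, see [hill_model()].
#' @return object of class `hill_fit`: `kd` (uM), `n`, `dff0_max`,
#'   `residual_sse`, `converged`, `message`, `fitted`.
#' @export
fit_hill <- function(curve, init = NULL, lower = NULL, upper = NULL,
                     form = c("standard", "literal")) {
  form <- match.arg(form)
  stopifnot(inherits(curve, "dose_response_curve"))
  conc <- curve$concentrations
  y <- curve$responses
  if (length(unique(conc)) < 3L) {
    stop(sensevo_error("insufficient_data",
      "at least 3 distinct concentrations required"))
  }
  ymax <- max(y)
  half_idx <- which.min(abs(y - ymax / 2))
  start <- list(kd = conc[half_idx], n = 1, dff0_max = ymax)
  if (!is.null(init)) start[names(init)] <- init
  lo <- c(kd = 1e-6, n = 1e-3, dff0_max = 1e-9)
  hi <- c(kd = 1e4, n = 10, dff0_max = 1e3)
  if (!is.null(lower)) lo[names(lower)] <- unlist(lower)
  if (!is.null(upper)) hi[names(upper)] <- unlist(upper)
  start$kd <- min(max(start$kd, lo[["kd"]]), hi[["kd"]])
  start$dff0_max <- min(max(start$dff0_max, lo[["dff0_max"]]), hi[["dff0_max"]])
  dat <- data.frame(conc = conc, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ hill_model(conc, kd, n, dff0_max, form = form),
      data = dat, start = start,
      lower = lo[c("kd", "n", "dff0_max")],
      upper = hi[c("kd", "n", "dff0_max")],
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                           ptol = 1e-12)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(
      list(kd = NA_real_, n = NA_real_, dff0_max = NA_real_,
           residual_sse = NA_real_, converged = FALSE,
           message = conditionMessage(fit), fitted = rep(NA_real_, length(y)),
           sensor = curve$sensor),
      class = "hill_fit"))
  }
  cf <- stats::coef(fit)
  conv <- fit$convInfo$isConv %||% TRUE
  structure(
    list(kd = unname(cf[["kd"]]), n = unname(cf[["n"]]),
         dff0_max = unname(cf[["dff0_max"]]),
         residual_sse = sum(stats::residuals(fit)^2),
         converged = isTRUE(conv),
         message = fit$convInfo$stopMessage %||% "converged",
         fitted = as.numeric(stats::fitted(fit)),
         sensor = curve$sensor),
    class = "hill_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> %s: Kd = %.4g uM, n = %.3g, dFF0_max = %.4g (SSE %.3g, %s)\n",
              if (nzchar(x$sensor)) x$sensor else "(unnamed)",
              x$kd, x$n, x$dff0_max, x$residual_sse,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Fit report row for one or more Hill fits
#'
#' @param fits list of `hill_fit` objects.
#' @return data.frame: sensor, Kd_uM, n, dFF0_max, sse, converged.
#' @export
hill_fit_table <- function(fits) {
  do.call(rbind, lapply(fits, function(f) {
    data.frame(sensor = f$sensor, Kd_uM = f$kd, n = f$n,
               dFF0_max = f$dff0_max, sse = f$residual_sse,
               converged = f$converged, stringsAsFactors = FALSE)
  }))
}

#' Measure and fit a full dose-response curve for a sensor
#'
#' Simulates replicated measurements at the seven protocol concentrations,
#' averages replicates, optionally normalizes, and fits the Hill model.
#'
#' @param model a calibrated `landscape`.
#' @param noise a `noise_model`.
#' @param sensor a `sensor_seq`.
#' @param analyte analyte (default "5HT").
#' @param concentrations uM grid (protocol default).
#' @param normalize divide by max response before fitting (default TRUE,
#'   matching how curves are reported).
#' @return list with `curve` (`dose_response_curve`), `fit` (`hill_fit`),
#'   and `measurements` (data.frame).
#' @export
measure_dose_response <- function(model, noise, sensor, analyte = "5HT",
                                  concentrations = PROTOCOL_CONCENTRATIONS,
                                  normalize = TRUE) {
  ms <- lapply(concentrations, function(cc)
    simulate_measurement(model, noise, sensor, analyte, cc))
  means <- vapply(ms, function(m) m$mean, numeric(1))
  curve <- dose_response_curve(concentrations, means,
                               sensor = if (nzchar(sensor$name)) sensor$name else sensor$bases)
  if (normalize) curve <- normalize_curve(curve)
  list(curve = curve, fit = fit_hill(curve), measurements = measurement_table(ms))
}
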