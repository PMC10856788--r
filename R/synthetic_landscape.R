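ANALYTES <- c("5HT", "DA", "Ach", "GABA", "Glu", "UA", "AA")

# deterministic positive integer from arbitrary strings (rolling polynomial
# hash mod 2^31-1); used to derive independent sub-seeds per (sequence,
# analyte, ...) so results never depend on evaluation order
hash_seed <- function(...) {
  s <- paste(unlist(list(...)), collapse = "\r")
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

#' Default configuration for the synthetic response landscape
#'
#' The landscape is an additive position-base model over the variable region
#' with optional sparse pairwise epistasis, one weight table per analyte,
#' calibrated by per-analyte offsets so that anchor responses are matched
#' exactly. The defaults encode the study conditions: serotonin (5HT)
#' response of the original sensor 0.949, serotonin/dopamine selectivity
#' 0.508 (hence dopamine response 0.949/0.508), small responses for the
#' off-target panel analytes, a larger-than-dopamine ascorbic-acid response,
#' and binding constants near 10 uM with the original sensor's 5HT K_d at
#' 11.6 uM.
#'
#' @param analytes analyte panel (default the seven-analyte study panel).
#' @param weight_sd standard deviation of the per-position-base response
#'   weights (dimensionless dF/F0 units; default 0.15).
#' @param epistasis_density expected number of pairwise epistatic terms per
#'   position pair (default 0: purely additive).
#' @param epistasis_sd standard deviation of epistatic effects (default 0.05).
#' @param hill_n Hill cooperativity used for concentration dependence
#'   (default 1).
#' @param kd_log_sd log-scale spread of per-(sequence, analyte) K_d values
#'   around 10 uM (default 0.25).
#' @param reference_bases the sequence whose responses the anchors pin
#'   (default the original 30-mer sensor).
#' @param flank_len fixed poly-C flank length of the sensor design
#'   (default 6).
#' @param anchors list of absolute anchors `list(bases=, analyte=, target=,
#'   kd=)` (`kd` optional, uM).
#' @param ratio_anchors list of ratio anchors `list(bases=, num=, den=,
#'   ratio=, kd=)`: pins response(den) = response(num)/ratio.
#' @param default_response named nominal responses of the reference sequence
#'   for analytes without anchors.
#' @return a config list consumed by [build_landscape()].
#' @export
landscape_config <- function(analytes = ANALYTES,
                             weight_sd = 0.15,
                             epistasis_density = 0,
                             epistasis_sd = 0.05,
                             hill_n = 1,
                             kd_log_sd = 0.25,
                             reference_bases = "CCCCCCAGCCCTTCACCACCAACTCCCCCC",
                             flank_len = 6L,
                             anchors = list(
                               list(bases = reference_bases, analyte = "5HT",
                                    target = 0.949, kd = 11.6)),
                             ratio_anchors = list(
                               list(bases = reference_bases, num = "5HT",
                                    den = "DA", ratio = 0.508, kd = 11.6)),
                             default_response = c(Ach = 0.05, GABA = 0.04,
                                                  Glu = 0.06, UA = 0.03,
                                                  AA = 2.0)) {
  list(analytes = analytes, weight_sd = weight_sd,
       epistasis_density = epistasis_density, epistasis_sd = epistasis_sd,
       hill_n = hill_n, kd_log_sd = kd_log_sd,
       reference_bases = reference_bases, flank_len = as.integer(flank_len),
       anchors = anchors, ratio_anchors = ratio_anchors,
       default_response = default_response)
}

raw_response_chr <- function(model, bases_chr, analyte) {
  fl <- model$flank_len
  L <- model$var_len
  n <- length(bases_chr)
  var_str <- substr(bases_chr, fl + 1L, fl + L)
  ch <- matrix(unlist(strsplit(var_str, "", fixed = TRUE)),
               nrow = n, ncol = L, byrow = TRUE)
  bidx <- matrix(match(ch, DNA_BASES), nrow = n)
  W <- model$weights[[analyte]]
  r <- numeric(n)
  for (j in seq_len(L)) r <- r + W[cbind(j, bidx[, j])]
  ep <- model$epistasis[[analyte]]
  if (!is.null(ep) && nrow(ep) > 0L) {
    for (t in seq_len(nrow(ep))) {
      hit <- bidx[, ep$i[t]] == ep$bi[t] & bidx[, ep$j[t]] == ep$bj[t]
      r[hit] <- r[hit] + ep$effect[t]
    }
  }
  r
}

check_analyte <- function(model, analyte) {
  if (!analyte %in% model$analytes) {
    stop(sensevo_error("unknown_analyte",
      sprintf("analyte '%s' not in landscape panel (%s)",
              analyte, paste(model$analytes, collapse = ", "))))
  }
}

resolve_anchors <- function(config) {
  anchors <- config$anchors
  for (ra in config$ratio_anchors) {
    num_target <- NULL
    for (a in anchors) {
      if (a$bases == ra$bases && a$analyte == ra$num) num_target <- a$target
    }
    if (is.null(num_target)) {
      stop(sensevo_error("infeasible_anchor",
        sprintf("ratio anchor %s/%s has no absolute anchor for its numerator",
                ra$num, ra$den)))
    }
    if (!is.finite(ra$ratio) || ra$ratio == 0) {
      stop(sensevo_error("infeasible_anchor",
        sprintf("ratio anchor %s/%s has zero/non-finite ratio: denominator response undefined",
                ra$num, ra$den)))
    }
    anchors <- c(anchors, list(list(bases = ra$bases, analyte = ra$den,
                                    target = num_target / ra$ratio,
                                    kd = ra$kd)))
  }
  # contradictory anchors: same (sequence, analyte), different targets
  keys <- vapply(anchors, function(a) paste(a$bases, a$analyte), character(1))
  for (k in unique(keys)) {
    tg <- vapply(anchors[keys == k], function(a) a$target, numeric(1))
    if (max(tg) - min(tg) > 1e-12) {
      stop(sensevo_error("infeasible_anchor",
        sprintf("contradictory anchors for (%s): targets %s", k,
                paste(format(tg), collapse = " vs "))))
    }
  }
  anchors
}

#' Build a calibrated synthetic sequence-to-response landscape
#'
#' Draws per-analyte additive position-base weight tables (and, when
#' `epistasis_density > 0`, sparse pairwise epistatic terms) under the given
#' seed, then calibrates per-analyte offsets so every anchor constraint is
#' satisfied exactly. The result is the ground truth the simulated assay
#' reads out: `true_response(model, seq, analyte)` is the plateau dF/F0 the
#' sensor would show at saturating analyte.
#'
#' @param seed integer RNG seed; the landscape is a pure function of
#'   `(seed, config)`.
#' @param config see [landscape_config()].
#' @return an object of class `landscape` with weight tables, epistasis
#'   terms, offsets, anchor K_d overrides, and spectrum/readout settings.
#' @export
build_landscape <- function(seed, config = landscape_config()) {
  ref <- sensor_seq(config$reference_bases,
                    name = "reference",
                    flank_len = config$flank_len %||% 6L)
  L <- nchar(ref$var_region)
  anchors <- resolve_anchors(config)
  model <- withr::with_seed(seed, {
    weights <- list()
    epistasis <- list()
    for (an in config$analytes) {
      W <- matrix(stats::rnorm(L * 4L, sd = config$weight_sd), nrow = L,
                  dimnames = list(NULL, DNA_BASES))
      weights[[an]] <- W
      n_ep <- stats::rbinom(1L, choose(L, 2L),
                            min(1, config$epistasis_density))
      if (n_ep > 0L) {
        prs <- utils::combn(L, 2L)
        sel <- sample(ncol(prs), n_ep)
        epistasis[[an]] <- data.frame(
          i = prs[1L, sel], j = prs[2L, sel],
          bi = sample(4L, n_ep, replace = TRUE),
          bj = sample(4L, n_ep, replace = TRUE),
          effect = stats::rnorm(n_ep, sd = config$epistasis_sd))
      } else {
        epistasis[[an]] <- data.frame(i = integer(), j = integer(),
                                      bi = integer(), bj = integer(),
                                      effect = numeric())
      }
    }
    list(weights = weights, epistasis = epistasis)
  })
  model <- structure(
    list(seed = seed, config = config, analytes = config$analytes,
         flank_len = ref$flank_len, var_len = L,
         reference = ref,
         weights = model$weights, epistasis = model$epistasis,
         offsets = stats::setNames(numeric(length(config$analytes)),
                                   config$analytes),
         anchors = anchors,
         readout_wavelength = 1202,
         # narrow emission peaks spaced so off-readout tails at 1202 nm are
         # < 1e-10 of the readout peak (keeps dF/F0 exact to true response)
         peaks = data.frame(center = c(1000, 1120, 1202, 1290),
                            width = c(12, 12, 12, 12),
                            amplitude = c(450, 700, 1000, 550))),
    class = "landscape")
  calibrate_landscape(model)
}

#' Calibrate (or re-calibrate) a landscape against its anchors
#'
#' Solves per-analyte additive offsets so anchored responses are matched
#' exactly; analytes without anchors are pinned to the configured nominal
#' response of the reference sequence. Idempotent: calibrating a calibrated
#' model changes nothing.
#'
#' @param model a `landscape`.
#' @return the calibrated `landscape`.
#' @export
calibrate_landscape <- function(model) {
  offsets <- stats::setNames(numeric(length(model$analytes)), model$analytes)
  anchored <- character(0)
  for (a in model$anchors) {
    check_analyte(model, a$analyte)
    raw <- raw_response_chr(model, a$bases, a$analyte)
    if (a$analyte %in% anchored) {
      implied <- raw + offsets[[a$analyte]]
      if (abs(implied - a$target) > 1e-9) {
        stop(sensevo_error("infeasible_anchor",
          sprintf("anchor (%s, %s) unsatisfiable with offset-only calibration",
                  a$bases, a$analyte)))
      }
    } else {
      offsets[[a$analyte]] <- a$target - raw
      anchored <- c(anchored, a$analyte)
    }
  }
  for (an in setdiff(model$analytes, anchored)) {
    nominal <- model$config$default_response[[an]]
    if (is.null(nominal)) nominal <- 0.05
    offsets[[an]] <- nominal - raw_response_chr(model, model$reference$bases, an)
  }
  model$offsets <- offsets
  model
}

#' Ground-truth plateau response of a sensor to an analyte
#'
#' Additive position-base weight sum plus epistasis plus the calibrated
#' per-analyte offset, clipped below at -1 (fluorescence cannot drop below
#' zero intensity). Deterministic given `(seed, sequence, analyte)`.
#'
#' @param model a calibrated `landscape`.
#' @param seq a `sensor_seq` (or plain sequence string) matching the
#'   landscape layout.
#' @param analyte one of the landscape's analytes.
#' @return dimensionless dF/F0 at saturating analyte concentration.
#' @export
true_response <- function(model, seq, analyte) {
  bases <- if (inherits(seq, "sensor_seq")) seq$bases else seq
  true_response_many(model, bases, analyte)
}

#' Vectorised ground-truth response over many sequences
#'
#' @param model a calibrated `landscape`.
#' @param bases_chr character vector of full sequence strings.
#' @param analyte one of the landscape's analytes.
#' @return numeric vector of plateau dF/F0 values.
#' @export
true_response_many <- function(model, bases_chr, analyte) {
  check_analyte(model, analyte)
  pmax(raw_response_chr(model, bases_chr, analyte) + model$offsets[[analyte]], -1)
}

#' Per-(sequence, analyte) dissociation constant of the synthetic assay
#'
#' Anchored (sequence, analyte) pairs use their anchor K_d; all others draw
#' a deterministic K_d near 10 uM (log-normal spread `kd_log_sd`) from a
#' sub-seed hashed out of (landscape seed, sequence, analyte).
#'
#' @inheritParams true_response
#' @return K_d in uM.
#' @export
landscape_kd <- function(model, seq, analyte) {
  check_analyte(model, analyte)
  bases <- if (inherits(seq, "sensor_seq")) seq$bases else seq
  for (a in model$anchors) {
    if (!is.null(a$kd) && a$bases == bases && a$analyte == analyte) {
      return(a$kd)
    }
  }
  z <- withr::with_seed(hash_seed(model$seed, "kd", bases, analyte),
                        stats::rnorm(1))
  10 * exp(model$config$kd_log_sd * z)
}

hill_fraction <- function(conc, kd, n) {
  ifelse(conc == 0, 0, conc^n / (kd^n + conc^n))
}

#' Simulate a near-infrared fluorescence emission spectrum
#'
#' The baseline spectrum is a fixed sum of Gaussian emission peaks (one per
#' nanotube chirality stand-in), with the readout peak centred at 1202 nm.
#' Analyte at concentration `conc` scales the readout peak by
#' `1 + true_response * hill_fraction(conc)`; concentration 0 returns the
#' baseline exactly.
#'
#' @inheritParams true_response
#' @param conc analyte concentration in uM (>= 0).
#' @param wavelengths wavelength grid in nm (default 950-1350, 1-nm step).
#' @return object of class `fluor_spectrum`: `wavelengths`, `intensities`,
#'   `label` (sensor name, analyte, concentration).
#' @export
simulate_spectrum <- function(model, seq, analyte, conc,
                              wavelengths = seq(950, 1350, by = 1)) {
  if (conc < 0) {
    stop(sensevo_error("invalid_concentration",
      sprintf("concentration must be >= 0, got %g", conc)))
  }
  s <- if (inherits(seq, "sensor_seq")) seq else sensor_seq(seq, flank_len = model$flank_len)
  pk <- model$peaks
  scale <- rep(1, nrow(pk))
  if (conc > 0) {
    r <- true_response(model, s, analyte)
    kd <- landscape_kd(model, s, analyte)
    readout <- which(pk$center == model$readout_wavelength)
    scale[readout] <- 1 + r * hill_fraction(conc, kd, model$config$hill_n)
  } else {
    analyte <- if (missing(analyte)) "baseline" else analyte
  }
  intens <- numeric(length(wavelengths))
  for (i in seq_len(nrow(pk))) {
    intens <- intens + scale[i] * pk$amplitude[i] *
      exp(-((wavelengths - pk$center[i])^2) / (2 * pk$width[i]^2))
  }
  structure(
    list(wavelengths = wavelengths, intensities = pmax(intens, 0),
         label = list(sensor = s$name, analyte = analyte, conc_uM = conc)),
    class = "fluor_spectrum")
}

#' Measurement noise model
#'
#' Multiplicative Gaussian noise on each replicate: replicate = noiseless *
#' (1 + eps), eps ~ Normal(0, relative_sd). Triplicates by default.
#'
#' @param relative_sd relative standard deviation (default 0.05).
#' @param replicate_count replicates per measurement (default 3).
#' @param seed base seed; per-measurement sub-seeds are hashed from it.
#' @return object of class `noise_model`.
#' @export
noise_model <- function(relative_sd = 0.05, replicate_count = 3L, seed = 1L) {
  stopifnot(relative_sd >= 0, replicate_count >= 1L)
  structure(list(relative_sd = relative_sd,
                 replicate_count = as.integer(replicate_count),
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Simulate a replicated dF/F0 measurement
#'
#' Reads the simulated analyte and baseline spectra at the readout
#' wavelength, forms dF/F0 = (F - F0)/F0, and applies seeded multiplicative
#' noise per replicate. The sub-seed is a hash of (noise seed, sequence,
#' analyte, concentration), so results are independent of call order.
#'
#' @inheritParams simulate_spectrum
#' @param noise a `noise_model`.
#' @return a `response_measurement` (see [response_measurement()]).
#' @export
simulate_measurement <- function(model, noise, seq, analyte, conc) {
  s <- if (inherits(seq, "sensor_seq")) seq else sensor_seq(seq, flank_len = model$flank_len)
  sp_c <- simulate_spectrum(model, s, analyte, conc)
  sp_0 <- simulate_spectrum(model, s, analyte, 0)
  f <- intensity_at(sp_c, model$readout_wavelength)
  f0 <- intensity_at(sp_0, model$readout_wavelength)
  noiseless <- delta_f_over_f0(f, f0)
  eps <- withr::with_seed(
    hash_seed(noise$seed, s$bases, analyte, format(conc)),
    stats::rnorm(noise$replicate_count, sd = noise$relative_sd))
  reps <- noiseless * (1 + eps)
  response_measurement(sensor = if (nzchar(s$name)) s$name else s$bases,
                       analyte = analyte, conc_uM = conc, replicates = reps)
}
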