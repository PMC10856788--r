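#!/usr/bin/env Rscript
# Hill dose-response characterisation: simulate the seven-concentration
# serotonin titration for the original sensor and the sensitivity campaign's
# final best, normalize, and fit K_d and cooperativity.

suppressPackageStartupMessages(library(sensevo))

LANDSCAPE_SEED <- 42L
RUN_SEED <- 7L

dir.create("results", showWarnings = FALSE)

model <- build_landscape(LANDSCAPE_SEED)
noise <- noise_model(relative_sd = 0.05, replicate_count = 3, seed = RUN_SEED)
original <- validate_sequence("CCCCCCAGCCCTTCACCACCAACTCCCCCC", "original")

trace_file <- "results/evolution_sensitivity_trace.csv"
sensors <- list(original)
if (file.exists(trace_file)) {
  tr <- utils::read.csv(trace_file, stringsAsFactors = FALSE)
  best <- tr[nrow(tr), ]
  sensors <- c(sensors, list(sensor_seq(best$best_seq, name = best$best_name)))
} else {
  cat("note: run 03_evolve_sensitivity.R first to also fit the evolved sensor\n")
}

fits <- list()
for (s in sensors) {
  res <- measure_dose_response(model, noise, s)
  fits <- c(fits, list(res$fit))
  cat(sprintf("%s: K_d = %.2f uM, n = %.2f, SSE = %.2e (%s)\n",
              res$curve$sensor, res$fit$kd, res$fit$n, res$fit$residual_sse,
              if (res$fit$converged) "converged" else "NOT converged"))
  utils::write.csv(
    data.frame(conc_uM = res$curve$concentrations,
               norm_dFF0 = res$curve$responses,
               fitted = res$fit$fitted),
    sprintf("results/dose_response_%s.csv", gsub("[^A-Za-z0-9]", "_", res$curve$sensor)),
    row.names = FALSE)
}

utils::write.csv(hill_fit_table(fits), "results/hill_fits.csv",
                 row.names = FALSE)
write_provenance("results/dose_response_provenance.json",
                 step = "04_dose_response", landscape_seed = LANDSCAPE_SEED,
                 run_seed = RUN_SEED,
                 concentrations = c(0.1, 1, 5, 10, 30, 70, 100))
cat("written: results/hill_fits.csv (+ per-sensor curves)\n")
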