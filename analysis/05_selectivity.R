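#!/usr/bin/env Rscript
# Selectivity campaign: two rounds of directed evolution ranked by the
# serotonin/dopamine ratio of triplicate-mean responses, then the full
# seven-analyte panel for the original and the evolved sensor.

suppressPackageStartupMessages(library(sensevo))

LANDSCAPE_SEED <- 42L
RUN_SEED <- 13L

dir.create("results", showWarnings = FALSE)

model <- build_landscape(LANDSCAPE_SEED)
noise <- noise_model(relative_sd = 0.05, replicate_count = 3, seed = RUN_SEED)
original <- validate_sequence("CCCCCCAGCCCTTCACCACCAACTCCCCCC", "original")

r0 <- selectivity_ratio(true_response(model, original, "5HT"),
                        true_response(model, original, "DA"),
                        sensor = "original")
cat(sprintf("original true-response selectivity 5HT/DA = %.3f\n",
            r0$ratio_5HT_DA))

trace <- run_evolution(original, model, noise, n_rounds = 2,
                       cfg = round_config(objective = "selectivity",
                                          seed = RUN_SEED),
                       surrogate = "ml")
print(trace)
best <- trace$trace[nrow(trace$trace), ]
cat(sprintf("selectivity %.3f -> %.3f (%.1f-fold)\n",
            trace$trace$parent_stat[1], best$best_stat,
            fold_change(best$best_stat, trace$trace$parent_stat[1])))

utils::write.csv(trace$trace, "results/evolution_selectivity_trace.csv",
                 row.names = FALSE)

best_seq <- sensor_seq(best$best_seq, name = best$best_name)
panel <- rbind(analyte_panel(model, noise, original),
               analyte_panel(model, noise, best_seq))
utils::write.csv(panel, "results/analyte_panel.csv", row.names = FALSE)
cat("panel (means):\n")
print(panel[, c("sensor", "analyte", "conc_uM", "mean_dFF0")],
      row.names = FALSE)

write_provenance("results/selectivity_provenance.json",
                 step = "05_selectivity", landscape_seed = LANDSCAPE_SEED,
                 run_seed = RUN_SEED, objective = "selectivity", n_rounds = 2)
cat("written: results/evolution_selectivity_trace.csv, results/analyte_panel.csv\n")
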