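#' Configuration for one directed-evolution round
#'
#' @param objective `"sensitivity"` (rank by mean serotonin dF/F0) or
#'   `"selectivity"` (rank by the serotonin/dopamine ratio of triplicate
#'   means).
#' @param k_mut substituted positions per mutant (default 3).
#' @param k_top candidates carried to measurement (default 20).
#' @param n_train landscape-labelled sequences used to train the surrogate
#'   each round (default 400; ignored by the oracle surrogate).
#' @param concentration screening concentration in uM (default 100,
#'   the panel protocol).
#' @param seed base seed; per-round sub-seeds are hashed from it.
#' @return config list for [run_round()] / [run_evolution()].
#' @export
round_config <- function(objective = c("sensitivity", "selectivity"),
                         k_mut = 3L, k_top = 20L, n_train = 400L,
                         concentration = 100, seed = 1L) {
  objective <- match.arg(objective)
  stopifnot(k_top >= 1L)
  list(objective = objective, k_mut = as.integer(k_mut),
       k_top = as.integer(k_top), n_train = as.integer(n_train),
       concentration = concentration, seed = as.integer(seed))
}

candidate_prefix <- function(objective) {
  if (objective == "selectivity") "L" else "N"
}

measure_candidate <- function(model, noise, s, objective, conc) {
  m5 <- simulate_measurement(model, noise, s, "5HT", conc)
  if (objective == "sensitivity") {
    list(stat = m5$mean, measurements = list(m5),
         stat_replicates = m5$replicates)
  } else {
    mda <- simulate_measurement(model, noise, s, "DA", conc)
    # ranking statistic: ratio of triplicate means; replicate-level ratios
    # retained for the saturation t-test
    list(stat = selectivity_ratio(m5$mean, mda$mean)$ratio_5HT_DA,
         measurements = list(m5, mda),
         stat_replicates = m5$replicates / mda$replicates)
  }
}

#' Run one directed-evolution round
#'
#' Enumerates the exactly-`k_mut` substitution library of the parent,
#' screens it with the surrogate ensemble (retrained each round on a seeded
#' sample of landscape-labelled sequences unless an oracle or frozen
#' ensemble is supplied), selects the top-`k_top` by mean predicted
#' response with classifier-consensus filtering, simulates triplicate
#' measurements for every candidate (serotonin only for the sensitivity
#' objective; serotonin and dopamine for selectivity), re-measures the
#' parent for within-round comparison, and picks the best candidate by the
#' objective statistic.
#'
#' @param parent a `sensor_seq`.
#' @param model a calibrated `landscape`.
#' @param noise a `noise_model`.
#' @param cfg see [round_config()].
#' @param surrogate `"ml"` (retrain this round), `"oracle"`, or a fitted
#'   `surrogate_ensemble` (frozen-model regime).
#' @param round_id integer round label.
#' @return object of class `round_result`: library size, top predictions,
#'   candidate measurement table, parent statistic, and `best`
#'   (sequence/name/statistic/replicates).
#' @export
run_round <- function(parent, model, noise, cfg = round_config(),
                      surrogate = "ml", round_id = 1L) {
  stopifnot(inherits(parent, "sensor_seq"), inherits(model, "landscape"))
  lib <- enumerate_k_mutants(parent, cfg$k_mut, round_id = round_id)
  ens <- if (inherits(surrogate, "surrogate_ensemble")) {
    surrogate
  } else if (identical(surrogate, "oracle")) {
    make_oracle_ensemble(model, "5HT")
  } else {
    idx <- withr::with_seed(hash_seed(cfg$seed, "train", round_id),
                            sample(length(lib$members), cfg$n_train))
    train_seqs <- lib$members[idx]
    fit_ensemble(train_seqs, true_response_many(model, train_seqs, "5HT"),
                 config = ensemble_config(seed = hash_seed(cfg$seed, "ens", round_id)),
                 flank_len = model$flank_len, var_len = model$var_len)
  }
  preds <- predict_ensemble(ens, lib$members)
  top <- select_top_k(preds, cfg$k_top)
  if (nrow(top) == 0L) {
    stop(sensevo_error("empty_selection",
      "no library member passed the classifier consistency filter"))
  }
  prefix <- candidate_prefix(cfg$objective)
  stats_list <- vector("list", nrow(top))
  meas <- list()
  for (i in seq_len(nrow(top))) {
    s <- sensor_seq(top$sequence[i],
                    name = sprintf("%s%d-%d", prefix, round_id, i),
                    flank_len = model$flank_len)
    stats_list[[i]] <- measure_candidate(model, noise, s, cfg$objective,
                                         cfg$concentration)
    meas <- c(meas, stats_list[[i]]$measurements)
  }
  parent_eval <- measure_candidate(model, noise, parent, cfg$objective,
                                   cfg$concentration)
  stat <- vapply(stats_list, function(x) x$stat, numeric(1))
  best_i <- order(-stat, top$sequence, method = "radix")[1L]
  top$measured_stat <- stat
  structure(
    list(round_id = as.integer(round_id), parent = parent,
         objective = cfg$objective, library_size = length(lib$members),
         top = top, measurements = measurement_table(meas),
         parent_stat = parent_eval$stat,
         parent_replicates = parent_eval$stat_replicates,
         best = list(
           sequence = top$sequence[best_i],
           name = sprintf("%s%d-%d", prefix, round_id, best_i),
           stat = stat[best_i],
           stat_replicates = stats_list[[best_i]]$stat_replicates)),
    class = "round_result")
}

#' @export
print.round_result <- function(x, ...) {
  cat(sprintf("<round_result> round %d (%s): library %d, measured %d, best %s = %.4g (parent %.4g)\n",
              x$round_id, x$objective, x$library_size, nrow(x$top),
              x$best$name, x$best$stat, x$parent_stat))
  invisible(x)
}

#' Welch saturation test between two replicate sets
#'
#' Two-sided Welch (unequal-variance) two-sample t-test; a non-significant
#' difference between consecutive round bests is read as saturation of the
#' evolution.
#'
#' @param replicates_a,replicates_b numeric vectors, >= 2 replicates each.
#' @param alpha significance level (default 0.05).
#' @return list `p_value`, `significant` (p < alpha).
#' @export
saturation_test <- function(replicates_a, replicates_b, alpha = 0.05) {
  if (length(replicates_a) < 2L || length(replicates_b) < 2L) {
    stop(sensevo_error("insufficient_replicates",
      "saturation test needs >= 2 replicates per group"))
  }
  if (stats::sd(replicates_a) == 0 && stats::sd(replicates_b) == 0) {
    # degenerate: t-test undefined at zero variance; identical means are
    # trivially non-significant, distinct means trivially significant
    p <- if (isTRUE(all.equal(mean(replicates_a), mean(replicates_b)))) 1 else 0
    return(list(p_value = p, significant = p < alpha))
  }
  tt <- stats::t.test(replicates_a, replicates_b, var.equal = FALSE)
  list(p_value = unname(tt$p.value), significant = unname(tt$p.value) < alpha)
}

#' Run a multi-round directed-evolution campaign
#'
#' Chains [run_round()]: each round's best candidate becomes the next
#' round's parent. Records the per-round best statistic and the Welch
#' saturation p-value between consecutive round bests; optionally stops
#' early once the improvement is no longer significant.
#'
#' @param start starting `sensor_seq` (e.g. the original sensor).
#' @param model a calibrated `landscape`.
#' @param noise a `noise_model`.
#' @param n_rounds rounds to attempt (>= 1).
#' @param cfg see [round_config()].
#' @param surrogate `"ml"`, `"oracle"`, or a frozen `surrogate_ensemble`.
#' @param early_stop stop after the first non-significant round-over-round
#'   change (default FALSE: fixed number of rounds, saturation judged post
#'   hoc).
#' @param alpha saturation test level.
#' @return object of class `evolution_trace`: `rounds` (list of
#'   `round_result`) and `trace` (data.frame round, parent, best_seq,
#'   best_name, best_stat, p_saturation).
#' @export
run_evolution <- function(start, model, noise, n_rounds, cfg = round_config(),
                          surrogate = "ml", early_stop = FALSE, alpha = 0.05) {
  stopifnot(n_rounds >= 1L)
  rounds <- list()
  parent <- start
  prev_best_reps <- NULL
  rows <- list()
  for (r in seq_len(n_rounds)) {
    res <- run_round(parent, model, noise, cfg, surrogate = surrogate,
                     round_id = r)
    p_sat <- NA_real_
    if (!is.null(prev_best_reps)) {
      p_sat <- saturation_test(prev_best_reps, res$best$stat_replicates,
                               alpha)$p_value
    }
    rounds[[r]] <- res
    rows[[r]] <- data.frame(
      round = r, parent = parent$bases, best_seq = res$best$sequence,
      best_name = res$best$name, best_stat = res$best$stat,
      parent_stat = res$parent_stat, p_saturation = p_sat,
      stringsAsFactors = FALSE)
    if (early_stop && !is.na(p_sat) && p_sat >= alpha) break
    parent <- sensor_seq(res$best$sequence, name = res$best$name,
                         flank_len = model$flank_len)
    prev_best_reps <- res$best$stat_replicates
  }
  structure(list(rounds = rounds, trace = do.call(rbind, rows)),
            class = "evolution_trace")
}

#' @export
print.evolution_trace <- function(x, ...) {
  cat("<evolution_trace>\n")
  print(x$trace, row.names = FALSE)
  invisible(x)
}

#' Write a provenance record beside an output file
#'
#' JSON record of the configuration, seeds and package version sufficient
#' to regenerate the output.
#'
#' @param path output JSON path.
#' @param ... named configuration entries (seeds, configs, input paths).
#' @return `path`, invisibly.
#' @export
write_provenance <- function(path, ...) {
  rec <- list(
    package = "sensevo",
    version = as.character(utils::packageVersion("sensevo")),
    r_version = R.version.string,
    ...)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a structured run-configuration file
#'
#' YAML file with optional sections `sequences`, `landscape`, `ensemble`,
#' `rounds`, `noise`, `output`; missing sections fall back to package
#' defaults.
#'
#' @param path YAML config path.
#' @return named list of sections.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  stopifnot(is.list(cfg))
  cfg
}
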