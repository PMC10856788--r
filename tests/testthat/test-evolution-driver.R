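test_that("an oracle-screened round recovers the brute-force library optimum", {
  m <- default_landscape()
  orig <- original_seq()
  nz <- noise_model(0, 3, seed = 1)
  res <- run_round(orig, m, nz, round_config(seed = 1), surrogate = "oracle")
  expect_identical(res$library_size, 22032L)
  expect_identical(nrow(res$top), 20L)

  lib <- full_library()
  truth <- true_response_many(m, lib$members, "5HT")
  best_bf <- lib$members[order(-truth, lib$members, method = "radix")[1]]
  expect_identical(res$best$sequence, best_bf)
  expect_true(res$best$sequence %in% res$top$sequence)
  expect_equal(res$best$stat, max(res$top$measured_stat))

  res1 <- run_round(orig, m, nz, round_config(k_top = 1, seed = 1),
                    surrogate = "oracle")
  expect_identical(nrow(res1$top), 1L)
  expect_identical(res1$best$sequence, res1$top$sequence[1])
})

test_that("selectivity rounds rank by the ratio of triplicate means", {
  m <- default_landscape()
  orig <- original_seq()
  nz <- noise_model(0, 3, seed = 2)
  cfg <- round_config(objective = "selectivity", k_top = 5, seed = 2)
  res <- run_round(orig, m, nz, cfg, surrogate = "oracle")
  expect_match(res$best$name, "^L1-")
  # zero noise: the measured statistic equals the true-response ratio
  # attenuated identically in numerator and denominator when K_d matches
  meas <- res$measurements
  for (i in seq_len(nrow(res$top))) {
    s <- res$top$sequence[i]
    kd5 <- landscape_kd(m, s, "5HT"); kdd <- landscape_kd(m, s, "DA")
    expected <- (true_response_many(m, s, "5HT") * 100 / (kd5 + 100)) /
      (true_response_many(m, s, "DA") * 100 / (kdd + 100))
    expect_equal(res$top$measured_stat[i], expected, tolerance = 1e-9)
  }
})

test_that("exhaustive toy campaign: greedy rounds equal brute-force per-round argmax", {
  m <- toy_landscape()
  start <- toy_seq("AAAAAA")
  nz <- noise_model(0, 3, seed = 1)
  cfg <- round_config(k_mut = 2, k_top = 10, seed = 3)
  tr <- run_evolution(start, m, nz, 3, cfg, surrogate = "oracle")

  parent <- start$bases
  for (r in 1:3) {
    lib <- enumerate_k_mutants(sensor_seq(parent, flank_len = 2L), 2)
    truth <- true_response_many(m, lib$members, "5HT")
    bf_best <- lib$members[order(-truth, lib$members, method = "radix")[1]]
    expect_identical(tr$trace$best_seq[r], bf_best)
    parent <- bf_best
  }
  # greedy statistic never decreases when the parent is improvable
  expect_true(all(diff(tr$trace$best_stat) >= -1e-12))
})

test_that("the toy landscape optimum is reachable and stable under the 2-mutation neighbourhood", {
  m <- toy_landscape()
  all_seqs <- all_toy_sequences(6L)
  truth <- true_response_many(m, all_seqs, "5HT")
  global_best <- max(truth)
  tr <- run_evolution(toy_seq("AAAAAA"), m, noise_model(0, 3, seed = 1), 6,
                      round_config(k_mut = 2, k_top = 10, seed = 3),
                      surrogate = "oracle")
  # the trace plateaus at a sequence no exactly-2-substitution move can
  # improve (a local optimum of the exhaustive landscape; because every
  # round must move by exactly k substitutions, later rounds oscillate
  # around it rather than repeat it)
  plateau <- tr$trace$best_seq[which.max(tr$trace$best_stat)]
  nb <- enumerate_k_mutants(sensor_seq(plateau, flank_len = 2L), 2)
  expect_true(all(true_response_many(m, nb$members, "5HT") <=
                    true_response_many(m, plateau, "5HT") + 1e-12))
  expect_lte(true_response_many(m, plateau, "5HT"), global_best + 1e-12)
})

test_that("the Welch saturation test flags clear differences and only those", {
  same <- saturation_test(c(1, 1.01, 0.99), c(1, 1.01, 0.99))
  expect_false(same$significant)
  expect_gte(same$p_value, 0.05)

  far <- saturation_test(rnorm(3, 1, 0.01), rnorm(3, 5, 0.01))
  expect_true(far$significant)

  expect_error(saturation_test(1, c(1, 2)),
               class = "sensevo_insufficient_replicates")

  # the two late-round responses (3.705 vs 3.765) at 5% relative noise are
  # statistically indistinguishable in at least 90% of triplicate draws
  n_sig <- 0L
  for (i in 1:1000) {
    reps <- withr::with_seed(50000 + i, {
      list(a = 3.705 * (1 + rnorm(3, 0, 0.05)),
           b = 3.765 * (1 + rnorm(3, 0, 0.05)))
    })
    if (saturation_test(reps$a, reps$b)$significant) n_sig <- n_sig + 1L
  }
  expect_lte(n_sig, 100L)
})

test_that("evolution traces chain parents and record saturation p-values", {
  m <- default_landscape()
  orig <- original_seq()
  nz <- noise_model(0.05, 3, seed = 9)
  tr <- run_evolution(orig, m, nz, 2, round_config(seed = 9),
                      surrogate = "oracle")
  expect_identical(nrow(tr$trace), 2L)
  expect_identical(tr$trace$parent[1], orig$bases)
  expect_identical(tr$trace$parent[2], tr$trace$best_seq[1])
  expect_true(is.na(tr$trace$p_saturation[1]))
  expect_false(is.na(tr$trace$p_saturation[2]))

  one <- run_evolution(orig, m, nz, 1, round_config(seed = 9),
                       surrogate = "oracle")
  expect_identical(nrow(one$trace), 1L)
})

test_that("identical seeds reproduce a machine-learned round byte for byte", {
  m <- default_landscape()
  orig <- original_seq()
  nz <- noise_model(0.05, 3, seed = 11)
  cfg <- round_config(n_train = 150, seed = 11)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  for (f in c(f1, f2)) {
    res <- run_round(orig, m, nz, cfg, surrogate = "ml")
    utils::write.csv(cbind(res$top, res$measurements), f, row.names = FALSE)
  }
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("provenance records and run configs round-trip", {
  f <- withr::local_tempfile(fileext = ".json")
  write_provenance(f, seed = 7, objective = "sensitivity",
                   noise = list(relative_sd = 0.05, replicates = 3))
  rec <- jsonlite::read_json(f)
  expect_identical(rec$package, "sensevo")
  expect_equal(rec$seed, 7)
  expect_equal(rec$noise$relative_sd, 0.05)

  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("landscape:", "  seed: 42", "noise:", "  relative_sd: 0.05",
               "rounds:", "  objective: sensitivity", "  n_rounds: 3"), yml)
  cfg <- read_run_config(yml)
  expect_identical(cfg$landscape$seed, 42L)
  expect_identical(cfg$rounds$objective, "sensitivity")
})
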