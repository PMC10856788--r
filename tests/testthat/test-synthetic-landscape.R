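test_that("calibration pins the anchor responses exactly and is idempotent", {
  m <- default_landscape()
  orig <- original_seq()
  expect_equal(true_response(m, orig, "5HT"), 0.949, tolerance = 1e-12)
  r_da <- true_response(m, orig, "DA")
  expect_equal(true_response(m, orig, "5HT") / r_da, 0.508,
               tolerance = 1e-9)

  m2 <- calibrate_landscape(m)
  expect_identical(m2$offsets, m$offsets)
  expect_identical(m2$weights, m$weights)
})

test_that("the landscape is a pure function of the seed", {
  a <- build_landscape(11)
  b <- build_landscape(11)
  c <- build_landscape(12)
  expect_identical(a$weights, b$weights)
  expect_identical(a$offsets, b$offsets)
  expect_false(identical(a$weights, c$weights))
})

test_that("contradictory or degenerate anchors are rejected", {
  cfg <- landscape_config(anchors = list(
    list(bases = ORIGINAL_BASES, analyte = "5HT", target = 1.0),
    list(bases = ORIGINAL_BASES, analyte = "5HT", target = 2.0)))
  expect_error(build_landscape(1, cfg), class = "sensevo_infeasible_anchor")

  cfg2 <- landscape_config(ratio_anchors = list(
    list(bases = ORIGINAL_BASES, num = "5HT", den = "DA", ratio = 0)))
  expect_error(build_landscape(1, cfg2), class = "sensevo_infeasible_anchor")
})

test_that("zero-weight landscapes return the calibrated offset everywhere", {
  cfg <- landscape_config(weight_sd = 0)
  m <- build_landscape(3, cfg)
  lib <- enumerate_k_mutants(original_seq(), 1)
  r <- true_response_many(m, lib$members, "5HT")
  expect_true(all(abs(r - 0.949) < 1e-12))
})

test_that("single-base changes shift the response by exactly the weight difference", {
  m <- default_landscape()
  orig <- original_seq()
  W <- m$weights[["5HT"]]
  pv <- strsplit(orig$var_region, "")[[1]]
  for (pos in c(1L, 9L, 18L)) {
    for (to in setdiff(c("A", "C", "G", "T"), pv[pos])) {
      mv <- pv; mv[pos] <- to
      mut <- paste0("CCCCCC", paste(mv, collapse = ""), "CCCCCC")
      delta <- true_response(m, mut, "5HT") - true_response(m, orig, "5HT")
      expect_equal(delta, unname(W[pos, to] - W[pos, pv[pos]]),
                   tolerance = 1e-12)
    }
  }
})

test_that("responses are clipped at -1 and spectra stay nonnegative", {
  cfg <- landscape_config(weight_sd = 1.5)
  m <- build_landscape(5, cfg)
  lib <- enumerate_k_mutants(original_seq(), 3)
  set.seed(1)
  r <- true_response_many(m, sample(lib$members, 500), "GABA")
  expect_true(all(r >= -1))
  worst <- lib$members[which.min(true_response_many(m, lib$members, "GABA"))]
  sp <- simulate_spectrum(m, worst, "GABA", 1e6)
  expect_true(all(sp$intensities >= 0))
})

test_that("epistatic terms are drawn when requested and respected by the response", {
  cfg <- landscape_config(epistasis_density = 0.5)
  m <- build_landscape(9, cfg)
  expect_gt(nrow(m$epistasis[["5HT"]]), 0)
  # vectorised and scalar paths agree with epistasis enabled
  lib <- enumerate_k_mutants(original_seq(), 2)
  set.seed(2)
  sub <- sample(lib$members, 50)
  vec <- true_response_many(m, sub, "5HT")
  ind <- vapply(sub, function(s) true_response(m, s, "5HT"), numeric(1),
                USE.NAMES = FALSE)
  expect_equal(vec, ind, tolerance = 1e-12)
})

test_that("spectra: baseline identity at zero concentration, Hill saturation, closed-form readout", {
  m <- default_landscape()
  orig <- original_seq()
  sp0 <- simulate_spectrum(m, orig, "5HT", 0)
  base <- simulate_spectrum(m, orig, "baseline", 0)
  expect_identical(sp0$intensities, base$intensities)
  expect_true(all(diff(sp0$wavelengths) > 0))

  # saturation: peak scaling approaches 1 + true_response
  r <- true_response(m, orig, "5HT")
  kd <- landscape_kd(m, orig, "5HT")
  sp_inf <- simulate_spectrum(m, orig, "5HT", 1e6 * kd)
  f0 <- intensity_at(sp0, 1202)
  expect_equal(intensity_at(sp_inf, 1202) / f0, 1 + r, tolerance = 1e-5)

  # closed form at the protocol concentration: K_d = 11.6 uM, n = 1
  sp100 <- simulate_spectrum(m, orig, "5HT", 100)
  expect_equal(intensity_at(sp100, 1202),
               f0 * (1 + 0.949 * (100 / (11.6 + 100))),
               tolerance = 1e-9)

  expect_error(simulate_spectrum(m, orig, "5HT", -1),
               class = "sensevo_invalid_concentration")
})

test_that("spectrum-derived dF/F0 equals true_response times the Hill fraction", {
  m <- default_landscape()
  orig <- original_seq()
  r <- true_response(m, orig, "5HT")
  kd <- landscape_kd(m, orig, "5HT")
  f0 <- intensity_at(simulate_spectrum(m, orig, "5HT", 0), 1202)
  for (conc in c(0.1, 1, 10, 100)) {
    f <- intensity_at(simulate_spectrum(m, orig, "5HT", conc), 1202)
    expect_equal(delta_f_over_f0(f, f0), r * conc / (kd + conc),
                 tolerance = 1e-9)
  }
})

test_that("dissociation constants are deterministic, near 10 uM, and anchor-overridable", {
  m <- default_landscape()
  orig <- original_seq()
  expect_identical(landscape_kd(m, orig, "5HT"), 11.6)
  expect_identical(landscape_kd(m, orig, "DA"), 11.6)
  lib <- enumerate_k_mutants(orig, 3)
  set.seed(3)
  kds <- vapply(sample(lib$members, 100), landscape_kd, numeric(1),
                model = m, analyte = "5HT")
  expect_identical(kds, vapply(names(kds), landscape_kd, numeric(1),
                               model = m, analyte = "5HT"))
  expect_true(all(kds > 2 & kds < 50))
  expect_gt(length(unique(round(kds, 6))), 50)
})

test_that("measurements follow the triplicate protocol with unbiased multiplicative noise", {
  m <- default_landscape()
  orig <- original_seq()

  clean <- simulate_measurement(m, noise_model(0, 3, seed = 1), orig, "5HT", 100)
  noiseless <- 0.949 * 100 / 111.6
  expect_length(clean$replicates, 3L)
  expect_true(all(abs(clean$replicates - noiseless) < 1e-9))

  expect_identical(noise_model()$replicate_count, 3L)
  expect_identical(noise_model()$relative_sd, 0.05)

  # Monte-Carlo unbiasedness: mean of replicate-means across seeds within
  # 3 standard errors of the noiseless value
  n_seeds <- 4000
  means <- vapply(seq_len(n_seeds), function(s) {
    simulate_measurement(m, noise_model(0.05, 3, seed = s), orig, "5HT", 100)$mean
  }, numeric(1))
  se <- noiseless * 0.05 / sqrt(3 * n_seeds)
  expect_lt(abs(mean(means) - noiseless), 3 * se)

  # same seed, same measurement; different seed, different noise
  a <- simulate_measurement(m, noise_model(0.05, 3, seed = 5), orig, "5HT", 100)
  b <- simulate_measurement(m, noise_model(0.05, 3, seed = 5), orig, "5HT", 100)
  c <- simulate_measurement(m, noise_model(0.05, 3, seed = 6), orig, "5HT", 100)
  expect_identical(a$replicates, b$replicates)
  expect_false(identical(a$replicates, c$replicates))
})
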