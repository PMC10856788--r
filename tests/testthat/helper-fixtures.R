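# sequences printed for the study sensors
ORIGINAL_BASES <- "CCCCCCAGCCCTTCACCACCAACTCCCCCC"
N21_BASES      <- "CCCCCCAACCCTACACAACCACCTCCCCCC"
L114_BASES     <- "CCCCCCAGCACTACACAACCAACTCCCCCC"

original_seq <- function() validate_sequence(ORIGINAL_BASES, "original")

PROTOCOL_CONC <- c(0.1, 1, 5, 10, 30, 70, 100)

# memoized expensive fixtures (landscape, full 22k library) shared across
# test files; all are pure functions of fixed seeds
.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

default_landscape <- function() memo("landscape42", build_landscape(42))

full_library <- function() memo("lib3", enumerate_k_mutants(original_seq(), 3))

# toy sensor design: 2-C flanks around a 6-nt variable region (4^6 = 4096
# total sequences -> exhaustive checks stay cheap)
toy_seq <- function(var = "AAAAAA", name = "toy") {
  sensor_seq(paste0("CC", var, "CC"), name = name, flank_len = 2L)
}

toy_landscape <- function(seed = 7) {
  memo(paste0("toy", seed), {
    # kd_log_sd = 0 pins every K_d at 10 uM, so the fixed-concentration
    # measured response is a monotone transform of the true response and
    # exhaustive argmax comparisons are exact
    cfg <- landscape_config(
      analytes = c("5HT", "DA"),
      reference_bases = paste0("CC", "AAAAAA", "CC"),
      flank_len = 2L,
      kd_log_sd = 0,
      anchors = list(list(bases = paste0("CC", "AAAAAA", "CC"),
                          analyte = "5HT", target = 0.9, kd = 10)),
      ratio_anchors = list(list(bases = paste0("CC", "AAAAAA", "CC"),
                                num = "5HT", den = "DA", ratio = 0.508,
                                kd = 10)),
      default_response = c())
    build_landscape(seed, cfg)
  })
}

# all 4^L sequences over a toy variable region (exhaustive oracle scans)
all_toy_sequences <- function(L, flank_len = 2L) {
  grids <- rep(list(c("A", "C", "G", "T")), L)
  combos <- do.call(expand.grid, c(grids, list(stringsAsFactors = FALSE)))
  vars <- do.call(paste0, combos)
  paste0(strrep("C", flank_len), vars, strrep("C", flank_len))
}

hamming_var <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}
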