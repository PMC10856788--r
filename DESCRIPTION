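Package: sensevo
Title: Machine-Learning-Guided Directed Evolution of ssDNA-SWCNT Serotonin Nanosensors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: In-silico pipeline for directed evolution of serotonin-responsive
    ssDNA-wrapped single-walled carbon nanotube (SWCNT) fluorescence nanosensors.
    Enumerates the complete exactly-three-base substitution library over the
    18-nt variable region of a 30-mer sensor sequence, screens it with a
    surrogate ensemble (two kernel regressors plus nine binary classifiers)
    ranked by the mean predicted fluorescence response, simulates triplicate
    near-infrared fluorescence measurements against a calibrated synthetic
    sequence-to-response landscape, fits Hill dose-response curves to recover
    dissociation constants, and chains greedy selection rounds for sensitivity
    and serotonin/dopamine selectivity objectives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    e1071,
    nnet,
    minpack.lm,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
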