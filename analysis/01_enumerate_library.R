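#!/usr/bin/env Rscript
# Round-1 mutant library: every sequence at exactly 3 substitutions from the
# original sensor's 18-nt variable region, hexa-C flanks fixed.

suppressPackageStartupMessages(library(sensevo))

dir.create("results", showWarnings = FALSE)

original <- validate_sequence("CCCCCCAGCCCTTCACCACCAACTCCCCCC", "original")
lib <- enumerate_k_mutants(original, 3, round_id = 1L)

cat(sprintf("parent: %s (variable region %s)\n", original$bases,
            original$var_region))
cat(sprintf("library: %d distinct members (choose(18,3) * 3^3 = %d)\n",
            length(lib$members), choose(18, 3) * 27))

write_library_fasta(lib, "results/library_round1.fasta")
utils::write.csv(library_manifest(lib), "results/library_round1_manifest.csv",
                 row.names = FALSE)
write_provenance("results/library_round1_provenance.json",
                 step = "01_enumerate_library", parent = original$bases,
                 k_mut = 3, round_id = 1)
cat("written: results/library_round1.fasta, results/library_round1_manifest.csv\n")
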