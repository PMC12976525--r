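#!/usr/bin/env Rscript

# Stage 1: generate the study dataset.
#
# Writes the simulated cis-region summary statistics (eQTL and pQTL exposure
# sources, sex-stratified and combined Parkinson's disease outcome strata, a
# type 2 diabetes mediator), the LD reference, and a JSON manifest recording
# the generating truth. Everything downstream reads these files.

library(targetmr)

seed <- 1
dir <- file.path("results", "data")

cfg <- make_fixture_study(seed = seed, dir = dir)

cat("Wrote study inputs to", dir, "\n")
cat("Files:", paste(list.files(dir), collapse = ", "), "\n")
truth <- attr(cfg, "truth")
cat("Causal cis-eQTL variants:", length(truth$causal_idx), "\n")
cat("Stratum log-odds effects:",
    paste(sprintf("%s=%.3f", names(truth$theta), unlist(truth$theta)),
          collapse = ", "), "\n")
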