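#!/usr/bin/env Rscript

# Stage 3: the primary MR estimator battery.
#
# For every exposure source x outcome stratum, run the full battery (IVW,
# MR-Egger, weighted median, weighted mode, PRESSO-style correction; Wald
# ratio for single-SNP cells) at the primary clumping threshold, with the
# decision rules (heterogeneity -> radial removal, directional pleiotropy ->
# Egger override) applied and traced.

library(targetmr)

seed <- 1
cfg <- make_fixture_study(seed = seed, dir = tempfile("data-"))
res <- run_full_study(cfg, out_dir = "results")

prim <- res$battery[!is.na(res$battery$primary) & res$battery$primary, ]
cat("Primary estimates (clump r^2 < 0.1):\n")
print(prim[, c("source", "stratum", "method", "nsnp", "or",
               "or_ci_low", "or_ci_high", "pvalue")], digits = 3)
cat("\nFull tables written under results/\n")
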