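# Shared builders for unit and acceptance tests. All fixtures are built in
# code; no files ship with the package.

# Minimal harmonized-pairs table from raw effect vectors.
make_pairs <- function(bx, by, sy, sx = rep(0.01, length(bx)),
                       eaf = rep(0.3, length(bx)),
                       ids = sprintf("snp%02d", seq_along(bx))) {
  data.frame(
    variant_id = ids, chrom = "1", pos = seq_along(bx) * 1000,
    effect_allele = "A", other_allele = "G",
    exposure_beta = bx, exposure_se = sx, exposure_eaf = eaf,
    exposure_pvalue = 2 * stats::pnorm(-abs(bx / sx)),
    exposure_n = 30000,
    outcome_beta = by, outcome_se = sy, outcome_eaf = eaf,
    outcome_pvalue = 2 * stats::pnorm(-abs(by / sy)),
    outcome_n = 20000, outcome_n_cases = 10000, outcome_n_controls = 10000,
    action = "aligned", stringsAsFactors = FALSE
  )
}

# Minimal summary-statistics table.
make_records <- function(ids, beta, se, eaf = rep(0.3, length(ids)),
                         ea = rep("A", length(ids)), oa = rep("G", length(ids)),
                         chrom = "1", pos = seq_along(ids) * 1000,
                         pvalue = 2 * stats::pnorm(-abs(beta / se)),
                         n = 30000, trait_id = "trait",
                         trait_type = "quantitative", ...) {
  # tests often set p-values purely to control rankings, so the reader's
  # p-vs-z consistency advisory is expected noise here
  withCallingHandlers(
    as_sumstats(data.frame(variant_id = ids, chrom = chrom, pos = pos,
                           effect_allele = ea, other_allele = oa, eaf = eaf,
                           beta = beta, se = se, pvalue = pvalue, n = n, ...,
                           stringsAsFactors = FALSE),
                trait_id = trait_id, trait_type = trait_type),
    targetmr_pvalue_inconsistent = function(w) invokeRestart("muffleWarning"))
}

# One scenario replicate run through instrument construction.
scenario_instrument <- function(name, seed, ...) {
  sc <- simulate_scenario(name, seed = seed, ...)
  inst <- suppressWarnings(
    build_instrument(sc$exposure, sc$outcome, sc$region$gene, sc$region$ld,
                     m = sc$region$m))
  list(sc = sc, inst = inst)
}

# Independent weighted-least-squares oracle (QR-based via lm) for IVW and
# Egger: regression of by on bx with weights 1/sy^2, through the origin or
# with an intercept.
wls_oracle <- function(bx, by, sy, intercept = FALSE) {
  w <- 1 / sy^2
  fit <- if (intercept) stats::lm(by ~ bx, weights = w) else
    stats::lm(by ~ 0 + bx, weights = w)
  cf <- summary(fit)$coefficients
  sigma <- summary(fit)$sigma
  slope_row <- if (intercept) 2 else 1
  list(slope = cf[slope_row, 1],
       slope_se_fixed = cf[slope_row, 2] / sigma,
       intercept = if (intercept) cf[1, 1] else 0,
       intercept_se_fixed = if (intercept) cf[1, 2] / sigma else NA_real_,
       sigma2 = sigma^2,
       q = sum(w * stats::residuals(fit)^2))
}

# Brute-force five-hypothesis colocalization oracle: explicit enumeration of
# all (i, j) causal-variant configurations, in log space for stability.
coloc_oracle <- function(t1, t2, priors, sd1, sd2) {
  la1 <- log_abf(t1$beta, t1$se, sd1)
  la2 <- log_abf(t2$beta, t2$se, sd2)
  m <- length(la1)
  lse <- function(x) {
    mx <- max(x)
    if (!is.finite(mx)) return(mx)
    mx + log(sum(exp(x - mx)))
  }
  l3_terms <- c()
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i != j) l3_terms <- c(l3_terms, la1[i] + la2[j])
  }
  lw <- c(0,
          log(priors$p1) + lse(la1),
          log(priors$p2) + lse(la2),
          if (m > 1) log(priors$p1) + log(priors$p2) + lse(l3_terms) else -Inf,
          log(priors$p12) + lse(la1 + la2))
  pp <- exp(lw - lse(lw))
  names(pp) <- paste0("PP", 0:4)
  pp
}
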