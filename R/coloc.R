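# Bayesian five-hypothesis colocalization between two association signals
# over a shared cis window, using Wakefield approximate Bayes factors under
# a single-causal-variant assumption per trait.
#
# Hypotheses: H0 no association; H1/H2 one trait only; H3 both traits,
# distinct causal variants; H4 both traits, one shared causal variant.

#' Colocalization priors
#'
#' Per-variant prior probabilities: `p1` (associated with trait 1 only),
#' `p2` (trait 2 only), `p12` (both). The defaults are the conventional
#' single-variant priors p1 = p2 = 1e-4, p12 = 1e-5; the `"relaxed"` preset
#' (p1 = 1e-4, p2 = 1e-3, p12 = 1e-4) accommodates limited overlap between
#' a QTL signal and a GWAS signal.
#'
#' @param p1,p2,p12 per-variant priors, each in (0,1) with sum below 1.
#' @return object of class `coloc_priors`.
#' @export
coloc_priors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  stopifnot(p1 > 0, p2 > 0, p12 > 0, p1 < 1, p2 < 1, p12 < 1, p1 + p2 + p12 < 1)
  structure(list(p1 = p1, p2 = p2, p12 = p12), class = "coloc_priors")
}

#' Named prior presets
#' @param name `"default"` or `"relaxed"`.
#' @return [coloc_priors()] object.
#' @export
coloc_priors_preset <- function(name = c("default", "relaxed")) {
  switch(match.arg(name),
         default = coloc_priors(1e-4, 1e-4, 1e-5),
         relaxed = coloc_priors(1e-4, 1e-3, 1e-4))
}

#' Wakefield log approximate Bayes factor
#'
#' For an estimate `beta` with standard error `se` under a normal effect
#' prior with scale `prior_sd`: with z = beta/se and
#' r = prior_sd^2 / (prior_sd^2 + se^2), log ABF = 0.5 (log(1 - r) + r z^2).
#'
#' @param beta,se estimate and standard error (se > 0). Vectorized.
#' @param prior_sd effect-size prior scale (> 0).
#' @return log Bayes factor in favour of association.
#' @export
log_abf <- function(beta, se, prior_sd) {
  stopifnot(all(se > 0), prior_sd > 0)
  r <- prior_sd^2 / (prior_sd^2 + se^2)
  z <- beta / se
  0.5 * (log1p(-r) + r * z^2)
}

default_prior_sd <- function(trait_type) {
  # effect-size prior scales: log-odds for binary traits, per-SD for
  # standardized quantitative traits
  if (identical(trait_type, "binary")) 0.15 else 0.2
}

#' Five-hypothesis colocalization of two traits over a region
#'
#' Computes per-variant log-ABFs for each trait over the shared variants and
#' assembles the hypothesis sums in log space (log-sum-exp):
#' H1 = sum_i ABF1_i, H2 = sum_j ABF2_j, H4 = sum_i ABF1_i ABF2_i, and
#' H3 = sum_{i != j} ABF1_i ABF2_j (the product of the single-trait sums
#' minus the diagonal). Posteriors are the prior-weighted hypothesis masses
#' (1, p1 H1, p2 H2, p1 p2 H3, p12 H4) normalized over the five hypotheses.
#'
#' @param trait1,trait2 summary-statistics tables sharing >= 1 variant;
#'   restrict both to the same cis window used for instrument selection
#'   before calling (see [select_cis_significant()]).
#' @param priors [coloc_priors()].
#' @param prior_sd1,prior_sd2 effect-size prior scales; default 0.15 for
#'   binary traits (log-odds) and 0.2 for standardized quantitative traits.
#' @return object of class `coloc_result`: list with `pp` (named PP0..PP4,
#'   summing to 1), `priors`, `nsnps`, `per_snp_log_abf` (two vectors), and
#'   `top_shared_variant` (largest per-SNP H4 contribution).
#' @export
colocalize <- function(trait1, trait2, priors = coloc_priors(),
                       prior_sd1 = NULL, prior_sd2 = NULL) {
  stopifnot(inherits(priors, "coloc_priors"))
  shared <- intersect(trait1$variant_id, trait2$variant_id)
  if (length(shared) == 0) {
    stop_targetmr("no shared variants between the two traits", "targetmr_no_overlap")
  }
  t1 <- trait1[match(shared, trait1$variant_id), ]
  t2 <- trait2[match(shared, trait2$variant_id), ]
  sd1 <- prior_sd1 %||% default_prior_sd(t1$trait_type[1])
  sd2 <- prior_sd2 %||% default_prior_sd(t2$trait_type[1])

  la1 <- log_abf(t1$beta, t1$se, sd1)
  la2 <- log_abf(t2$beta, t2$se, sd2)

  l1 <- logsumexp(la1)
  l2 <- logsumexp(la2)
  l4 <- logsumexp(la1 + la2)
  l3 <- if (length(shared) == 1L) -Inf else logdiffexp(l1 + l2, l4)

  lw <- c(0,
          log(priors$p1) + l1,
          log(priors$p2) + l2,
          log(priors$p1) + log(priors$p2) + l3,
          log(priors$p12) + l4)
  pp <- exp(lw - logsumexp(lw))
  names(pp) <- paste0("PP", 0:4)

  h4_contrib <- la1 + la2
  structure(list(pp = pp, priors = priors, nsnps = length(shared),
                 per_snp_log_abf = list(trait1 = stats::setNames(la1, shared),
                                        trait2 = stats::setNames(la2, shared)),
                 top_shared_variant = shared[which.max(h4_contrib)]),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("Colocalization over %d variants (p1=%.1g, p2=%.1g, p12=%.1g)\n",
              x$nsnps, x$priors$p1, x$priors$p2, x$priors$p12))
  print(round(x$pp, 4))
  cat(sprintf("top shared-variant candidate: %s\n", x$top_shared_variant))
  invisible(x)
}

#' Colocalization over a grid of priors
#'
#' Runs [colocalize()] at each prior setting and flags grid points where
#' PP4 crosses the 0.8 decision threshold for a shared causal variant.
#'
#' @param trait1,trait2 as in [colocalize()].
#' @param priors_grid named list of [coloc_priors()]; default the
#'   `"default"` and `"relaxed"` presets.
#' @param pp4_threshold decision threshold (default 0.8).
#' @param ... passed to [colocalize()].
#' @return data.frame with one row per grid point: preset name, priors,
#'   PP0..PP4, nsnps, and `pp4_above_threshold`.
#' @export
prior_sensitivity <- function(trait1, trait2,
                              priors_grid = list(default = coloc_priors_preset("default"),
                                                 relaxed = coloc_priors_preset("relaxed")),
                              pp4_threshold = 0.8, ...) {
  stopifnot(length(priors_grid) >= 1)
  rows <- lapply(names(priors_grid), function(nm) {
    pr <- priors_grid[[nm]]
    res <- colocalize(trait1, trait2, priors = pr, ...)
    data.frame(preset = nm, p1 = pr$p1, p2 = pr$p2, p12 = pr$p12,
               PP0 = res$pp[["PP0"]], PP1 = res$pp[["PP1"]], PP2 = res$pp[["PP2"]],
               PP3 = res$pp[["PP3"]], PP4 = res$pp[["PP4"]],
               nsnps = res$nsnps,
               top_shared_variant = res$top_shared_variant,
               pp4_above_threshold = res$pp[["PP4"]] > pp4_threshold,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
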