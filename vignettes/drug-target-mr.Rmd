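---
title: "Drug-target Mendelian randomization: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug-target Mendelian randomization: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetmr)
```

# Scope

`targetmr` implements a complete two-sample drug-target Mendelian
randomization (MR) workflow from summary statistics: instrument selection
in a cis window around a target gene, allele harmonization, an estimator
battery with explicit decision rules, directionality and power checks,
two-step mediation with an instrument-stratification fallback, Bayesian
colocalization, and a ground-truth simulator used to validate all of the
above. This vignette documents the model, every tunable parameter and its
default, the numerical choices, and the limitations.

# Model and assumptions

## Instruments

A variant is an eligible instrument if it lies in the cis window
`[start - w, end + w]` (inclusive; `window_kb = 200` by default — wide
enough to capture regulatory variation for most genes while keeping the
"cis" interpretation that the variant acts through the target) and passes a
significance rule. The default rule is Bonferroni: `p < alpha_family / m`
with `alpha_family = 0.05` and `m` the number of markers tested in the
window, which must be supplied explicitly — silently defaulting `m` to the
number of rows would understate the correction whenever the input has been
pre-filtered. A fixed-threshold policy (`p < 1e-5`) is available for
lower-powered exposure datasets such as tissue-specific QTL panels.

Correlated instruments are pruned by greedy LD clumping: variants are
ranked by p-value (ties broken deterministically by `(pvalue, variant_id)`
so results never depend on input order), the best variant is kept, and
everything with `r^2 >= r2_threshold` against a kept variant is dropped.
The default `r2_threshold = 0.1` balances instrument count against the
independence assumption of the estimators; a sweep over
`{0.3, 0.2, 0.1, 0.05, 0.01}` is built into the pipeline because this
choice is the single most influential analyst degree of freedom. Note that
greedy clumping at a looser threshold is *not* guaranteed to keep a
superset of the variants kept at a tighter threshold — only the kept
*count* is monotone — so the sweep reports every threshold rather than
assuming nesting.

Instrument strength is summarized by the explained variance
`R^2 = sum_j 2 beta_j^2 EAF_j (1 - EAF_j)` (per-allele effects,
Hardy-Weinberg variance) and
`F = [(N - K - 1) / K] * [R^2 / (1 - R^2)]`; `F < 10` flags a weak
instrument. Summing per-variant `R^2` overstates the total under residual
LD; this is the conventional choice and is why it is paired with clumping
at `r^2 < 0.1`.

## Harmonization

Exposure and outcome records are aligned on variant ID. Alleles may match
directly, after swapping (flipping the outcome beta sign), or after strand
complementation. Palindromic variants (A/T, C/G) are kept only when both
allele frequencies fall on the same side of 0.5 and both minor-allele
frequencies are below `palindrome_eaf_limit = 0.42`; closer to 0.5 the
strand cannot be inferred from frequency and the variant is dropped. Every
input row is returned with an action label
(`aligned`/`flipped`/`dropped_palindromic`/`dropped_mismatch`) so the
harmonization is fully auditable.

## Estimators

* **Wald ratio** (single variant): `beta_y / beta_x`, first-order delta
  standard error `s_y / |beta_x|`; an optional second-order term adds
  exposure-side noise.
* **IVW**: weighted regression of `beta_y` on `beta_x` through the origin,
  weights `1/s_y^2`. The standard error is multiplied by
  `sqrt(max(1, Q/(k-1)))` (multiplicative random effects): heterogeneity
  widens intervals but is never allowed to shrink them.
* **MR-Egger**: the same regression with an intercept, after orienting all
  pairs to `beta_x > 0` (the estimate is invariant to joint per-variant
  sign flips; orientation makes the intercept interpretable as average
  directional pleiotropy). The *slope* keeps the truncated multiplicative
  random-effects form for comparability with IVW. The *intercept test*
  uses a t reference with `k - 2` degrees of freedom and untruncated
  dispersion: with the instrument counts typical of a single cis region
  (5-15 variants) a normal test with truncated dispersion is visibly
  anticonservative, and the t form is exact under the null. This is the
  one place the package deliberately departs from the simplest textbook
  formula; the choice is validated by a calibration test.
* **Weighted median**: ratio estimates ordered, cumulative weights
  (`(beta_x/s_y)^2`, normalized) interpolated at the midpoint convention;
  the standard error is a parametric bootstrap (`nboot = 1000` by default —
  enough for a stable second digit without dominating runtime). Midpoint
  interpolation means a variant carrying just over half the weight
  dominates but does not exactly determine the estimate.
* **Weighted mode**: Gaussian-kernel weighted density over ratio estimates,
  bandwidth `0.9 min(sd, mad) n^{-1/5} * phi` (modified Silverman;
  `phi = 1` default), maximized on a 512-point grid refined by
  `optimize()`.
* **Radial outliers**: per-variant contributions to Cochran's Q compared to
  chi-squared(1) at a Bonferroni-corrected level `0.05/k`, removed
  iteratively, IVW refit on the remainder.
* **PRESSO-style test**: observed leave-one-out residual sums of squares
  against `nsim = 1000` parametric simulations; per-variant removal is only
  applied when the global test fires (`p < 0.05`), mirroring the reference
  procedure's gating so that clean instruments are never modified.
* **Steiger directionality**: compares instrument-explained correlation in
  exposure versus outcome via Fisher's z; for binary outcomes the implied
  correlation uses the observed-scale `cf(1-cf)` factor at case fraction
  `cf`. This tests direction on the observed scale only.
* **Power**: analytic binary-outcome power with
  `se = 1/sqrt(n cf (1-cf) R^2)` at a two-sided `alpha = 0.05`.

## Reporting decision rules

`run_mr_cell()` applies a fixed, traced rule set: one variant reports the
Wald ratio; otherwise IVW is primary; heterogeneity (`Q` p < 0.05, k >= 3)
triggers radial outlier removal and records the refit; a significant Egger
intercept (p < 0.05) overrides the primary to the Egger slope, taking
precedence over the heterogeneity rule because directional pleiotropy
biases IVW whether or not outliers are removed. Every firing is recorded in
a trace (`primary_method_used`, `outliers_removed`, `rationale`) so a
report can be audited or replayed from the recorded diagnostics alone.

## Mediation

Two-step MR estimates exposure-to-mediator (step 1, cis instruments) and
mediator-to-outcome (step 2, genome-wide mediator instruments at
`p < 5e-8`, clumped at `r^2 < 0.001`). A gate refuses the
product-of-coefficients decomposition (`indirect = b1 * b2`, delta-method
standard error) unless both steps are estimable and significant; refusal
reasons are reported verbatim. Independently, the exposure instrument is
split at mediator association `p <= 0.05` and the battery re-run per
stratum — a coarse but assumption-light probe of whether the effect
concentrates in mediator-associated variants.

## Colocalization

Per-variant Wakefield log approximate Bayes factors
`0.5 [log(1 - r) + r z^2]`, `r = W/(W + se^2)`, with prior effect standard
deviation `sqrt(W) = 0.2` for quantitative and `0.15` for binary traits
(conventional values for standardized and log-odds effects respectively).
Hypothesis sums use `logsumexp`, and the two-distinct-variants term H3 is
computed as `logdiffexp(l1 + l2, l4)` — the sum over ordered pairs `i != j`
— which is exact and avoids the quadratic enumeration. Priors default to
`p1 = p2 = 1e-4`, `p12 = 1e-5`; a `relaxed` preset (`p2 = 1e-3`,
`p12 = 1e-4`) is provided for outcome datasets where per-variant power is
low, and `prior_sensitivity()` reports posteriors across presets because
PP4 is monotone in `p12` and a single prior choice should never carry a
colocalization claim alone. `PP4 > 0.8` is the conventional shared-variant
call. Single-variant regions make H3 structurally impossible (`PP3 = 0`).

# The simulator

## What it emulates

`simulate_region()` builds a cis region of `m` variants with AR1 LD
(`r[i,j] = rho^|i-j|`, default `rho = 0.8`) and allele frequencies drawn in
`[0.05, 0.95]`. Summary statistics are drawn *directly from the sampling
distribution of marginal GWAS estimators*: on the standardized scale the
marginal means are `mu = R gamma` (LD-smeared joint effects) with noise
covariance `se^2 R`, where `se = 1/sqrt(n)` for quantitative traits and
`1/sqrt(n cf (1-cf))` for binary traits, converted to per-allele units by
`sqrt(2 EAF (1-EAF))`. This reproduces exactly the quantities an MR
analysis consumes — correlated effect estimates, standard errors, allele
frequencies — without simulating individual-level genotypes.

Named scenarios provide designed truths: `null`, `causal` (theta = 0.3),
`pleiotropy` (directional per-variant effects), `outlier` (one gross
pleiotropic variant), `shared_coloc`/`distinct_coloc`, `reverse`
(outcome-causal), and `mediation` (exposure -> mediator -> outcome with
non-mediating exposure variants as negative controls). Scenario defaults —
`m = 60`, `rho = 0.8`, `n_exposure = 30000`, 10000 cases / 10000
controls — are this package's own choice of a realistically sized
single-region problem: large enough for 5-10 clumped instruments and
stable operating characteristics, small enough that thousand-replicate
calibration studies run in seconds.

`make_fixture_study()` assembles a full multi-dataset study: eQTL and pQTL
exposure sources (protein effects proportional to expression effects, so
the pQTL estimate is attenuated, as expected when the protein is
downstream), three outcome strata with distinct effects (a strong effect in
men, none in women, intermediate pooled), a mediator with a weak
exposure-driven component and no genome-wide instruments of its own (so the
two-step gate must refuse and the stratified fallback runs), and a written
set of inputs (TSV + JSON manifest recording the full generating truth).

All randomness flows from one master seed through named sub-streams
(`derive_seed(master, name)`), so any component can be regenerated in
isolation and full-study reruns are byte-identical.

## What it does not emulate

* No individual-level genotypes, sample overlap between datasets,
  population stratification, or relatedness.
* AR1 LD is a stylized pattern; real regions have block structure and
  long-range tags.
* Binary-trait effects are generated on the observed (linear) scale with
  the `cf(1-cf)` variance factor; liability-scale phenomena such as
  case-control ascertainment bias are not modeled.
* Allele frequencies are shared across datasets (no cross-population
  frequency drift), so harmonization stress cases (strand flips,
  palindromes near 0.5) are exercised by dedicated unit fixtures, not by
  the simulator.
* Winner's curse from selecting instruments in the same data that estimated
  them is present (as in most real QTL instruments) but not corrected.

# Numerical choices

* All posterior/Bayes-factor arithmetic is in log space (`logsumexp`,
  `logdiffexp`); posteriors remain exact when individual ABFs overflow.
* Deterministic tie-breaking everywhere a ranking occurs, so outputs are
  invariant to input row order.
* Two-sided p-values are computed as `2 * pnorm(-|z|)`; generated p-values
  are floored at `1e-300` to keep TSV round-trips lossless.
* Tables are written with `%.17g` so that write-then-read reproduces
  doubles bit for bit; the manifest records no timestamps, making reruns
  byte-identical.
* The bootstrap standard errors (`weighted_median`, `weighted_mode`) use a
  dedicated seed argument; no estimator touches the global RNG state except
  through documented seed parameters.

# Open questions and the positions taken

* **Palindromic variants**: dropped when frequency-ambiguous rather than
  strand-corrected by imputation; the 0.42 MAF limit is the conventional
  compromise between losing variants and allowing mis-strand errors.
* **Bonferroni `m`**: the number of markers tested in the window, not the
  number of rows supplied, and therefore a required argument.
* **Egger intercept reference distribution**: t with `k - 2` degrees of
  freedom (see above).
* **Weighted-median convention**: midpoint interpolation, which means the
  "majority-weight variant wins exactly" intuition holds only
  approximately; the tests encode the interpolated behavior.
* **Total `R^2` under residual LD**: summed per-variant, accepted as an
  overestimate and mitigated by clumping.
* **Steiger on binary outcomes**: observed-scale pseudo-correlation with
  the `cf(1-cf)` factor; liability-scale conversion is out of scope.

# Limitations

The estimator battery assumes independent instruments after clumping;
residual LD inflates precision. The decision rules are a fixed audit-able
policy, not an optimality claim. The PRESSO-style test needs at least four
variants and its simulations make it the slowest battery member. The
mediation stratification splits at an unadjusted `p <= 0.05` and small
strata can reduce to single-variant Wald cells with wide intervals.
Colocalization assumes at most one causal variant per trait in the window;
multiple causal variants can masquerade as H3. No empirical claim in this
vignette goes beyond what the test suite and `scripts/acceptance.R`
compute.
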