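# Ground-truth generator for LD-structured cis-region summary statistics.
#
# Summary statistics are drawn directly from the multivariate sampling
# distribution of marginal association estimators, without individual-level
# genotypes. On the standardized-genotype scale the marginal effect vector
# is R %*% gamma (R the LD correlation matrix, gamma the joint causal
# effects), and the estimator noise has covariance se^2 * R with
# se = 1/sqrt(n) for a standardized quantitative trait and
# se = 1/sqrt(n * cf * (1 - cf)) for a binary trait with case fraction cf
# (rare-disease log-odds approximation). Per-allele records divide by the
# genotype SD sqrt(2 * eaf * (1 - eaf)) (Hardy-Weinberg), which reproduces
# the familiar per-allele standard errors (2 n eaf (1 - eaf))^(-1/2).

#' Simulate a cis-region model
#'
#' Builds the variant grid (positions spanning the gene boundary +/- the
#' window, strictly increasing), effect-allele frequencies drawn uniformly
#' in \[0.05, 0.95\], and an autoregressive LD correlation structure
#' r(i, j) = ld_rho^|i - j| (positive definite by construction).
#'
#' @param m number of variants (>= 2).
#' @param gene [gene_region()]; default a DPP4-like 83 kb gene on chr2 with
#'   a 200 kb flank.
#' @param ld_rho adjacent-variant correlation, in \[0, 1).
#' @param seed RNG seed (deterministic: same seed, same region).
#' @return object of class `region_model`: list with `m`, `positions`,
#'   `variant_ids`, `eafs`, `ld` ([ld_reference()]), `chol` (upper Cholesky
#'   factor of the LD matrix), `gene`.
#' @export
simulate_region <- function(m = 60,
                            gene = gene_region("GENE1", "2", 162848755, 162931052, 200),
                            ld_rho = 0.8, seed = 1) {
  stopifnot(m >= 2, ld_rho >= 0, ld_rho < 1)
  win <- cis_window(gene)
  positions <- round(seq(win[1], win[2], length.out = m))
  variant_ids <- sprintf("rs%04d", seq_len(m))
  eafs <- with_seed(derive_seed(seed, "region_eaf"), stats::runif(m, 0.05, 0.95))
  r <- ld_rho^abs(outer(seq_len(m), seq_len(m), "-"))
  ld <- ld_reference(variant_ids, r)
  structure(list(m = m, positions = positions, variant_ids = variant_ids,
                 eafs = eafs, ld = ld, chol = chol(ld$r), gene = gene,
                 ld_rho = ld_rho, seed = seed),
            class = "region_model")
}

#' Generative ground truth for one simulated study
#'
#' All effects are on the standardized-genotype scale. `gamma` holds the
#' joint causal effects of variants on the exposure (per SD of the
#' exposure); `theta` is the causal effect of one SD of exposure on the
#' outcome log-odds; `pleiotropy` holds direct variant effects on the
#' outcome log-odds (horizontal pleiotropy, outlier effects, or - for
#' colocalization and reverse-causation scenarios - the outcome's own causal
#' effects). With `reverse = TRUE` the outcome's own effects (`pleiotropy`)
#' generate the outcome and the exposure inherits `theta` times the outcome
#' marginals (reverse causation). `mediator`, when present, is a list with
#' `mask` (logical, which exposure causal paths run through the mediator),
#' `b_em` (exposure -> mediator), `b_mo` (mediator -> outcome log-odds),
#' `own` (the mediator's own joint causal effects), `n_cases`, `n_controls`.
#'
#' @param m number of variants.
#' @param gamma joint exposure effects (length m).
#' @param theta causal effect of exposure on outcome log-odds.
#' @param pleiotropy direct outcome effects (length m; default none).
#' @param reverse reverse-causation flag.
#' @param shared_causal flag recorded for colocalization scenarios.
#' @param mediator optional mediator parameter list (see Details).
#' @param seed master seed recorded with the truth.
#' @return object of class `simulation_truth`.
#' @export
simulation_truth <- function(m, gamma = numeric(m), theta = 0,
                             pleiotropy = numeric(m), reverse = FALSE,
                             shared_causal = FALSE, mediator = NULL, seed = 1) {
  stopifnot(length(gamma) == m, length(pleiotropy) == m)
  if (theta != 0 && !reverse && all(gamma == 0)) {
    stop_targetmr("theta != 0 requires at least one causal exposure variant",
                  "targetmr_infeasible_truth")
  }
  if (reverse && all(pleiotropy == 0)) {
    stop_targetmr("reverse causation requires outcome causal effects",
                  "targetmr_infeasible_truth")
  }
  structure(list(m = m, gamma = gamma,
                 causal_exposure_idx = which(gamma != 0),
                 theta = theta, pleiotropy = pleiotropy, reverse = reverse,
                 shared_causal = shared_causal, mediator = mediator, seed = seed),
            class = "simulation_truth")
}

# One multivariate draw of marginal estimates on the standardized scale:
# mean mu, covariance se_std^2 * R, using the region's cached Cholesky factor.
draw_marginals <- function(region, mu, se_std, seed) {
  z <- with_seed(seed, stats::rnorm(region$m))
  as.numeric(mu + se_std * crossprod(region$chol, z))
}

# Convert standardized-scale draws to per-allele records.
records_from_std <- function(region, bhat_std, se_std, n, trait_id, trait_type,
                             n_cases = NA_real_, n_controls = NA_real_) {
  sdg <- sqrt(2 * region$eafs * (1 - region$eafs))
  beta <- bhat_std / sdg
  se <- se_std / sdg
  as_sumstats(data.frame(
    variant_id = region$variant_ids, chrom = region$gene$chrom,
    pos = region$positions, effect_allele = "A", other_allele = "G",
    eaf = region$eafs, beta = beta, se = se,
    pvalue = pmax(z_pvalue(beta, se), 1e-300), n = n,
    n_cases = n_cases, n_controls = n_controls,
    stringsAsFactors = FALSE
  ), trait_id = trait_id, trait_type = trait_type)
}

#' Simulate exposure, outcome, and optional mediator summary statistics
#'
#' Draws one replicate of marginal summary statistics for a quantitative
#' exposure, a binary outcome, and (when the truth carries mediator
#' parameters) a binary mediator, under the generative model in the package
#' notes: exposure marginals R gamma; outcome marginals
#' theta * (exposure marginals) + R pleiotropy (+ mediated path); noise with
#' the LD-induced covariance at the stated sample sizes.
#'
#' @param region [simulate_region()] output.
#' @param truth [simulation_truth()].
#' @param n_exposure exposure sample size.
#' @param n_cases,n_controls outcome case/control counts.
#' @param seed replicate seed (sub-streams are derived per dataset).
#' @param exposure_id,outcome_id,mediator_id trait labels.
#' @return list with `exposure`, `outcome`, optionally `mediator`
#'   (summary-statistics data.frames), and `truth`.
#' @export
simulate_sumstats <- function(region, truth, n_exposure = 30000,
                              n_cases = 10000, n_controls = 10000, seed = 1,
                              exposure_id = "exposure", outcome_id = "outcome",
                              mediator_id = "mediator") {
  stopifnot(inherits(region, "region_model"), inherits(truth, "simulation_truth"),
            n_exposure >= 100, n_cases + n_controls >= 100)
  R <- region$ld$r
  n_out <- n_cases + n_controls
  cf <- n_cases / n_out
  se_x <- 1 / sqrt(n_exposure)
  se_y <- 1 / sqrt(n_out * cf * (1 - cf))

  if (truth$reverse) {
    mu_y <- as.numeric(R %*% truth$pleiotropy)
    mu_x <- truth$theta * mu_y
  } else {
    mu_x <- as.numeric(R %*% truth$gamma)
    mu_y <- truth$theta * mu_x + as.numeric(R %*% truth$pleiotropy)
  }

  mediator <- NULL
  if (!is.null(truth$mediator)) {
    med <- truth$mediator
    gamma_med <- truth$gamma * as.numeric(med$mask)
    mu_m <- med$b_em * as.numeric(R %*% gamma_med) +
      as.numeric(R %*% (med$own %||% numeric(region$m)))
    mu_y <- mu_y + med$b_mo * mu_m
    n_med <- med$n_cases + med$n_controls
    cf_m <- med$n_cases / n_med
    se_m <- 1 / sqrt(n_med * cf_m * (1 - cf_m))
    bhat_m <- draw_marginals(region, mu_m, se_m, derive_seed(seed, "mediator"))
    mediator <- records_from_std(region, bhat_m, se_m, n_med, mediator_id,
                                 "binary", med$n_cases, med$n_controls)
  }

  bhat_x <- draw_marginals(region, mu_x, se_x, derive_seed(seed, "exposure"))
  bhat_y <- draw_marginals(region, mu_y, se_y, derive_seed(seed, "outcome"))

  out <- list(
    exposure = records_from_std(region, bhat_x, se_x, n_exposure,
                                exposure_id, "quantitative"),
    outcome = records_from_std(region, bhat_y, se_y, n_out, outcome_id,
                               "binary", n_cases, n_controls),
    truth = truth
  )
  if (!is.null(mediator)) out$mediator <- mediator
  out
}

SCENARIO_NAMES <- c("null", "causal", "pleiotropy", "outlier", "shared_coloc",
                    "distinct_coloc", "reverse", "mediation", "sex_specific")

# Scatter k causal indices evenly with seeded jitter so they are spread
# across the region but not on a fixed lattice.
spread_indices <- function(m, k, seed) {
  centers <- round(seq(m / (2 * k), m - m / (2 * k), length.out = k))
  jit <- with_seed(seed, sample(-1:1, k, replace = TRUE))
  pmin(pmax(centers + jit, 1), m)
}

#' Simulate one named study scenario
#'
#' Generates a region, a ground truth, and one replicate of summary
#' statistics for a named scenario. Defaults define the reference study
#' conditions used throughout the package's validation suite: a 60-variant
#' cis region with autoregressive LD (rho = 0.8), a quantitative exposure
#' measured in 30,000 samples, and a binary outcome with 10,000 cases and
#' 10,000 controls. Scenario-specific truths:
#'
#' * `null`: 8 causal exposure variants, theta = 0.
#' * `causal`: as `null` with theta = 0.3.
#' * `pleiotropy`: `causal` plus directional pleiotropy at the causal
#'   variants (direct outcome effects 0.005 +/- 0.002 on the standardized
#'   scale, oriented with the exposure-increasing allele).
#' * `outlier`: `causal` plus a single gross direct effect (0.09) at the
#'   strongest causal variant.
#' * `shared_coloc`: one shared causal variant driving both traits
#'   (exposure 0.15, outcome 0.10), theta = 0.
#' * `distinct_coloc`: exposure and outcome causal variants far apart
#'   (negligible LD), theta = 0.
#' * `reverse`: the outcome drives the exposure (theta = 0.5 applied in the
#'   reverse direction).
#' * `mediation`: theta = 0; four mediating and four non-mediating exposure
#'   causal variants in well-separated blocks, a binary mediator
#'   (80,154 / 853,816) with two additional own causal variants, paths
#'   b_em = 0.8, b_mo = 0.4.
#'
#' @param name scenario name (see Details).
#' @param seed replicate seed; region, truth draws, and noise all derive
#'   from it.
#' @param m,ld_rho region size and LD decay.
#' @param n_exposure,n_cases,n_controls sample sizes (overridable).
#' @param theta causal effect override (default per scenario).
#' @return list with `region`, `truth`, `exposure`, `outcome`, optionally
#'   `mediator`, and `spec` (the realized scenario parameters).
#' @export
simulate_scenario <- function(name = SCENARIO_NAMES, seed = 1, m = 60,
                              ld_rho = 0.8, n_exposure = 30000,
                              n_cases = 10000, n_controls = 10000,
                              theta = NULL) {
  name <- match.arg(name)
  if (name == "sex_specific") {
    stop_targetmr("the sex_specific scenario is generated by make_fixture_study()",
                  "targetmr_bad_scenario")
  }
  region <- simulate_region(m = m, ld_rho = ld_rho, seed = seed)
  gamma <- numeric(m)
  pleio <- numeric(m)
  mediator <- NULL
  reverse <- FALSE
  shared <- FALSE

  draw_gamma <- function(idx, lo = 0.03, hi = 0.08) {
    with_seed(derive_seed(seed, "gamma"), {
      stats::runif(length(idx), lo, hi) * sample(c(-1, 1), length(idx), replace = TRUE)
    })
  }

  if (name %in% c("null", "causal", "pleiotropy", "outlier")) {
    idx <- spread_indices(m, 8, derive_seed(seed, "idx"))
    gamma[idx] <- draw_gamma(idx)
    theta <- theta %||% if (name == "null") 0 else 0.3
    if (name == "pleiotropy") {
      pleio[idx] <- sign(gamma[idx]) *
        (0.005 + with_seed(derive_seed(seed, "pleio"), stats::rnorm(length(idx), 0, 0.002)))
    }
    if (name == "outlier") {
      j <- idx[which.max(abs(gamma[idx]))]
      pleio[j] <- 0.09 * sign(gamma[j])
    }
  } else if (name == "shared_coloc") {
    j <- m %/% 2
    gamma[j] <- 0.15
    pleio[j] <- 0.10
    theta <- theta %||% 0
    shared <- TRUE
    n_exposure <- if (missing(n_exposure)) 31684 else n_exposure
  } else if (name == "distinct_coloc") {
    gamma[max(1, m %/% 4)] <- 0.15
    pleio[min(m, (3 * m) %/% 4)] <- 0.10
    theta <- theta %||% 0
    n_exposure <- if (missing(n_exposure)) 31684 else n_exposure
  } else if (name == "reverse") {
    idx <- spread_indices(m, 4, derive_seed(seed, "idx"))
    pleio[idx] <- with_seed(derive_seed(seed, "gamma"), {
      stats::runif(length(idx), 0.08, 0.15) * sample(c(-1, 1), length(idx), replace = TRUE)
    })
    theta <- theta %||% 0.5
    reverse <- TRUE
  } else if (name == "mediation") {
    idx_med <- c(5, 9, 13, 17)
    idx_non <- c(43, 47, 51, 55)
    idx_med <- idx_med[idx_med <= m]; idx_non <- idx_non[idx_non <= m]
    idx <- c(idx_med, idx_non)
    gamma[idx] <- draw_gamma(idx)
    mask <- logical(m); mask[idx_med] <- TRUE
    own <- numeric(m); own[c(28, 32)[c(28, 32) <= m]] <- 0.05
    mediator <- list(mask = mask, b_em = 0.8, b_mo = 0.4, own = own,
                     n_cases = 80154, n_controls = 853816)
    theta <- theta %||% 0
  }

  truth <- simulation_truth(m, gamma = gamma, theta = theta, pleiotropy = pleio,
                            reverse = reverse, shared_causal = shared,
                            mediator = mediator, seed = seed)
  sim <- simulate_sumstats(region, truth, n_exposure = n_exposure,
                           n_cases = n_cases, n_controls = n_controls, seed = seed)
  c(list(region = region,
         spec = list(name = name, m = m, ld_rho = ld_rho,
                     n_exposure = n_exposure, n_cases = n_cases,
                     n_controls = n_controls, theta = theta, seed = seed)),
    sim)
}

#' Write a bundled synthetic fixture study to disk
#'
#' Generates a small complete study over one cis region: two exposure
#' sources (an eQTL-like blood-expression trait, n = 31,684, and a
#' pQTL-like plasma-protein trait, n = 34,557), three outcome strata with a
#' sex-specific causal effect (men theta = log(2.25), 12,054 / 11,999;
#' women theta = 0, 7,384 / 12,389; combined theta = log(1.78),
#' 37,688 / 981,372), and
#' a binary mediator (80,154 / 853,816) on which the exposure has a weak
#' effect (b_em = 0.12) but which itself has no effect on the outcome -
#' so the two-step mediation gate is exercised. All files use the package's
#' delimited formats; the truth parameters are recorded in a JSON manifest.
#'
#' @param seed master seed.
#' @param dir output directory (created if needed).
#' @return an `analysis_config` (see [analysis_config()]) whose record
#'   tables are also written under `dir`, with attribute `"truth"`.
#' @export
make_fixture_study <- function(seed = 1, dir = tempfile("fixture_study_")) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- 60
  region <- simulate_region(m = m, ld_rho = 0.8, seed = seed)
  R <- region$ld$r

  idx <- spread_indices(m, 8, derive_seed(seed, "idx"))
  gamma_e <- numeric(m)
  gamma_e[idx] <- with_seed(derive_seed(seed, "gamma_e"), {
    stats::runif(length(idx), 0.03, 0.08) * sample(c(-1, 1), length(idx), replace = TRUE)
  })
  # protein abundance sits downstream of expression: its QTL effects are
  # proportional (scaled up 1.25x, small regulatory jitter), so the pQTL
  # instrument recovers an attenuated causal estimate (theta / 1.25)
  gamma_p <- 1.25 * gamma_e
  gamma_p[idx] <- gamma_p[idx] +
    with_seed(derive_seed(seed, "gamma_p"), stats::rnorm(length(idx), 0, 0.003))

  mu_e <- as.numeric(R %*% gamma_e)
  mu_p <- as.numeric(R %*% gamma_p)

  n_eqtl <- 31684; n_pqtl <- 34557
  se_e <- 1 / sqrt(n_eqtl); se_p <- 1 / sqrt(n_pqtl)
  exposure_eqtl <- records_from_std(
    region, draw_marginals(region, mu_e, se_e, derive_seed(seed, "x_eqtl")),
    se_e, n_eqtl, "expression", "quantitative")
  exposure_pqtl <- records_from_std(
    region, draw_marginals(region, mu_p, se_p, derive_seed(seed, "x_pqtl")),
    se_p, n_pqtl, "protein", "quantitative")

  # stratum-specific causal effects chosen to match the magnitude of the
  # sex-specific pattern this fixture emulates: a strong effect in men
  # (OR 2.25 per SD expression), none in women, intermediate combined
  strata <- list(
    men = list(theta = log(2.25), n_cases = 12054, n_controls = 11999),
    women = list(theta = 0, n_cases = 7384, n_controls = 12389),
    all = list(theta = log(1.78), n_cases = 37688, n_controls = 981372)
  )
  # mediator: weak exposure->mediator path, no mediator->outcome path
  # (theta acts on the outcome directly, so the two-step gate must refuse)
  b_em <- 0.12
  mu_m <- b_em * mu_e
  med_cases <- 80154; med_controls <- 853816
  n_med <- med_cases + med_controls
  se_m <- 1 / sqrt(n_med * (med_cases / n_med) * (med_controls / n_med))
  mediator <- records_from_std(
    region, draw_marginals(region, mu_m, se_m, derive_seed(seed, "mediator")),
    se_m, n_med, "t2dm", "binary", med_cases, med_controls)

  outcomes <- lapply(names(strata), function(s) {
    st <- strata[[s]]
    n <- st$n_cases + st$n_controls
    cf <- st$n_cases / n
    se <- 1 / sqrt(n * cf * (1 - cf))
    mu <- st$theta * mu_e
    rec <- records_from_std(
      region, draw_marginals(region, mu, se, derive_seed(seed, paste0("y_", s))),
      se, n, paste0("pd_", s), "binary", st$n_cases, st$n_controls)
    list(name = paste0("pd_", s), stratum = s, records = rec,
         n_cases = st$n_cases, n_controls = st$n_controls)
  })
  names(outcomes) <- names(strata)

  write_results_table(exposure_eqtl, file.path(dir, "exposure_eqtl.tsv"))
  write_results_table(exposure_pqtl, file.path(dir, "exposure_pqtl.tsv"))
  for (s in names(outcomes)) {
    write_results_table(outcomes[[s]]$records, file.path(dir, paste0("outcome_", s, ".tsv")))
  }
  write_results_table(mediator, file.path(dir, "mediator_t2dm.tsv"))
  write_ld_reference(region$ld, file.path(dir, "ld.tsv"))

  truth <- list(seed = seed, m = m, ld_rho = 0.8,
                causal_idx = idx, gamma_eqtl = gamma_e, gamma_pqtl = gamma_p,
                theta = lapply(strata, `[[`, "theta"),
                mediator = list(b_em = b_em, b_mo = 0))
  write_run_metadata(list(kind = "synthetic fixture study", truth = truth),
                     file.path(dir, "manifest.json"))

  config <- analysis_config(
    gene = region$gene,
    exposure_sources = list(
      eQTL = list(records = exposure_eqtl, n = n_eqtl),
      pQTL = list(records = exposure_pqtl, n = n_pqtl)
    ),
    outcome_datasets = outcomes,
    mediator_dataset = list(name = "t2dm", records = mediator,
                            n_cases = med_cases, n_controls = med_controls),
    ld = region$ld,
    m_markers = m,
    seed = seed,
    dir = dir
  )
  attr(config, "truth") <- truth
  config
}
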