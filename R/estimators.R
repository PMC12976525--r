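# Two-sample MR estimator battery and diagnostics: Wald ratio, IVW,
# MR-Egger, weighted median, weighted mode, radial outlier removal,
# PRESSO-style global/per-SNP outlier test, Steiger directionality, and
# binary-outcome power.
#
# All estimators operate on harmonized pairs (see harmonize()) and report
# the causal effect of a 1-SD exposure increase on the outcome log-odds,
# alongside the exponentiated odds-ratio scale used for reporting.

mr_result <- function(method, estimate, se, nsnp, pvalue = z_pvalue(estimate, se)) {
  ci_low <- estimate - CI_Z * se
  ci_high <- estimate + CI_Z * se
  data.frame(method = method, estimate = estimate, se = se,
             ci_low = ci_low, ci_high = ci_high, pvalue = pvalue, nsnp = nsnp,
             or = exp(estimate), or_ci_low = exp(ci_low), or_ci_high = exp(ci_high),
             stringsAsFactors = FALSE)
}

# Canonical orientation: re-sign each pair so the exposure beta is positive
# (flipping the outcome beta with it). All estimators are invariant to the
# per-SNP joint sign flip; Egger requires this orientation explicitly.
orient_pairs <- function(pairs) {
  s <- sign(pairs$exposure_beta)
  s[s == 0] <- 1
  pairs$exposure_beta <- pairs$exposure_beta * s
  pairs$outcome_beta <- pairs$outcome_beta * s
  pairs
}

check_pairs <- function(pairs, min_n, caller) {
  if (is.null(pairs) || nrow(pairs) < min_n) {
    stop_targetmr(sprintf("%s requires at least %d SNPs (got %d)%s",
                          caller, min_n, if (is.null(pairs)) 0L else nrow(pairs),
                          if (min_n == 2) "; use wald_ratio for a single SNP" else ""),
                  "targetmr_too_few_snps")
  }
  if (any(pairs$exposure_beta == 0)) {
    stop_targetmr("null instrument: exposure beta of 0", "targetmr_null_instrument")
  }
  invisible(TRUE)
}

#' Wald ratio for a single-SNP instrument
#'
#' Estimate = outcome_beta / exposure_beta. The default standard error is
#' the first-order delta method |outcome_se / exposure_beta| (exposure-side
#' noise ignored); `second_order = TRUE` adds the exposure-noise term
#' sqrt(se_y^2/bx^2 + by^2 se_x^2 / bx^4).
#'
#' @param pair one harmonized row.
#' @param second_order include exposure-side noise in the se.
#' @return one-row MR result data.frame.
#' @export
wald_ratio <- function(pair, second_order = FALSE) {
  stopifnot(nrow(pair) == 1)
  if (pair$exposure_beta == 0) {
    stop_targetmr("null instrument: exposure beta of 0", "targetmr_null_instrument")
  }
  est <- pair$outcome_beta / pair$exposure_beta
  se <- if (second_order) {
    sqrt(pair$outcome_se^2 / pair$exposure_beta^2 +
           pair$outcome_beta^2 * pair$exposure_se^2 / pair$exposure_beta^4)
  } else {
    abs(pair$outcome_se / pair$exposure_beta)
  }
  mr_result("wald", est, se, 1L)
}

#' Inverse-variance-weighted estimate and Cochran's Q
#'
#' Weighted regression of the outcome betas on the exposure betas through
#' the origin with weights 1/se_y^2:
#' estimate = sum(bx * by / sy^2) / sum(bx^2 / sy^2). The fixed-effects se
#' is (sum bx^2/sy^2)^(-1/2); the default multiplicative random-effects
#' model scales it by sqrt(max(1, Q/(k-1))), never narrowing below
#' fixed-effects. Cochran's Q = sum w_i (ratio_i - estimate)^2 with
#' w_i = (bx_i/sy_i)^2, referred to chi-square(k-1).
#'
#' @param pairs harmonized pairs (>= 2 rows).
#' @param effects_model `"multiplicative_random"` (default) or `"fixed"`.
#' @return list with `result` (MR result row) and `heterogeneity`
#'   (data.frame with `q`, `df`, `pvalue`).
#' @export
ivw <- function(pairs, effects_model = c("multiplicative_random", "fixed")) {
  effects_model <- match.arg(effects_model)
  check_pairs(pairs, 2L, "ivw")
  bx <- pairs$exposure_beta; by <- pairs$outcome_beta; sy <- pairs$outcome_se
  w <- bx^2 / sy^2
  est <- sum(bx * by / sy^2) / sum(w)
  se_fixed <- 1 / sqrt(sum(w))
  k <- length(bx)
  q <- sum(w * (by / bx - est)^2)
  q_df <- k - 1L
  q_p <- stats::pchisq(q, q_df, lower.tail = FALSE)
  se <- if (effects_model == "multiplicative_random") {
    se_fixed * sqrt(max(1, q / q_df))
  } else se_fixed
  list(result = mr_result("ivw", est, se, k),
       heterogeneity = data.frame(q = q, df = q_df, pvalue = q_p))
}

#' MR-Egger regression
#'
#' Weighted linear fit of the outcome betas on the exposure betas with an
#' intercept (weights 1/se_y^2), after re-signing each pair so the exposure
#' beta is positive. The slope is the causal estimate; the intercept
#' estimates directional pleiotropy. The slope se uses multiplicative
#' random-effects scaling sqrt(max(1, Q_resid/(k-2))) as in [ivw()]. The
#' pleiotropy test refers intercept / (dispersion-scaled se) to a
#' t distribution with k-2 degrees of freedom — the exact reference
#' distribution for a weighted least-squares intercept with estimated
#' dispersion, keeping the test calibrated at small k.
#'
#' @param pairs harmonized pairs (>= 3 rows).
#' @param effects_model `"multiplicative_random"` (default) or `"fixed"`
#'   (slope/intercept reporting; the pleiotropy test always uses the
#'   dispersion-scaled t form).
#' @return list with `result` (slope MR result), `pleiotropy` (data.frame
#'   `intercept`, `se`, `pvalue`), and `heterogeneity` (residual Q on k-2 df).
#' @export
egger <- function(pairs, effects_model = c("multiplicative_random", "fixed")) {
  effects_model <- match.arg(effects_model)
  check_pairs(pairs, 3L, "egger")
  p <- orient_pairs(pairs)
  bx <- p$exposure_beta; by <- p$outcome_beta; w <- 1 / p$outcome_se^2
  k <- length(bx)

  sw <- sum(w); swx <- sum(w * bx); swy <- sum(w * by)
  sxx <- sum(w * bx^2); sxy <- sum(w * bx * by)
  denom <- sw * sxx - swx^2
  slope <- (sw * sxy - swx * swy) / denom
  intercept <- (swy - slope * swx) / sw
  # fixed-effects (known-variance) standard errors from (X'WX)^{-1}
  se_slope_fixed <- sqrt(sw / denom)
  se_int_fixed <- sqrt(sxx / denom)

  resid <- by - intercept - slope * bx
  q <- sum(w * resid^2)
  q_df <- k - 2L
  sigma2 <- q / q_df
  scale <- if (effects_model == "multiplicative_random") sqrt(max(1, sigma2)) else 1

  res <- mr_result("egger", slope, se_slope_fixed * scale, k)
  se_int_t <- se_int_fixed * sqrt(sigma2)
  pleio_p <- 2 * stats::pt(-abs(intercept / se_int_t), df = q_df)
  list(result = res,
       pleiotropy = data.frame(intercept = intercept, se = se_int_fixed * scale,
                               pvalue = pleio_p),
       heterogeneity = data.frame(q = q, df = q_df,
                                  pvalue = stats::pchisq(q, q_df, lower.tail = FALSE)))
}

ratio_weights <- function(pairs) {
  w <- (pairs$exposure_beta / pairs$outcome_se)^2
  w / sum(w)
}

weighted_percentile <- function(x, w, prob = 0.5) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord] / sum(w)
  cw <- cumsum(w) - w / 2
  if (prob <= cw[1]) return(x[1])
  if (prob >= cw[length(cw)]) return(x[length(x)])
  stats::approx(cw, x, xout = prob)$y
}

boot_se <- function(pairs, statistic, nboot, seed) {
  with_seed(seed, {
    k <- nrow(pairs)
    reps <- vapply(seq_len(nboot), function(b) {
      bs <- pairs
      bs$exposure_beta <- stats::rnorm(k, pairs$exposure_beta, pairs$exposure_se)
      bs$outcome_beta <- stats::rnorm(k, pairs$outcome_beta, pairs$outcome_se)
      statistic(bs)
    }, numeric(1))
    stats::sd(reps)
  })
}

#' Weighted-median MR estimate
#'
#' The weighted 50th percentile of the per-SNP Wald ratios with inverse
#' ratio-variance weights w_i = (bx_i/sy_i)^2 (normalized), interpolating
#' linearly across the cumulative-weight grid. The standard error comes
#' from a seeded parametric bootstrap resampling (bx, by) under their
#' stated standard errors.
#'
#' @param pairs harmonized pairs (>= 3 rows).
#' @param nboot bootstrap replicates (default 1000).
#' @param seed bootstrap seed.
#' @return one-row MR result data.frame.
#' @export
weighted_median <- function(pairs, nboot = 1000, seed = 1) {
  check_pairs(pairs, 3L, "weighted_median")
  stat <- function(p) weighted_percentile(p$outcome_beta / p$exposure_beta,
                                          ratio_weights(p))
  est <- stat(pairs)
  se <- boot_se(pairs, stat, nboot, seed)
  mr_result("weighted_median", est, se, nrow(pairs))
}

weighted_mode_point <- function(pairs, phi = 1) {
  r <- pairs$outcome_beta / pairs$exposure_beta
  w <- ratio_weights(pairs)
  if (max(r) - min(r) < 1e-12) return(r[1])
  # modified Silverman bandwidth on the weighted ratio spread
  s <- 0.9 * min(stats::sd(r), stats::mad(r)) / length(r)^(1 / 5)
  if (s <= 0) s <- stats::sd(r) / length(r)^(1 / 5)
  h <- max(phi * s, 1e-8)
  dens <- function(x) colSums(w * stats::dnorm(outer(r, x, "-") / h))
  pad <- 3 * h
  grid <- seq(min(r) - pad, max(r) + pad, length.out = 512)
  x0 <- grid[which.max(dens(grid))]
  span <- diff(range(grid)) / 511
  stats::optimize(function(x) dens(x), lower = x0 - 2 * span, upper = x0 + 2 * span,
                  maximum = TRUE)$maximum
}

#' Weighted-mode MR estimate
#'
#' The mode of a Gaussian-kernel weighted density over the per-SNP Wald
#' ratios (weights as in [weighted_median()]), with bandwidth
#' `phi` times a modified Silverman rule on the ratio spread. As the
#' bandwidth grows, the mode approaches the weighted mean. Standard error
#' by seeded parametric bootstrap.
#'
#' @param pairs harmonized pairs (>= 3 rows).
#' @param phi bandwidth multiplier (default 1).
#' @param nboot bootstrap replicates (default 1000).
#' @param seed bootstrap seed.
#' @return one-row MR result data.frame.
#' @export
weighted_mode <- function(pairs, phi = 1, nboot = 1000, seed = 1) {
  check_pairs(pairs, 3L, "weighted_mode")
  est <- weighted_mode_point(pairs, phi)
  se <- boot_se(pairs, function(p) weighted_mode_point(p, phi), nboot, seed)
  mr_result("weighted_mode", est, se, nrow(pairs))
}

#' Radial outlier detection and IVW refit
#'
#' Decomposes Cochran's Q into per-SNP contributions
#' Q_i = w_i (ratio_i - ivw)^2 and iteratively removes SNPs whose Q_i has an
#' upper-tail chi-square(1) p-value below `alpha` (default Bonferroni,
#' 0.05 / k), refitting after each pass until no SNP is flagged or only two
#' remain.
#'
#' @param pairs harmonized pairs (>= 3 rows).
#' @param alpha per-SNP flagging level; default `0.05 / nrow(pairs)`.
#' @return list with `outliers` (flagged variant ids, possibly empty),
#'   `result` (refit IVW MR result, method `"ivw_radial"`), `heterogeneity`
#'   (refit Q), and `q_contributions` (initial per-SNP Q_i).
#' @export
radial_outliers <- function(pairs, alpha = NULL) {
  check_pairs(pairs, 3L, "radial_outliers")
  if (is.null(alpha)) alpha <- 0.05 / nrow(pairs)
  flagged <- character(0)
  current <- pairs
  q_init <- NULL
  repeat {
    fit <- ivw(current)
    w <- (current$exposure_beta / current$outcome_se)^2
    qi <- w * (current$outcome_beta / current$exposure_beta - fit$result$estimate)^2
    if (is.null(q_init)) {
      q_init <- data.frame(variant_id = current$variant_id, q_i = qi,
                           pvalue = stats::pchisq(qi, 1, lower.tail = FALSE))
    }
    p_i <- stats::pchisq(qi, 1, lower.tail = FALSE)
    bad <- which(p_i < alpha)
    if (length(bad) == 0 || nrow(current) - length(bad) < 2) break
    flagged <- c(flagged, current$variant_id[bad])
    current <- current[-bad, , drop = FALSE]
    if (nrow(current) <= 2) break
  }
  fit <- ivw(current)
  fit$result$method <- "ivw_radial"
  list(outliers = flagged, result = fit$result,
       heterogeneity = fit$heterogeneity, q_contributions = q_init)
}

#' PRESSO-style global and per-SNP outlier test
#'
#' The observed residual sum of squares of leave-one-out IVW fits,
#' RSS = sum_i ((by_i - bx_i * est_(-i)) / sy_i)^2, is compared against
#' `nsim` parametric simulations drawn under the no-pleiotropy model
#' (by_i* ~ N(bx_i * est_(-i), sy_i)) to give a global p-value. Per-SNP
#' outlier p-values compare each observed squared residual to its simulated
#' distribution. When the global test is significant (p < 0.05), the
#' corrected estimate is the IVW fit after removing SNPs with per-SNP
#' p < 0.05; otherwise it equals the plain IVW fit.
#'
#' @param pairs harmonized pairs (>= 4 rows; fewer raises a classed
#'   `targetmr_too_few_snps` error so callers can fall back to
#'   [radial_outliers()]).
#' @param nsim parametric simulations (default 1000).
#' @param seed simulation seed.
#' @return list with `global_p`, `per_snp` (variant_id, pvalue), `outliers`,
#'   and `result` (corrected MR result, method `"presso_corrected"`).
#' @export
presso_like <- function(pairs, nsim = 1000, seed = 1) {
  check_pairs(pairs, 4L, "presso_like")
  bx <- pairs$exposure_beta; by <- pairs$outcome_beta; sy <- pairs$outcome_se
  k <- length(bx)
  w <- bx^2 / sy^2
  sxy <- sum(bx * by / sy^2); sxx <- sum(w)
  est_loo <- (sxy - bx * by / sy^2) / (sxx - w)   # leave-one-out IVW estimates
  resid_obs <- ((by - bx * est_loo) / sy)^2
  rss_obs <- sum(resid_obs)

  sims <- with_seed(seed, {
    matrix(stats::rnorm(nsim * k, mean = rep(bx * est_loo, each = nsim),
                        sd = rep(sy, each = nsim)), nrow = nsim)
  })
  # recompute the full leave-one-out RSS within each simulation
  sim_resid <- matrix(0, nsim, k)
  sxy_s <- as.numeric(sims %*% (bx / sy^2))
  for (j in seq_len(k)) {
    est_loo_s <- (sxy_s - sims[, j] * bx[j] / sy[j]^2) / (sxx - w[j])
    sim_resid[, j] <- ((sims[, j] - bx[j] * est_loo_s) / sy[j])^2
  }
  rss_sim <- rowSums(sim_resid)
  global_p <- (1 + sum(rss_sim >= rss_obs)) / (nsim + 1)
  per_snp_p <- vapply(seq_len(k), function(j) {
    (1 + sum(sim_resid[, j] >= resid_obs[j])) / (nsim + 1)
  }, numeric(1))

  outliers <- character(0)
  keep <- pairs
  if (global_p < 0.05) {
    bad <- which(per_snp_p < 0.05)
    if (length(bad) > 0 && k - length(bad) >= 2) {
      outliers <- pairs$variant_id[bad]
      keep <- pairs[-bad, , drop = FALSE]
    }
  }
  fit <- ivw(keep)
  fit$result$method <- "presso_corrected"
  list(global_p = global_p,
       per_snp = data.frame(variant_id = pairs$variant_id, pvalue = per_snp_p),
       outliers = outliers, result = fit$result)
}

#' Steiger directionality test
#'
#' Compares the exposure variance explained by the instrument,
#' sum 2 bx^2 eaf (1-eaf), with the outcome variance explained on the
#' observed log-odds scale, sum 2 by^2 eaf (1-eaf) * cf (1-cf) for a binary
#' outcome with case fraction cf (cf(1-cf) converts the log-odds effects to
#' the observed 0/1 scale; for a quantitative outcome the factor is 1).
#' The causal direction is called true when the exposure r^2 exceeds the
#' outcome r^2; the p-value is a two-sided Fisher-z test comparing the two
#' implied correlations at the two sample sizes.
#'
#' @param pairs harmonized pairs with non-missing eaf.
#' @param n_exposure exposure sample size.
#' @param n_outcome outcome sample size.
#' @param case_fraction outcome case fraction (NULL for quantitative).
#' @return data.frame with `r2_exposure`, `r2_outcome`, `direction_true`,
#'   `indeterminate`, `pvalue`.
#' @export
steiger <- function(pairs, n_exposure, n_outcome, case_fraction = NULL) {
  miss <- is.na(pairs$exposure_eaf)
  if (any(miss)) {
    stop_targetmr(paste0("missing eaf for variants: ",
                         paste(pairs$variant_id[miss], collapse = ", ")),
                  "targetmr_missing_eaf")
  }
  r2_exp <- sum(variance_explained(pairs$exposure_beta, pairs$exposure_eaf))
  vf <- if (is.null(case_fraction)) 1 else case_fraction * (1 - case_fraction)
  r2_out <- sum(variance_explained(pairs$outcome_beta, pairs$exposure_eaf)) * vf
  r_exp <- sqrt(min(r2_exp, 1 - 1e-12))
  r_out <- sqrt(min(r2_out, 1 - 1e-12))
  z <- (atanh(r_exp) - atanh(r_out)) /
    sqrt(1 / (n_exposure - 3) + 1 / (n_outcome - 3))
  data.frame(r2_exposure = r2_exp, r2_outcome = r2_out,
             direction_true = r2_exp > r2_out,
             indeterminate = r2_exp == r2_out,
             pvalue = 2 * stats::pnorm(-abs(z)))
}

#' Statistical power of an IVW analysis with a binary outcome
#'
#' Normal-approximation power of the two-sided test at level `alpha`, using
#' the asymptotic IVW standard error on the log-odds scale,
#' se = 1 / sqrt(n * cf * (1 - cf) * R^2), for a hypothesized odds ratio
#' `true_or` — the binary-outcome formulation of the standard MR power
#' calculator.
#'
#' @param n_outcome outcome sample size (cases + controls).
#' @param case_fraction proportion of cases, in (0,1).
#' @param total_r2 exposure variance explained by the instrument, in \[0,1).
#' @param true_or hypothesized causal odds ratio per SD of exposure.
#' @param alpha test level (default 0.05).
#' @return data.frame with the inputs and `power`.
#' @export
power_binary <- function(n_outcome, case_fraction, total_r2, true_or, alpha = 0.05) {
  stopifnot(case_fraction > 0, case_fraction < 1, total_r2 >= 0, total_r2 < 1)
  b <- log(true_or)
  se <- 1 / sqrt(n_outcome * case_fraction * (1 - case_fraction) * total_r2)
  zc <- stats::qnorm(1 - alpha / 2)
  power <- stats::pnorm(b / se - zc) + stats::pnorm(-b / se - zc)
  data.frame(alpha = alpha, n_outcome = n_outcome, case_fraction = case_fraction,
             total_r2 = total_r2, true_or = true_or, power = power)
}
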