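test_that("Wald ratio matches the delta-method arithmetic", {
  p <- make_pairs(bx = 0.5, by = 0.1, sy = 0.02)
  r <- wald_ratio(p)
  expect_equal(r$estimate, 0.2)
  expect_equal(r$se, 0.04)
  expect_equal(r$or, exp(0.2))
  expect_equal(r$or_ci_low, exp(0.2 - 1.96 * 0.04), tolerance = 1e-9)

  expect_equal(wald_ratio(make_pairs(0.5, 0, 0.02))$estimate, 0)
  # joint sign flip leaves the estimate unchanged
  r2 <- wald_ratio(make_pairs(-0.5, -0.1, 0.02))
  expect_equal(r2$estimate, r$estimate)
  expect_error(wald_ratio(make_pairs(0, 0.1, 0.02)),
               class = "targetmr_null_instrument")

  # second-order se adds exposure-side noise
  p3 <- make_pairs(0.5, 0.1, 0.02, sx = 0.1)
  expect_gt(wald_ratio(p3, second_order = TRUE)$se, wald_ratio(p3)$se)
})

test_that("IVW reproduces the closed-form two-SNP example", {
  p <- make_pairs(bx = c(1, 1), by = c(0.2, 0.4), sy = c(0.1, 0.1))
  fx <- ivw(p, effects_model = "fixed")
  expect_equal(fx$result$estimate, 0.3)
  expect_equal(fx$result$se, 1 / sqrt(200), tolerance = 1e-12)
  expect_equal(fx$heterogeneity$q, 2)
  re <- ivw(p)
  expect_equal(re$result$se, 0.1, tolerance = 1e-12)   # sqrt(Q/(k-1)) scaling

  # identical ratios: Q = 0, heterogeneity p = 1, RE = fixed
  p2 <- make_pairs(c(1, 2, 4), c(0.3, 0.6, 1.2), sy = c(0.1, 0.2, 0.1))
  f2 <- ivw(p2)
  expect_equal(f2$heterogeneity$q, 0, tolerance = 1e-20)
  expect_equal(f2$heterogeneity$pvalue, 1)
  expect_equal(f2$result$estimate, 0.3)

  expect_error(ivw(make_pairs(1, 0.2, 0.1)), class = "targetmr_too_few_snps")
})

test_that("IVW and Egger agree with the weighted-least-squares oracle", {
  set.seed(314)
  for (rep in 1:200) {
    k <- sample(3:15, 1)
    bx <- runif(k, 0.02, 0.2) * sample(c(-1, 1), k, TRUE)
    by <- 0.3 * bx + rnorm(k, 0, 0.05)
    sy <- runif(k, 0.01, 0.1)
    p <- make_pairs(bx, by, sy)

    fit <- ivw(p, effects_model = "fixed")
    orc <- wls_oracle(bx, by, sy, intercept = FALSE)
    expect_equal(fit$result$estimate, orc$slope, tolerance = 1e-10)
    expect_equal(fit$result$se, orc$slope_se_fixed, tolerance = 1e-10)
    expect_equal(fit$heterogeneity$q, orc$q, tolerance = 1e-10)

    op <- targetmr:::orient_pairs(p)
    eg <- egger(p, effects_model = "fixed")
    orc2 <- wls_oracle(op$exposure_beta, op$outcome_beta, sy, intercept = TRUE)
    expect_equal(eg$result$estimate, orc2$slope, tolerance = 1e-10)
    expect_equal(eg$result$se, orc2$slope_se_fixed, tolerance = 1e-10)
    expect_equal(eg$pleiotropy$intercept, orc2$intercept, tolerance = 1e-10)
    expect_equal(eg$heterogeneity$q, orc2$q, tolerance = 1e-10)
  }
})

test_that("Egger reproduces the exact collinear line fit", {
  p <- make_pairs(bx = c(1, 2, 3), by = c(0.2, 0.5, 0.8), sy = rep(0.1, 3))
  eg <- egger(p)
  expect_equal(eg$result$estimate, 0.3, tolerance = 1e-12)
  expect_equal(eg$pleiotropy$intercept, -0.1, tolerance = 1e-12)
  expect_equal(eg$heterogeneity$q, 0, tolerance = 1e-18)
  expect_error(egger(make_pairs(c(1, 2), c(0.1, 0.2), c(0.1, 0.1))),
               class = "targetmr_too_few_snps")
})

test_that("Egger intercept test is calibrated under the null", {
  # exact-weight simulation: the dispersion-scaled t test should reject at
  # the nominal rate
  set.seed(2024)
  k <- 10
  bx <- runif(k, 0.03, 0.1)
  sy <- rep(0.05, k)
  rej <- vapply(1:800, function(i) {
    by <- 0.2 * bx + rnorm(k, 0, sy)
    egger(make_pairs(bx, by, sy))$pleiotropy$pvalue < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.075)
})

test_that("weighted median interpolates the cumulative-weight grid", {
  p <- make_pairs(bx = c(1, 1, 1), by = c(0.1, 0.2, 0.3), sy = rep(1, 3))
  wm <- weighted_median(p, nboot = 100, seed = 1)
  expect_equal(wm$estimate, 0.2)

  # a SNP with ~all the weight dominates the median (interpolation keeps a
  # small residual pull from the light SNPs)
  p2 <- make_pairs(bx = c(10, 1, 1), by = c(9, 0.1, 0.2), sy = rep(1, 3))
  wm2 <- weighted_median(p2, nboot = 100, seed = 1)
  expect_lt(abs(wm2$estimate - 0.9), 0.02)

  # bootstrap se stabilizes across seeds at large nboot
  set.seed(5)
  p3 <- make_pairs(runif(8, 0.05, 0.15), rnorm(8, 0.03, 0.02), runif(8, 0.02, 0.05))
  a <- weighted_median(p3, nboot = 5000, seed = 1)$se
  b <- weighted_median(p3, nboot = 5000, seed = 2)$se
  expect_lt(abs(a - b) / a, 0.05)
})

test_that("weighted mode finds the dominant ratio cluster", {
  p <- make_pairs(bx = rep(1, 4), by = c(0.30, 0.31, 0.29, 0.90), sy = rep(0.05, 4))
  wm <- weighted_mode(p, nboot = 50, seed = 1)
  expect_gt(wm$estimate, 0.28)
  expect_lt(wm$estimate, 0.32)

  # all ratios identical: returns that value exactly
  pe <- make_pairs(c(1, 2, 5), c(0.4, 0.8, 2.0), sy = rep(0.1, 3))
  expect_equal(weighted_mode(pe, nboot = 50, seed = 1)$estimate, 0.4)

  # bandwidth -> infinity approaches the weighted mean
  set.seed(9)
  p3 <- make_pairs(runif(6, 0.5, 1.5), rnorm(6, 0.3, 0.3), runif(6, 0.05, 0.2))
  r <- p3$outcome_beta / p3$exposure_beta
  w <- (p3$exposure_beta / p3$outcome_se)^2
  wmean <- sum(w * r) / sum(w)
  est <- targetmr:::weighted_mode_point(p3, phi = 1e4)
  expect_equal(est, wmean, tolerance = 1e-4)
})

test_that("radial procedure flags a constructed outlier and decomposes Q", {
  bx <- rep(0.1, 10)
  sy <- rep(0.02, 10)
  by <- 0.3 * bx
  by[10] <- 0.3 * bx[10] + 5 * sy[10]   # ratio 5 se's away
  p <- make_pairs(bx, by, sy)
  rad <- radial_outliers(p)
  expect_equal(rad$outliers, "snp10")
  expect_lt(abs(rad$result$estimate - 0.3), 1e-10)

  # homogeneous instrument: no flags, refit equals the plain IVW
  set.seed(2)
  bxh <- runif(8, 0.05, 0.2)
  ph <- make_pairs(bxh, 0.3 * bxh + rnorm(8, 0, 0.01), rep(0.05, 8))
  radh <- radial_outliers(ph)
  expect_length(radh$outliers, 0)
  expect_equal(radh$result$estimate, ivw(ph)$result$estimate)

  # per-SNP Q contributions sum to Cochran's Q
  expect_equal(sum(rad$q_contributions$q_i), ivw(p)$heterogeneity$q,
               tolerance = 1e-10)
})

test_that("PRESSO-style test detects gross outliers and is quiet when clean", {
  bx <- rep(0.1, 10); sy <- rep(0.02, 10)
  by <- 0.3 * bx; by[4] <- 0.3 * bx[4] + 8 * sy[4]
  p <- make_pairs(bx, by, sy)
  pr <- presso_like(p, nsim = 500, seed = 3)
  expect_lt(pr$global_p, 0.05)
  expect_equal(pr$per_snp$variant_id[which.min(pr$per_snp$pvalue)], "snp04")
  expect_true("snp04" %in% pr$outliers)
  expect_lt(abs(pr$result$estimate - 0.3), 0.02)

  # clean instrument: corrected estimate equals plain IVW
  set.seed(4)
  bxc <- runif(8, 0.05, 0.2)
  pc <- make_pairs(bxc, 0.3 * bxc + rnorm(8, 0, 0.05), rep(0.05, 8))
  prc <- presso_like(pc, nsim = 300, seed = 5)
  if (length(prc$outliers) == 0) {
    expect_equal(prc$result$estimate, ivw(pc)$result$estimate)
  }
  expect_error(presso_like(make_pairs(1:3 / 10, 1:3 / 10, rep(0.1, 3))),
               class = "targetmr_too_few_snps")
})

test_that("PRESSO-style global p is roughly uniform under the null", {
  set.seed(77)
  k <- 10
  bx <- runif(k, 0.05, 0.15)
  sy <- rep(0.03, k)
  ps <- vapply(1:150, function(i) {
    by <- 0.2 * bx + rnorm(k, 0, sy)
    presso_like(make_pairs(bx, by, sy), nsim = 200, seed = i)$global_p
  }, numeric(1))
  expect_gt(mean(ps < 0.05), 0.005)
  expect_lt(mean(ps < 0.05), 0.12)
  expect_gt(mean(ps), 0.4)   # centred, not skewed toward 0
})

test_that("Steiger test compares explained variances with a case-fraction adjustment", {
  # r2_exposure 0.01 vs r2_outcome 1e-4 at large n: direction true, p < 0.001
  eaf <- 0.5
  bx <- sqrt(0.01 / (2 * eaf * (1 - eaf)))
  by <- sqrt(1e-4 / (2 * eaf * (1 - eaf)) / 0.25)   # cf = 0.5 adjustment
  p <- make_pairs(bx, by, 0.01, eaf = eaf)
  st <- steiger(p, n_exposure = 30000, n_outcome = 20000, case_fraction = 0.5)
  expect_equal(st$r2_exposure, 0.01)
  expect_equal(st$r2_outcome, 1e-4)
  expect_true(st$direction_true)
  expect_lt(st$pvalue, 0.001)

  # equal explained variance: indeterminate, p = 1 (quantitative outcome)
  p2 <- make_pairs(0.1, 0.1, 0.01, eaf = 0.3)
  st2 <- steiger(p2, 30000, 30000, case_fraction = NULL)
  expect_true(st2$indeterminate)
  expect_equal(st2$pvalue, 1)

  # swapping exposure and outcome inverts the direction call
  p3 <- make_pairs(0.2, 0.05, 0.01, eaf = 0.3)
  st3 <- steiger(p3, 30000, 30000, case_fraction = NULL)
  p3_swap <- p3
  p3_swap$exposure_beta <- p3$outcome_beta
  p3_swap$outcome_beta <- p3$exposure_beta
  st4 <- steiger(p3_swap, 30000, 30000, case_fraction = NULL)
  expect_true(st3$direction_true)
  expect_false(st4$direction_true)
  expect_equal(st3$pvalue, st4$pvalue)

  pm <- make_pairs(0.1, 0.05, 0.01, eaf = NA)
  expect_error(steiger(pm, 1000, 1000, 0.5), class = "targetmr_missing_eaf")
})

test_that("binary-outcome power has the right boundary and monotonicity", {
  expect_equal(power_binary(20000, 0.5, 0.02, 1)$power, 0.05, tolerance = 1e-12)
  base <- power_binary(20000, 0.5, 0.02, 1.3)$power
  expect_gt(power_binary(40000, 0.5, 0.02, 1.3)$power, base)
  expect_gt(power_binary(20000, 0.5, 0.04, 1.3)$power, base)
  expect_gt(power_binary(20000, 0.5, 0.02, 1.5)$power, base)
  expect_equal(power_binary(20000, 0.5, 0.02, 1 / 1.3)$power, base,
               tolerance = 1e-12)
})

test_that("estimators are invariant to per-SNP joint sign flips", {
  set.seed(12)
  bxs <- runif(8, 0.05, 0.2)
  p <- make_pairs(bxs, 0.3 * bxs + rnorm(8, 0, 0.02), runif(8, 0.02, 0.06))
  flip <- sample(c(-1, 1), 8, replace = TRUE)
  pf <- p
  pf$exposure_beta <- p$exposure_beta * flip
  pf$outcome_beta <- p$outcome_beta * flip
  expect_equal(ivw(pf)$result$estimate, ivw(p)$result$estimate, tolerance = 1e-12)
  expect_equal(egger(pf)$result$estimate, egger(p)$result$estimate, tolerance = 1e-12)
  expect_equal(weighted_median(pf, nboot = 10, seed = 1)$estimate,
               weighted_median(p, nboot = 10, seed = 1)$estimate, tolerance = 1e-12)
  expect_equal(targetmr:::weighted_mode_point(pf), targetmr:::weighted_mode_point(p),
               tolerance = 1e-9)
})

test_that("IVW, Egger, and weighted median agree under clean simulation", {
  set.seed(3001)
  k <- 30
  bx <- runif(k, 0.05, 0.2)
  sy <- rep(0.01, k)
  by <- 0.25 * bx + rnorm(k, 0, sy)
  p <- make_pairs(bx, by, sy)
  fits <- list(ivw(p)$result, egger(p)$result,
               weighted_median(p, nboot = 50, seed = 1))
  # each estimator recovers the truth within 3 of its own standard errors;
  # the flat-tolerance version of this check ignores that Egger's sampling
  # variance is several times IVW's
  for (f in fits) expect_lt(abs(f$estimate - 0.25), 3 * f$se)
  # the precise estimators (IVW, weighted median) are also tight in absolute
  # terms at this noise level
  expect_lt(abs(fits[[1]]$estimate - 0.25), 0.02)
  expect_lt(abs(fits[[3]]$estimate - 0.25), 0.02)
})
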