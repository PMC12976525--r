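test_that("cis-window selection respects boundaries and the Bonferroni rule", {
  region <- gene_region("G1", "1", 1000000, 1020000, window_kb = 200)
  rec <- make_records(c("in_edge", "out_edge", "weak"),
                      beta = c(0.1, 0.1, 0.1), se = 0.01,
                      pos = c(800000, 799999, 810000),
                      pvalue = c(1e-8, 1e-8, 6e-5))
  sel <- select_cis_significant(rec, region, alpha_family = 0.05, m = 1000)
  expect_equal(attr(sel, "threshold"), 5e-5)
  expect_true("in_edge" %in% sel$variant_id)     # pos 800000 = start - window
  expect_false("out_edge" %in% sel$variant_id)   # one base outside
  expect_false("weak" %in% sel$variant_id)       # p = 6e-5 > 5e-5

  # all non-significant: typed empty-result signal
  rec2 <- make_records("rs1", beta = 0.01, se = 0.01, pos = 1010000, pvalue = 0.5)
  expect_warning(sel2 <- select_cis_significant(rec2, region, m = 10),
                 class = "targetmr_no_significant_cis_qtl")
  expect_equal(nrow(sel2), 0)

  # Bonferroni m is a required explicit input
  expect_error(select_cis_significant(rec, region), class = "targetmr_missing_m")

  # fixed-threshold policy (tissue-style instruments)
  sel3 <- select_cis_significant(rec, region, policy = "fixed", fixed_p = 1e-5)
  expect_equal(attr(sel3, "threshold"), 1e-5)
  expect_setequal(sel3$variant_id, "in_edge")
})

test_that("greedy clumping follows the hand-traced keep set", {
  r <- diag(3)
  r[1, 2] <- r[2, 1] <- sqrt(0.5)
  r[1, 3] <- r[3, 1] <- sqrt(0.05)
  r[2, 3] <- r[3, 2] <- sqrt(0.04)
  ld <- ld_reference(c("SNP1", "SNP2", "SNP3"), r)
  rec <- make_records(c("SNP1", "SNP2", "SNP3"), beta = 0.1, se = 0.01,
                      pvalue = c(1e-10, 1e-8, 1e-6))
  kept <- ld_clump(rec, ld, 0.1)
  expect_equal(kept$variant_id, c("SNP1", "SNP3"))

  # zero LD: everything kept
  ld0 <- ld_reference(c("SNP1", "SNP2", "SNP3"), diag(3))
  expect_equal(nrow(ld_clump(rec, ld0, 0.1)), 3)

  # tie broken lexicographically by variant id
  rec_tie <- make_records(c("SNPb", "SNPa"), beta = 0.1, se = 0.01,
                          pvalue = c(1e-8, 1e-8))
  r2 <- matrix(c(1, 0.9, 0.9, 1), 2)
  ld2 <- ld_reference(c("SNPb", "SNPa"), r2)
  expect_equal(ld_clump(rec_tie, ld2, 0.1)$variant_id, "SNPa")
})

test_that("clumping is invariant to input row order and enforces pairwise r2", {
  set.seed(7)
  for (rep in 1:10) {
    m <- 25
    rho <- runif(1, 0.3, 0.95)
    r <- rho^abs(outer(1:m, 1:m, "-"))
    ids <- sprintf("rs%03d", 1:m)
    ld <- ld_reference(ids, r)
    rec <- make_records(ids, beta = rnorm(m, 0, 0.05), se = 0.01,
                        pvalue = runif(m, 1e-12, 1e-3))
    kept <- ld_clump(rec, ld, 0.1)
    shuffled <- rec[sample(m), ]
    kept2 <- ld_clump(shuffled, ld, 0.1)
    expect_equal(kept$variant_id, kept2$variant_id)
    sub <- ld$r[kept$variant_id, kept$variant_id]^2
    expect_true(all(sub[upper.tri(sub)] < 0.1))
  }
})

test_that("nsnp is monotone nonincreasing as the clump threshold tightens", {
  for (s in 1:5) {
    sc <- simulate_scenario("causal", seed = s)
    sel <- suppressWarnings(select_cis_significant(sc$exposure, sc$region$gene,
                                                   m = sc$region$m))
    ks <- vapply(c(0.3, 0.2, 0.1, 0.05, 0.01),
                 function(g) nrow(ld_clump(sel, sc$region$ld, g)), numeric(1))
    expect_true(all(diff(ks) <= 0))
  }
})

test_that("variance explained follows 2 b^2 p (1-p) and peaks at eaf 0.5", {
  expect_equal(variance_explained(0, 0.3), 0)
  expect_equal(variance_explained(0.2, 0), 0)
  expect_equal(variance_explained(0.2, 1), 0)
  expect_equal(variance_explained(0.1, 0.5), 0.005)
  eafs <- seq(0.01, 0.99, by = 0.01)
  v <- variance_explained(0.3, eafs)
  expect_equal(eafs[which.max(v)], 0.5)
  expect_true(all(v <= 0.5 * 0.3^2 + 1e-15))
})

test_that("F statistic matches the closed form and flags weak instruments", {
  f <- f_statistic(0.005, 31684, 1)
  expect_equal(as.numeric(f), (31684 - 1 - 1) / 1 * 0.005 / 0.995)
  expect_equal(round(as.numeric(f), 1), 159.2)
  expect_false(attr(f, "weak_instrument"))

  f0 <- f_statistic(0, 1000, 5)
  expect_equal(as.numeric(f0), 0)
  expect_true(attr(f0, "weak_instrument"))

  # doubling k at fixed R2 and n strictly decreases F
  expect_lt(as.numeric(f_statistic(0.01, 10000, 10)),
            as.numeric(f_statistic(0.01, 10000, 5)))
  expect_error(f_statistic(1, 1000, 1), class = "targetmr_bad_r2")

  # random-grid agreement with an independent evaluation
  set.seed(11)
  for (i in 1:50) {
    r2 <- runif(1, 0, 0.5); n <- sample(1000:100000, 1); k <- sample(1:20, 1)
    expect_equal(as.numeric(f_statistic(r2, n, k)),
                 ((n - k - 1) / k) * (r2 / (1 - r2)), tolerance = 1e-12)
  }
})

test_that("variants absent from the LD reference are dropped before clumping", {
  ld <- ld_reference(c("rs1", "rs2"), diag(2))
  rec <- make_records(c("rs1", "rs2", "rs3"), beta = 0.1, se = 0.01,
                      pvalue = c(1e-9, 1e-8, 1e-7))
  expect_message(kept <- ld_clump(rec, ld, 0.1), "absent from the LD reference")
  expect_setequal(kept$variant_id, c("rs1", "rs2"))
})

test_that("build_instrument assembles pairs, R2, and F consistently", {
  x <- scenario_instrument("causal", seed = 5)
  inst <- x$inst
  expect_s3_class(inst, "instrument_set")
  expect_gt(nrow(inst$pairs), 1)
  win <- cis_window(inst$gene)
  expect_true(all(inst$pairs$pos >= win[1] & inst$pairs$pos <= win[2]))
  expect_true(all(inst$pairs$exposure_pvalue < inst$significance_alpha))
  sub <- x$sc$region$ld$r[inst$pairs$variant_id, inst$pairs$variant_id]^2
  expect_true(all(sub[upper.tri(sub)] < inst$clump_r2))
  expect_equal(inst$total_r2, sum(inst$per_snp_r2))
  expect_equal(inst$f_statistic,
               as.numeric(f_statistic(inst$total_r2, 30000, nrow(inst$pairs))))
})
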