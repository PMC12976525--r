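test_that("delimited reader parses well-formed tables and rejects bad rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(
    rsid = c("rs1", "rs2", "rs3"), chr = "2", bp = c(100, 200, 300),
    ea = c("A", "C", "G"), nea = c("G", "T", "A"), freq = c(0.2, 0.5, 0.8),
    b = c(0.1, -0.05, 0.02), se = c(0.01, 0.02, 0.01),
    p = 2 * stats::pnorm(-abs(c(0.1, -0.05, 0.02) / c(0.01, 0.02, 0.01))),
    N = 1000
  )
  data.table::fwrite(df, path, sep = "\t")
  cmap <- c(variant_id = "rsid", chrom = "chr", pos = "bp",
            effect_allele = "ea", other_allele = "nea", eaf = "freq",
            beta = "b", se = "se", pvalue = "p", n = "N")
  rec <- read_sumstats(path, cmap, trait_id = "x")
  expect_equal(nrow(rec), 3)
  expect_equal(nrow(attr(rec, "rejects")), 0)
  expect_equal(rec$variant_id, c("rs1", "rs2", "rs3"))
  expect_equal(rec$beta, df$b)

  # se = 0 violates the record invariant: row rejected and counted
  df2 <- df; df2$se[2] <- 0
  data.table::fwrite(df2, path, sep = "\t")
  rec2 <- suppressMessages(read_sumstats(path, cmap, trait_id = "x"))
  expect_equal(nrow(rec2), 2)
  rej <- attr(rec2, "rejects")
  expect_equal(nrow(rej), 1)
  expect_match(rej$reason, "se")

  # unmapped eaf: records carry missing eaf
  cmap_noeaf <- cmap[names(cmap) != "eaf"]
  df3 <- df[, setdiff(names(df), "freq")]
  data.table::fwrite(df3, path, sep = "\t")
  rec3 <- read_sumstats(path, cmap_noeaf, trait_id = "x")
  expect_true(all(is.na(rec3$eaf)))

  # missing mapped column is a hard error
  expect_error(read_sumstats(path, c(cmap_noeaf, eaf = "freq"), trait_id = "x"),
               class = "targetmr_missing_column")
})

test_that("missing eaf forces palindromic variants to be dropped downstream", {
  ex <- make_records(c("rs1", "rs2"), beta = c(0.1, 0.1), se = 0.01,
                     eaf = c(NA, NA), ea = c("A", "A"), oa = c("T", "G"))
  ou <- make_records(c("rs1", "rs2"), beta = c(0.05, 0.05), se = 0.01,
                     eaf = c(NA, NA), ea = c("A", "A"), oa = c("T", "G"))
  h <- harmonize(ex, ou)
  expect_equal(h$action[h$variant_id == "rs1"], "dropped_palindromic")
  expect_equal(h$action[h$variant_id == "rs2"], "aligned")
})

test_that("allele swap flips the outcome beta and complements its eaf", {
  ex <- make_records("rs1", beta = 0.10, se = 0.01, eaf = 0.30,
                     ea = "A", oa = "G")
  ou <- make_records("rs1", beta = 0.05, se = 0.01, eaf = 0.70,
                     ea = "G", oa = "A")
  h <- harmonize(ex, ou)
  expect_equal(h$action, "flipped")
  expect_equal(h$outcome_beta, -0.05)
  expect_equal(h$outcome_eaf, 0.30)

  # strand-flipped representation of the same orientation stays aligned
  ou2 <- make_records("rs1", beta = 0.05, se = 0.01, eaf = 0.30,
                      ea = "T", oa = "C")
  h2 <- harmonize(ex, ou2)
  expect_equal(h2$action, "aligned")
  expect_equal(h2$outcome_beta, 0.05)
})

test_that("palindromic handling follows the eaf-agreement rule", {
  # eaf exactly 0.5: strand cannot be inferred, dropped
  ex <- make_records("rs1", beta = 0.1, se = 0.01, eaf = 0.50, ea = "A", oa = "T")
  ou <- make_records("rs1", beta = 0.1, se = 0.01, eaf = 0.30, ea = "A", oa = "T")
  expect_equal(harmonize(ex, ou)$action, "dropped_palindromic")

  # both minor and on the same side of 0.5: kept
  ex2 <- make_records("rs1", beta = 0.1, se = 0.01, eaf = 0.20, ea = "C", oa = "G")
  ou2 <- make_records("rs1", beta = 0.1, se = 0.01, eaf = 0.25, ea = "C", oa = "G")
  expect_equal(harmonize(ex2, ou2)$action, "aligned")

  # frequencies on opposite sides: ambiguous, dropped
  ou3 <- make_records("rs1", beta = 0.1, se = 0.01, eaf = 0.75, ea = "C", oa = "G")
  expect_equal(harmonize(ex2, ou3)$action, "dropped_palindromic")

  # common palindrome (maf above the limit): dropped even when sides agree
  ex4 <- make_records("rs1", beta = 0.1, se = 0.01, eaf = 0.45, ea = "A", oa = "T")
  ou4 <- make_records("rs1", beta = 0.1, se = 0.01, eaf = 0.44, ea = "A", oa = "T")
  expect_equal(harmonize(ex4, ou4)$action, "dropped_palindromic")
})

test_that("harmonization is idempotent on surviving rows and an involution", {
  ex <- make_records(c("rs1", "rs2", "rs3"), beta = c(0.1, -0.2, 0.05),
                     se = 0.01, eaf = c(0.2, 0.6, 0.4),
                     ea = c("A", "C", "G"), oa = c("G", "T", "A"))
  ou <- make_records(c("rs1", "rs2", "rs3"), beta = c(0.05, 0.08, -0.01),
                     se = 0.02, eaf = c(0.8, 0.6, 0.4),
                     ea = c("G", "C", "G"), oa = c("A", "T", "A"))
  h1 <- harmonized_kept(harmonize(ex, ou))
  # rebuild the outcome from the harmonized orientation and harmonize again
  ou2 <- make_records(h1$variant_id, beta = h1$outcome_beta, se = h1$outcome_se,
                      eaf = h1$outcome_eaf, ea = h1$effect_allele,
                      oa = h1$other_allele)
  h2 <- harmonized_kept(harmonize(ex, ou2))
  expect_equal(h2$outcome_beta, h1$outcome_beta)
  expect_equal(h2$outcome_eaf, h1$outcome_eaf)
  expect_true(all(h2$action == "aligned"))

  # involution: flipping alleles twice restores the original record
  flipped_once <- harmonize(ex, ou)
  rs1 <- flipped_once[flipped_once$variant_id == "rs1", ]
  expect_equal(rs1$action, "flipped")
  reflip_beta <- -rs1$outcome_beta
  reflip_eaf <- 1 - rs1$outcome_eaf
  expect_equal(reflip_beta, ou$beta[ou$variant_id == "rs1"])
  expect_equal(reflip_eaf, ou$eaf[ou$variant_id == "rs1"])
})

test_that("no surviving pair has incompatible alleles (fuzzed)", {
  set.seed(42)
  bases <- c("A", "C", "G", "T")
  for (rep in 1:30) {
    k <- 20
    ea_x <- sample(bases, k, replace = TRUE)
    oa_x <- vapply(ea_x, function(a) sample(setdiff(bases, a), 1), "")
    ea_y <- sample(bases, k, replace = TRUE)
    oa_y <- vapply(ea_y, function(a) sample(setdiff(bases, a), 1), "")
    ex <- make_records(sprintf("rs%d", 1:k), beta = rnorm(k, 0, 0.1), se = 0.01,
                       eaf = runif(k, 0.05, 0.95), ea = ea_x, oa = oa_x)
    ou <- make_records(sprintf("rs%d", 1:k), beta = rnorm(k, 0, 0.1), se = 0.01,
                       eaf = runif(k, 0.05, 0.95), ea = ea_y, oa = oa_y)
    h <- harmonize(ex, ou)
    kept <- harmonized_kept(h)
    for (i in seq_len(nrow(kept))) {
      id <- kept$variant_id[i]
      pair_x <- c(ea_x[match(id, ex$variant_id)], oa_x[match(id, ex$variant_id)])
      pair_y <- c(ea_y[match(id, ou$variant_id)], oa_y[match(id, ou$variant_id)])
      comp <- unname(c(T = "A", A = "T", C = "G", G = "C")[pair_y])
      expect_true(setequal(pair_x, pair_y) || setequal(pair_x, comp))
    }
  }
})

test_that("zero shared variants is a hard error", {
  ex <- make_records("rs1", beta = 0.1, se = 0.01)
  ou <- make_records("rs2", beta = 0.1, se = 0.01)
  expect_error(harmonize(ex, ou), class = "targetmr_no_overlap")
})

test_that("results tables round-trip losslessly", {
  path <- withr::local_tempfile(fileext = ".tsv")
  res <- rbind(
    targetmr:::mr_result("ivw", 0.3141592653589793, 0.07071067811865475, 5L),
    targetmr:::mr_result("egger", -1.234567890123456e-3, 2.2e-16, 9L)
  )
  write_results_table(res, path)
  back <- read_results_table(path)
  for (cl in names(res)) {
    if (is.numeric(res[[cl]])) {
      expect_true(all(abs(back[[cl]] - res[[cl]]) <=
                        1e-12 * pmax(abs(res[[cl]]), 1e-300)))
    } else {
      expect_equal(as.character(back[[cl]]), as.character(res[[cl]]))
    }
  }

  # empty set: header-only file
  write_results_table(res[0, ], path)
  expect_equal(length(readLines(path)), 1L)
  expect_equal(nrow(read_results_table(path)), 0L)

  # bulk round-trip preserves row count and values
  big <- data.frame(id = sprintf("v%05d", 1:10000),
                    x = rnorm(10000), p = 10^runif(10000, -300, 0))
  write_results_table(big, path)
  back <- read_results_table(path)
  expect_equal(nrow(back), 10000L)
  expect_true(all(abs(back$p - big$p) <= 1e-12 * big$p))
})

test_that("pvalue/z consistency check warns on mis-parsed columns", {
  df <- data.frame(variant_id = sprintf("rs%d", 1:20), chrom = "1",
                   pos = 1:20, effect_allele = "A", other_allele = "G",
                   eaf = 0.3, beta = 0.5, se = 0.05,
                   pvalue = rep(0.5, 20), n = 1000)
  expect_warning(as_sumstats(df), class = "targetmr_pvalue_inconsistent")
})
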