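# Instrument construction for a drug-target gene: cis filtering,
# significance selection, greedy LD clumping, and instrument-strength
# metrics (per-SNP variance explained and the F statistic).

#' Select significant cis variants for a gene region
#'
#' Keeps variants inside the cis window (gene boundary +/- flank, inclusive)
#' whose p-value passes the significance rule. The default rule is the
#' Bonferroni family correction p < alpha_family / m, where `m` is the
#' number of markers tested; `m` must be supplied explicitly (conventionally
#' the number of markers tested within the cis window for the trait). A
#' `"fixed"` policy with a plain threshold (default 1e-5, as used for
#' tissue-level eQTL instruments) is also available.
#'
#' @param records exposure summary statistics ([as_sumstats()]).
#' @param region [gene_region()].
#' @param alpha_family nominal family-wise level (default 0.05).
#' @param m number of markers tested (required for the Bonferroni policy).
#' @param policy `"bonferroni"` or `"fixed"`.
#' @param fixed_p plain per-marker threshold for the `"fixed"` policy.
#' @return filtered records with attributes `m`, `threshold`, `window`.
#'   When no variant passes, a zero-row table is returned and a classed
#'   warning `targetmr_no_significant_cis_qtl` is signalled so pipelines can
#'   continue with other instrument sources.
#' @export
select_cis_significant <- function(records, region, alpha_family = 0.05, m = NULL,
                                   policy = c("bonferroni", "fixed"),
                                   fixed_p = 1e-5) {
  policy <- match.arg(policy)
  if (policy == "bonferroni") {
    if (is.null(m)) {
      stop_targetmr("m (number of markers tested) must be supplied explicitly for the Bonferroni policy",
                    "targetmr_missing_m")
    }
    stopifnot(m >= 1)
    threshold <- alpha_family / m
  } else {
    threshold <- fixed_p
  }
  win <- cis_window(region)
  keep <- records$chrom == region$chrom &
    records$pos >= win[1] & records$pos <= win[2] &
    records$pvalue < threshold
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "m") <- m
  attr(out, "threshold") <- threshold
  attr(out, "window") <- win
  if (nrow(out) == 0) {
    warn_targetmr(sprintf("no significant cis-QTL for %s at p < %.3g",
                          region$gene_id, threshold),
                  "targetmr_no_significant_cis_qtl")
  }
  out
}

#' Greedy LD clumping
#'
#' Repeatedly takes the remaining variant with the smallest p-value
#' (ties broken by variant id, lexicographically) and discards every
#' remaining variant with squared correlation >= `r2_threshold` against it.
#' The output is ordered by p-value and its pairwise r^2 values are all
#' below the threshold. Variants absent from the LD reference are dropped
#' beforehand (with a message).
#'
#' @param records significance-filtered summary statistics.
#' @param ld [ld_reference()] covering the region.
#' @param r2_threshold squared-correlation cutoff in (0,1); default 0.1.
#'   The conventional sensitivity grid is r^2 < 0.3, 0.2, 0.1, 0.05, 0.01.
#' @return clumped records (ordered by p-value then variant id).
#' @export
ld_clump <- function(records, ld, r2_threshold = 0.1) {
  stopifnot(inherits(ld, "ld_reference"), r2_threshold > 0, r2_threshold < 1)
  if (nrow(records) == 0) return(records)
  known <- records$variant_id %in% ld$variant_ids
  if (any(!known)) {
    message(sprintf("ld_clump: dropping %d variant(s) absent from the LD reference",
                    sum(!known)))
    records <- records[known, , drop = FALSE]
  }
  if (nrow(records) == 0) return(records)
  ord <- order(records$pvalue, records$variant_id)
  records <- records[ord, , drop = FALSE]
  r2 <- ld$r[records$variant_id, records$variant_id, drop = FALSE]^2
  keep <- logical(nrow(records))
  alive <- rep(TRUE, nrow(records))
  for (i in seq_len(nrow(records))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive <- alive & (r2[i, ] < r2_threshold)
    alive[i] <- FALSE
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Variance in a standardized trait explained by one variant
#'
#' For a per-allele effect `beta` on a unit-variance trait and effect-allele
#' frequency `eaf` (Hardy-Weinberg), the explained variance is
#' 2 * beta^2 * eaf * (1 - eaf).
#'
#' @param beta per-allele effect (per SD of the trait).
#' @param eaf effect-allele frequency in \[0,1\] (NA propagates).
#' @return explained variance, in \[0, 0.5 * beta^2\]. Vectorized.
#' @export
variance_explained <- function(beta, eaf) {
  stopifnot(all(is.na(eaf) | (eaf >= 0 & eaf <= 1)))
  2 * beta^2 * eaf * (1 - eaf)
}

#' Instrument-strength F statistic
#'
#' F = \[(N - K - 1) / K\] * \[R^2 / (1 - R^2)\] for an instrument of K
#' variants jointly explaining R^2 of the exposure in a sample of size N.
#' F < 10 conventionally indicates a weak instrument.
#'
#' @param total_r2 summed per-SNP explained variance, in \[0, 1).
#' @param n exposure sample size (> k + 1).
#' @param k number of variants in the instrument (>= 1).
#' @return F value with attribute `weak_instrument` (TRUE when F < 10).
#' @export
f_statistic <- function(total_r2, n, k) {
  if (any(total_r2 >= 1)) stop_targetmr("total_r2 must be < 1", "targetmr_bad_r2")
  stopifnot(total_r2 >= 0, k >= 1, n > k + 1)
  f <- ((n - k - 1) / k) * (total_r2 / (1 - total_r2))
  attr(f, "weak_instrument") <- f < 10
  f
}

#' Build a harmonized instrument set for one exposure source
#'
#' Runs the full instrument construction chain: cis + significance
#' selection, LD clumping, harmonization against the outcome, and
#' instrument-strength metrics. Per-SNP R^2 uses the exposure beta and eaf
#' (variants with missing eaf are excluded from R^2 and F, with a count
#' recorded); instrument-level R^2 is the sum of per-SNP R^2 over the
#' clumped variants.
#'
#' @param exposure,outcome summary-statistics tables.
#' @param region [gene_region()].
#' @param ld [ld_reference()].
#' @param m number of markers tested (Bonferroni policy).
#' @param alpha_family family-wise level (default 0.05).
#' @param r2_threshold clumping threshold (default 0.1).
#' @param policy,fixed_p significance policy, see [select_cis_significant()].
#' @param source label for the instrument source (e.g. `"eQTL"`, `"pQTL"`,
#'   `"tissue:thyroid"`).
#' @param palindrome_eaf_limit see [harmonize()].
#' @return object of class `instrument_set`: list with `pairs` (usable
#'   harmonized rows), `gene`, `source`, `clump_r2`, `significance_alpha`,
#'   `m`, `per_snp_r2`, `total_r2`, `f_statistic`, `n_exposure`,
#'   `n_missing_eaf`, and `report` (one row per SNP plus metrics).
#' @export
build_instrument <- function(exposure, outcome, region, ld, m = NULL,
                             alpha_family = 0.05, r2_threshold = 0.1,
                             policy = c("bonferroni", "fixed"), fixed_p = 1e-5,
                             source = "eQTL", palindrome_eaf_limit = 0.42) {
  policy <- match.arg(policy)
  sel <- select_cis_significant(exposure, region, alpha_family = alpha_family,
                                m = m, policy = policy, fixed_p = fixed_p)
  threshold <- attr(sel, "threshold")
  clumped <- ld_clump(sel, ld, r2_threshold = r2_threshold)
  if (nrow(clumped) == 0) {
    return(structure(list(pairs = NULL, gene = region, source = source,
                          clump_r2 = r2_threshold, significance_alpha = threshold,
                          m = m, per_snp_r2 = numeric(0), total_r2 = 0,
                          f_statistic = NA_real_, n_exposure = NA_real_,
                          n_missing_eaf = 0L, report = NULL),
                     class = "instrument_set"))
  }
  h <- harmonize(clumped, outcome, palindrome_eaf_limit = palindrome_eaf_limit)
  pairs <- harmonized_kept(h)
  per_snp_r2 <- variance_explained(pairs$exposure_beta, pairs$exposure_eaf)
  n_missing <- sum(is.na(per_snp_r2))
  total_r2 <- sum(per_snp_r2, na.rm = TRUE)
  n_exp <- stats::median(pairs$exposure_n, na.rm = TRUE)
  k <- nrow(pairs)
  f <- if (k >= 1 && is.finite(n_exp) && n_exp > k + 1 && total_r2 < 1) {
    as.numeric(f_statistic(total_r2, n_exp, k))
  } else NA_real_
  report <- cbind(pairs,
                  per_snp_r2 = per_snp_r2,
                  cumulative_r2 = cumsum(ifelse(is.na(per_snp_r2), 0, per_snp_r2)))
  structure(list(pairs = pairs, gene = region, source = source,
                 clump_r2 = r2_threshold, significance_alpha = threshold,
                 m = m, per_snp_r2 = per_snp_r2, total_r2 = total_r2,
                 f_statistic = f, n_exposure = n_exp,
                 n_missing_eaf = n_missing, report = report),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  k <- if (is.null(x$pairs)) 0L else nrow(x$pairs)
  cat(sprintf("Instrument set [%s] for %s: %d SNP(s), clump r2 < %g, p < %.3g\n",
              x$source, x$gene$gene_id, k, x$clump_r2, x$significance_alpha))
  if (k > 0) {
    cat(sprintf("  total R2 = %.4g, F = %.1f%s\n", x$total_r2, x$f_statistic,
                if (!is.na(x$f_statistic) && x$f_statistic < 10) " (weak)" else ""))
  }
  invisible(x)
}
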