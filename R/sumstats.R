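# Summary-statistics data model, delimited-text IO, and allele harmonization.
#
# A summary-statistics table is a plain data.frame with one row per variant
# and the canonical columns below; `trait_type` is "quantitative" (beta per
# SD of the trait) or "binary" (beta on the log-odds scale).

SUMSTAT_COLUMNS <- c(
  "variant_id", "chrom", "pos", "effect_allele", "other_allele",
  "eaf", "beta", "se", "pvalue", "n", "n_cases", "n_controls",
  "trait_id", "trait_type"
)

VALID_ALLELES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

is_palindromic <- function(a1, a2) COMPLEMENT[a1] == a2

#' Construct a summary-statistics table
#'
#' Assembles and validates a canonical summary-statistics data.frame. Rows
#' violating the record invariants (se > 0, eaf in \[0,1\], distinct A/C/G/T
#' alleles, p in (0,1\], case + control = n when all present) are removed and
#' reported via the `"rejects"` attribute.
#'
#' @param df data.frame holding (a superset of) the canonical columns.
#' @param trait_id trait label stamped on every row.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @return validated data.frame with attribute `"rejects"` (a data.frame of
#'   row numbers and reasons for every rejected input row).
#' @export
as_sumstats <- function(df, trait_id = df$trait_id[1] %||% "trait",
                        trait_type = df$trait_type[1] %||% "quantitative") {
  trait_type <- match.arg(trait_type, c("quantitative", "binary"))
  out <- data.frame(
    variant_id = as.character(df$variant_id),
    chrom = as.character(df$chrom),
    pos = as.numeric(df$pos),
    effect_allele = toupper(as.character(df$effect_allele)),
    other_allele = toupper(as.character(df$other_allele)),
    eaf = if ("eaf" %in% names(df)) suppressWarnings(as.numeric(df$eaf)) else NA_real_,
    beta = suppressWarnings(as.numeric(df$beta)),
    se = suppressWarnings(as.numeric(df$se)),
    pvalue = suppressWarnings(as.numeric(df$pvalue)),
    n = if ("n" %in% names(df)) suppressWarnings(as.numeric(df$n)) else NA_real_,
    n_cases = if ("n_cases" %in% names(df)) suppressWarnings(as.numeric(df$n_cases)) else NA_real_,
    n_controls = if ("n_controls" %in% names(df)) suppressWarnings(as.numeric(df$n_controls)) else NA_real_,
    trait_id = trait_id,
    trait_type = trait_type,
    stringsAsFactors = FALSE
  )

  reason <- rep(NA_character_, nrow(out))
  flag <- function(bad, why) ifelse(bad & is.na(reason), why, reason)
  reason <- flag(is.na(out$beta) | is.na(out$se) | is.na(out$pvalue) | is.na(out$pos),
                 "unparseable numeric field")
  reason <- flag(!is.na(out$se) & out$se <= 0, "se must be > 0")
  reason <- flag(!is.na(out$eaf) & (out$eaf < 0 | out$eaf > 1), "eaf outside [0,1]")
  reason <- flag(!(out$effect_allele %in% VALID_ALLELES) |
                   !(out$other_allele %in% VALID_ALLELES),
                 "alleles must be single A/C/G/T bases")
  reason <- flag(out$effect_allele == out$other_allele, "alleles must differ")
  reason <- flag(!is.na(out$pvalue) & (out$pvalue <= 0 | out$pvalue > 1),
                 "pvalue outside (0,1]")
  if (trait_type == "binary") {
    full <- !is.na(out$n_cases) & !is.na(out$n_controls) & !is.na(out$n)
    reason <- flag(full & abs(out$n_cases + out$n_controls - out$n) > 0.5,
                   "n_cases + n_controls != n")
  }

  bad <- !is.na(reason)
  rejects <- data.frame(row = which(bad), variant_id = out$variant_id[bad],
                        reason = reason[bad], stringsAsFactors = FALSE)
  out <- out[!bad, , drop = FALSE]
  rownames(out) <- NULL

  # Warn-level consistency check: p should match a two-sided normal test of
  # beta/se within a factor of 2 (catches mis-mapped columns, e.g. -log10 p).
  ok <- !is.na(out$pvalue) & out$pvalue > 1e-280
  if (any(ok)) {
    implied <- z_pvalue(out$beta[ok], out$se[ok])
    off <- implied > 1e-280 & (out$pvalue[ok] / implied > 2 | implied / out$pvalue[ok] > 2)
    if (mean(off) > 0.05) {
      warn_targetmr(sprintf(
        "%.0f%% of p-values disagree with |beta/se| by more than a factor of 2; check the column map",
        100 * mean(off)), "targetmr_pvalue_inconsistent")
    }
  }

  attr(out, "rejects") <- rejects
  out
}

#' Read a delimited summary-statistics file
#'
#' Reads tab- or comma-delimited text (gzip accepted) with a header and maps
#' file columns onto the canonical schema. Rows failing the record
#' invariants are rejected, counted, and reported through the `"rejects"`
#' attribute; row order is preserved for surviving rows.
#'
#' @param path file path.
#' @param column_map named character vector mapping canonical names
#'   (`variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`, `pvalue`, `n`, `n_cases`, `n_controls`) to file column
#'   names. Canonical names already present in the file need not be mapped.
#'   `eaf`, `n`, `n_cases`, `n_controls` are optional; when absent the field
#'   is recorded as missing (palindromic variants are then dropped at
#'   harmonization and the variant is excluded from R^2/F computation).
#' @param trait_id,trait_type trait descriptor stamped on all rows.
#' @return see [as_sumstats()].
#' @export
read_sumstats <- function(path, column_map = NULL, trait_id = "trait",
                          trait_type = c("quantitative", "binary")) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop_targetmr(paste0("file not found: ", path), "targetmr_io_error")
  raw <- data.table::fread(path, header = TRUE, data.table = FALSE,
                           colClasses = "character", showProgress = FALSE)
  for (canon in names(column_map)) {
    src <- column_map[[canon]]
    if (!src %in% names(raw)) {
      stop_targetmr(sprintf("mapped column '%s' (for '%s') not found in %s",
                            src, canon, path), "targetmr_missing_column")
    }
    raw[[canon]] <- raw[[src]]
  }
  required <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                "beta", "se", "pvalue")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop_targetmr(paste0("required columns absent after mapping: ",
                         paste(missing, collapse = ", ")), "targetmr_missing_column")
  }
  out <- as_sumstats(raw, trait_id = trait_id, trait_type = trait_type)
  rej <- attr(out, "rejects")
  if (nrow(rej) > 0) {
    message(sprintf("read_sumstats: rejected %d of %d rows from %s",
                    nrow(rej), nrow(raw), basename(path)))
  }
  out
}

#' Pairwise LD reference for a region
#'
#' @param variant_ids ordered variant identifiers.
#' @param r symmetric matrix of pairwise allelic correlations (unit
#'   diagonal, entries in \[-1, 1\]).
#' @return object of class `ld_reference`.
#' @export
ld_reference <- function(variant_ids, r) {
  r <- as.matrix(r)
  stopifnot(length(variant_ids) == nrow(r), nrow(r) == ncol(r))
  if (max(abs(r - t(r))) > 1e-8) stop_targetmr("LD matrix is not symmetric", "targetmr_ld_error")
  if (max(abs(diag(r) - 1)) > 1e-8) stop_targetmr("LD matrix diagonal must be 1", "targetmr_ld_error")
  if (max(abs(r)) > 1 + 1e-8) stop_targetmr("|r| must be <= 1", "targetmr_ld_error")
  dimnames(r) <- list(variant_ids, variant_ids)
  structure(list(variant_ids = as.character(variant_ids), r = r),
            class = "ld_reference")
}

#' Read a delimited LD matrix with variant-id header row and column
#' @param path file path to a square delimited matrix.
#' @return [ld_reference()] object.
#' @export
read_ld_reference <- function(path) {
  m <- data.table::fread(path, header = TRUE, data.table = FALSE, showProgress = FALSE)
  ids <- as.character(m[[1]])
  r <- as.matrix(m[, -1, drop = FALSE])
  ld_reference(ids, r)
}

#' Write an LD reference to delimited text
#' @param ld [ld_reference()] object.
#' @param path output path.
#' @export
write_ld_reference <- function(ld, path) {
  df <- data.frame(variant_id = ld$variant_ids, ld$r, check.names = FALSE)
  write_results_table(df, path)
}

#' Gene region with a cis flank
#'
#' Coordinates are 1-based inclusive; the cis window is
#' `[start - window_kb*1000, end + window_kb*1000]` inclusive.
#'
#' @param gene_id gene label.
#' @param chrom chromosome.
#' @param start,end gene boundary (1-based, inclusive), start <= end.
#' @param window_kb flank size in kilobases (default 200, the conventional
#'   cis-QTL window for drug-target instrument selection).
#' @return object of class `gene_region`.
#' @export
gene_region <- function(gene_id, chrom, start, end, window_kb = 200) {
  stopifnot(start <= end, window_kb >= 0)
  structure(list(gene_id = gene_id, chrom = as.character(chrom),
                 start = as.numeric(start), end = as.numeric(end),
                 window_kb = as.numeric(window_kb)),
            class = "gene_region")
}

#' Cis-window bounds of a gene region
#' @param region [gene_region()].
#' @return numeric length-2 vector (inclusive bounds).
#' @export
cis_window <- function(region) {
  c(region$start - region$window_kb * 1000, region$end + region$window_kb * 1000)
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome rows to the exposure's effect allele for every shared
#' variant. When the outcome's alleles are stated in the opposite order
#' (directly or on the opposite strand), its beta is negated and its eaf
#' complemented (`action = "flipped"`). Palindromic variants (A/T, C/G) are
#' strand-ambiguous: they are kept (as aligned) only when both effect-allele
#' frequencies fall strictly on the same side of 0.5 and both minor-allele
#' frequencies are below `palindrome_eaf_limit`; otherwise
#' `action = "dropped_palindromic"`. Missing eaf on either side also drops a
#' palindrome. Variants with incompatible allele sets get
#' `action = "dropped_mismatch"`.
#'
#' @param exposure,outcome summary-statistics data.frames ([as_sumstats()]).
#' @param palindrome_eaf_limit frequency limit above which a palindromic
#'   variant's strand cannot be inferred (default 0.42).
#' @return data.frame of harmonized pairs with an `action` column; rows with
#'   `action` in `aligned`/`flipped` are the usable pairs (see
#'   [harmonized_kept()]).
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_limit = 0.42) {
  shared <- intersect(exposure$variant_id, outcome$variant_id)
  if (length(shared) == 0) {
    stop_targetmr("no overlapping instruments between exposure and outcome",
                  "targetmr_no_overlap")
  }
  ex <- exposure[match(shared, exposure$variant_id), ]
  ou <- outcome[match(shared, outcome$variant_id), ]

  n <- length(shared)
  action <- character(n)
  out_beta <- ou$beta
  out_eaf <- ou$eaf

  for (i in seq_len(n)) {
    ea_x <- ex$effect_allele[i]; oa_x <- ex$other_allele[i]
    ea_y <- ou$effect_allele[i]; oa_y <- ou$other_allele[i]
    pal <- is_palindromic(ea_x, oa_x)

    if (pal) {
      # Same allele pair whether read direct or strand-flipped; orientation
      # must come from allele frequencies.
      same_pair <- setequal(c(ea_y, oa_y), c(ea_x, oa_x))
      if (!same_pair) { action[i] <- "dropped_mismatch"; next }
      if (is.na(ex$eaf[i]) || is.na(ou$eaf[i])) { action[i] <- "dropped_palindromic"; next }
      maf_x <- pmin(ex$eaf[i], 1 - ex$eaf[i])
      maf_y <- pmin(ou$eaf[i], 1 - ou$eaf[i])
      same_side <- (ex$eaf[i] - 0.5) * (ou$eaf[i] - 0.5) > 0
      if (same_side && maf_x < palindrome_eaf_limit && maf_y < palindrome_eaf_limit) {
        action[i] <- "aligned"
      } else {
        action[i] <- "dropped_palindromic"
      }
      next
    }

    if (ea_y == ea_x && oa_y == oa_x) {
      action[i] <- "aligned"
    } else if (ea_y == oa_x && oa_y == ea_x) {
      action[i] <- "flipped"
    } else if (identical(unname(COMPLEMENT[ea_y]), ea_x) &&
               identical(unname(COMPLEMENT[oa_y]), oa_x)) {
      action[i] <- "aligned"   # same orientation, opposite strand
    } else if (identical(unname(COMPLEMENT[ea_y]), oa_x) &&
               identical(unname(COMPLEMENT[oa_y]), ea_x)) {
      action[i] <- "flipped"   # swapped orientation, opposite strand
    } else {
      action[i] <- "dropped_mismatch"
    }

    if (action[i] == "flipped") {
      out_beta[i] <- -ou$beta[i]
      out_eaf[i] <- 1 - ou$eaf[i]
    }
  }

  data.frame(
    variant_id = shared,
    chrom = ex$chrom,
    pos = ex$pos,
    effect_allele = ex$effect_allele,
    other_allele = ex$other_allele,
    exposure_beta = ex$beta,
    exposure_se = ex$se,
    exposure_eaf = ex$eaf,
    exposure_pvalue = ex$pvalue,
    exposure_n = ex$n,
    outcome_beta = out_beta,
    outcome_se = ou$se,
    outcome_eaf = out_eaf,
    outcome_pvalue = ou$pvalue,
    outcome_n = ou$n,
    outcome_n_cases = ou$n_cases,
    outcome_n_controls = ou$n_controls,
    action = action,
    stringsAsFactors = FALSE
  )
}

#' Usable rows of a harmonized table
#' @param h output of [harmonize()].
#' @return rows with `action` `"aligned"` or `"flipped"`.
#' @export
harmonized_kept <- function(h) {
  out <- h[h$action %in% c("aligned", "flipped"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a results table as lossless tab-delimited text
#'
#' Numeric columns are serialized at 17 significant digits so a
#' write/read round-trip preserves values to better than 1e-12 relative
#' precision.
#'
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(df, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop_targetmr(paste0("directory does not exist: ", dir),
                                      "targetmr_io_error")
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) {
      v <- sprintf("%.17g", out[[j]])
      v[is.na(out[[j]])] <- "NA"
      out[[j]] <- v
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

#' Read a table written by [write_results_table()]
#' @param path file path.
#' @return data.frame.
#' @export
read_results_table <- function(path) {
  data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                    na.strings = "NA", showProgress = FALSE)
}

#' Write a run-metadata sidecar (inputs, thresholds, seeds, version)
#' @param meta named list.
#' @param path output path (JSON).
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(meta, path) {
  meta$package_version <- as.character(utils::packageVersion("targetmr"))
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
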