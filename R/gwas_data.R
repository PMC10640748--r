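## GWAS summary-statistic types and I/O, instrument selection, and
## exposure/outcome allele harmonisation.

# Canonical column order of the summary-stat TSV interchange format.
SUMSTAT_COLS <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                  "eaf", "beta", "se", "pval", "n")

# Built-in header aliases accepted on input (file name -> canonical name).
DEFAULT_COLUMN_MAP <- c(
  SNP = "variant_id", rsid = "variant_id", rsID = "variant_id",
  ID = "variant_id", MarkerName = "variant_id",
  CHR = "chrom", chr = "chrom", chromosome = "chrom",
  BP = "pos", position = "pos", base_pair_location = "pos",
  A1 = "effect_allele", EA = "effect_allele", ALT = "effect_allele",
  A2 = "other_allele", OA = "other_allele", REF = "other_allele",
  freq = "eaf", EAF = "eaf", effect_allele_frequency = "eaf", af = "eaf",
  b = "beta", BETA = "beta", Effect = "beta",
  SE = "se", standard_error = "se",
  p = "pval", P = "pval", pvalue = "pval", p_value = "pval",
  N = "n", samplesize = "n", sample_size = "n"
)

#' Describe a GWAS trait
#'
#' Light-weight metadata attached to a set of summary statistics. The
#' `trait_type` fixes the scale convention of the `beta` column: standard
#' deviation units for continuous traits, log-odds for binary traits.
#'
#' @param trait_id Short machine identifier.
#' @param label Human-readable name; defaults to `trait_id`.
#' @param trait_type `"continuous"` or `"binary"`.
#' @param ncase,ncontrol Optional case/control counts for binary traits.
#' @return An object of class `trait_info`.
#' @export
trait_info <- function(trait_id, label = trait_id,
                       trait_type = c("continuous", "binary"),
                       ncase = NA_integer_, ncontrol = NA_integer_) {
  trait_type <- match.arg(trait_type)
  structure(list(trait_id = trait_id, label = label, trait_type = trait_type,
                 ncase = ncase, ncontrol = ncontrol),
            class = "trait_info")
}

#' @export
print.trait_info <- function(x, ...) {
  cat(sprintf("<trait_info> %s (%s, %s)\n", x$trait_id, x$label, x$trait_type))
  invisible(x)
}

is_acgt <- function(a) a %in% c("A", "C", "G", "T")

complement_allele <- function(a) {
  c(A = "T", T = "A", C = "G", G = "C")[a]
}

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

# Validate a variant-association data.frame in place; stops on violated
# invariants that cannot be repaired by row filtering.
validate_assoc <- function(assoc) {
  stopifnot(is.data.frame(assoc))
  missing_cols <- setdiff(setdiff(SUMSTAT_COLS, c("eaf", "n")), names(assoc))
  if (length(missing_cols) > 0) {
    stop_mrphewas(sprintf("missing mandatory column(s): %s",
                          paste(missing_cols, collapse = ", ")),
                  "mrphewas_format_error")
  }
  if (!"eaf" %in% names(assoc)) assoc$eaf <- NA_real_
  if (!"n" %in% names(assoc)) assoc$n <- NA_real_
  assoc[, SUMSTAT_COLS]
}

#' Read GWAS summary statistics from a TSV file
#'
#' Expects a tab-separated table with a header row. Columns may use common
#' aliases (`SNP`, `rsid`, `A1`/`A2`, `freq`, ...); additional aliases can be
#' supplied through `column_map`. Alleles are uppercased. Rows whose alleles
#' are not single A/C/G/T bases (indels, multi-allelic records) or whose
#' standard error is not positive are skipped with a reported count.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param trait Optional [trait_info()] attached as the `"trait"` attribute.
#' @param column_map Optional named character vector of extra header aliases,
#'   `c(file_name = "canonical_name")`.
#' @return A data.frame with columns `variant_id, chrom, pos, effect_allele,
#'   other_allele, eaf, beta, se, pval, n`, one row per retained input row, in
#'   input order.
#' @export
read_summary_stats <- function(path, trait = NULL, column_map = NULL) {
  if (!file.exists(path)) {
    stop_mrphewas(sprintf("file not found: %s", path), "mrphewas_io_error")
  }
  raw <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) {
      stop_mrphewas(sprintf("empty or unreadable summary-statistic file: %s",
                            path), "mrphewas_format_error")
    })
  map <- c(column_map, DEFAULT_COLUMN_MAP)
  hits <- names(raw) %in% names(map)
  names(raw)[hits] <- unname(map[names(raw)[hits]])
  assoc <- validate_assoc(raw)

  assoc$variant_id <- as.character(assoc$variant_id)
  assoc$chrom <- as.character(assoc$chrom)
  assoc$pos <- as.integer(assoc$pos)
  assoc$effect_allele <- toupper(as.character(assoc$effect_allele))
  assoc$other_allele <- toupper(as.character(assoc$other_allele))
  for (col in c("eaf", "beta", "se", "pval", "n")) {
    assoc[[col]] <- as.numeric(assoc[[col]])
  }

  bad <- !is_acgt(assoc$effect_allele) | !is_acgt(assoc$other_allele) |
    assoc$effect_allele == assoc$other_allele |
    !is.finite(assoc$se) | assoc$se <= 0
  if (any(bad)) {
    message(sprintf("read_summary_stats: skipped %d of %d rows (non-SNP alleles or se <= 0)",
                    sum(bad), nrow(assoc)))
    assoc <- assoc[!bad, , drop = FALSE]
    rownames(assoc) <- NULL
  }
  attr(assoc, "trait") <- trait
  assoc
}

#' Write GWAS summary statistics to a TSV file
#'
#' Inverse of [read_summary_stats()]: fixed canonical column order, tab
#' separated, numbers written with 17 significant digits so a round trip
#' reproduces every field.
#'
#' @param assoc Variant-association data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(assoc, path) {
  assoc <- validate_assoc(assoc)
  out <- assoc
  for (col in c("eaf", "beta", "se", "pval", "n")) {
    out[[col]] <- ifelse(is.na(assoc[[col]]), "NA",
                         sprintf("%.17g", assoc[[col]]))
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) {
    stop_mrphewas(sprintf("cannot write summary statistics to %s", path),
                  "mrphewas_io_error")
  }
  invisible(path)
}

#' Select genome-wide significant instruments
#'
#' Keeps associations with `pval` strictly below the threshold (default the
#' conventional genome-wide level 5e-8), sorted by ascending p-value with
#' ties broken by variant id.
#'
#' @param assoc Variant-association data.frame.
#' @param p_threshold Strict upper bound on the p-value; in (0, 1).
#' @return The selected rows; possibly empty.
#' @export
select_instruments <- function(assoc, p_threshold = 5e-8) {
  stopifnot(is.numeric(p_threshold), length(p_threshold) == 1,
            p_threshold > 0, p_threshold < 1)
  assoc <- validate_assoc(assoc)
  keep <- assoc[assoc$pval < p_threshold, , drop = FALSE]
  keep <- keep[order(keep$pval, keep$variant_id), , drop = FALSE]
  rownames(keep) <- NULL
  keep
}

# Build a one-row harmonised-instrument record.
harmonised_record <- function(variant_id, ea, oa,
                              exp_beta, exp_se, exp_eaf,
                              out_beta, out_se, out_eaf,
                              action, drop_reason = "", proxy_of = "") {
  data.frame(variant_id = variant_id, effect_allele = ea, other_allele = oa,
             exposure_beta = exp_beta, exposure_se = exp_se,
             exposure_eaf = exp_eaf,
             outcome_beta = out_beta, outcome_se = out_se,
             outcome_eaf = out_eaf,
             action = action, drop_reason = drop_reason, proxy_of = proxy_of,
             stringsAsFactors = FALSE)
}

#' Harmonise one exposure/outcome association pair onto a common effect allele
#'
#' Aligns the outcome association to the exposure's effect/other allele pair
#' so both refer to the same allele on the same strand:
#'
#' * alleles already match in order: record kept unchanged;
#' * alleles match with roles swapped: outcome beta is negated and the
#'   outcome effect-allele frequency complemented (`flipped`);
#' * alleles are strand complements: the outcome alleles are complemented
#'   first, then the two rules above apply;
#' * palindromic pairs (A/T or C/G), where strand cannot be read off the
#'   allele labels: the effect-allele frequencies of both studies decide the
#'   orientation, provided both are available and both lie outside the
#'   ambiguity window around 0.5; otherwise the variant is dropped as
#'   `ambiguous_palindrome`;
#' * incompatible allele sets are dropped as `allele_mismatch`.
#'
#' The operation is idempotent: re-harmonising its own output changes
#' nothing.
#'
#' @param exposure,outcome One-row variant-association data.frames for the
#'   same variant (or `outcome` is a declared proxy; see `proxy_of`).
#' @param palindrome_eaf_window Half-width of the frequency ambiguity window:
#'   palindromic variants with either EAF within `0.5 +/-` this value are
#'   dropped. Default 0.08, i.e. the window \\[0.42, 0.58\\].
#' @param proxy_of If `outcome` is a proxy observation already aligned to the
#'   exposure variant's alleles, the original variant id it stands in for.
#' @return A one-row harmonised-instrument data.frame with columns
#'   `variant_id, effect_allele, other_allele, exposure_beta, exposure_se,
#'   exposure_eaf, outcome_beta, outcome_se, outcome_eaf, action,
#'   drop_reason, proxy_of`.
#' @export
harmonise_pair <- function(exposure, outcome, palindrome_eaf_window = 0.08,
                           proxy_of = "") {
  stopifnot(nrow(exposure) == 1, nrow(outcome) == 1)
  if (exposure$variant_id != outcome$variant_id && !nzchar(proxy_of)) {
    stop_mrphewas(sprintf("variant_id mismatch (%s vs %s) without a proxy declaration",
                          exposure$variant_id, outcome$variant_id),
                  "mrphewas_usage_error")
  }
  ea_x <- exposure$effect_allele
  oa_x <- exposure$other_allele
  ea_y <- outcome$effect_allele
  oa_y <- outcome$other_allele
  rec <- function(action, out_beta, out_eaf, drop_reason = "") {
    harmonised_record(exposure$variant_id, ea_x, oa_x,
                      exposure$beta, exposure$se, exposure$eaf,
                      out_beta, outcome$se, out_eaf,
                      action, drop_reason, proxy_of)
  }
  dropped <- function(reason) {
    r <- rec("dropped", NA_real_, NA_real_, reason)
    r
  }

  if (is_palindromic(ea_x, oa_x)) {
    if (!setequal(c(ea_y, oa_y), c(ea_x, oa_x))) {
      return(dropped("allele_mismatch"))
    }
    eaf_x <- exposure$eaf
    eaf_y <- outcome$eaf
    lo <- 0.5 - palindrome_eaf_window
    hi <- 0.5 + palindrome_eaf_window
    if (is.na(eaf_x) || is.na(eaf_y) ||
        (eaf_x >= lo && eaf_x <= hi) || (eaf_y >= lo && eaf_y <= hi)) {
      return(dropped("ambiguous_palindrome"))
    }
    # Nominal alignment by allele labels, then let the frequencies decide
    # whether the outcome study reported the opposite strand.
    if (ea_y == ea_x) {
      out_beta <- outcome$beta
      out_eaf <- eaf_y
    } else {
      out_beta <- -outcome$beta
      out_eaf <- 1 - eaf_y
    }
    if ((eaf_x - 0.5) * (out_eaf - 0.5) < 0) {
      return(rec("flipped", -out_beta, 1 - out_eaf))
    }
    return(rec("palindromic_resolved", out_beta, out_eaf))
  }

  # Non-palindromic: try as reported, then the strand complement.
  for (comp in c(FALSE, TRUE)) {
    a1 <- if (comp) complement_allele(ea_y) else ea_y
    a2 <- if (comp) complement_allele(oa_y) else oa_y
    if (a1 == ea_x && a2 == oa_x) {
      return(rec("kept", outcome$beta, outcome$eaf))
    }
    if (a1 == oa_x && a2 == ea_x) {
      return(rec("flipped", -outcome$beta,
                 if (is.na(outcome$eaf)) NA_real_ else 1 - outcome$eaf))
    }
  }
  dropped("allele_mismatch")
}

#' Harmonise an instrument set against an outcome dataset
#'
#' Matches each exposure instrument to the outcome summary statistics by
#' variant id and applies [harmonise_pair()]. Instruments absent from the
#' outcome dataset are either substituted by a proxy variant in high LD
#' (when a reference panel is supplied) or dropped with reason
#' `not_in_outcome`. Dropped records are retained in the output with their
#' reason so exclusion tallies can be reported; use
#' `subset(x, action != "dropped")` for estimation.
#'
#' @param exposure Instrument rows (variant-association data.frame).
#' @param outcome Outcome summary statistics (variant-association
#'   data.frame).
#' @param panel Optional [reference_panel()] used for proxy search.
#' @param proxy_r2_min Minimum r-squared (strict) for a proxy substitute.
#' @param proxy_window_kb Window around the missing instrument searched for
#'   proxies, in kilobases.
#' @param palindrome_eaf_window Passed to [harmonise_pair()].
#' @return A harmonised-instrument data.frame, one row per exposure
#'   instrument, in input order.
#' @export
harmonise <- function(exposure, outcome, panel = NULL,
                      proxy_r2_min = 0.8, proxy_window_kb = 10000,
                      palindrome_eaf_window = 0.08) {
  exposure <- validate_assoc(exposure)
  outcome <- validate_assoc(outcome)
  if (nrow(exposure) == 0) {
    return(harmonised_record(character(0), character(0), character(0),
                             numeric(0), numeric(0), numeric(0),
                             numeric(0), numeric(0), numeric(0),
                             character(0), character(0), character(0)))
  }
  out <- vector("list", nrow(exposure))
  for (i in seq_len(nrow(exposure))) {
    exp_row <- exposure[i, , drop = FALSE]
    j <- match(exp_row$variant_id, outcome$variant_id)
    if (!is.na(j)) {
      out[[i]] <- harmonise_pair(exp_row, outcome[j, , drop = FALSE],
                                 palindrome_eaf_window)
      next
    }
    prox <- NULL
    if (!is.null(panel) && exp_row$variant_id %in% panel$variants$variant_id) {
      cand <- outcome$variant_id[
        outcome$chrom == exp_row$chrom &
          abs(outcome$pos - exp_row$pos) <= proxy_window_kb * 1000]
      cand <- intersect(cand, panel$variants$variant_id)
      if (length(cand) > 0) {
        prox <- find_proxy(panel, exp_row$variant_id, cand, proxy_r2_min)
      }
    }
    if (is.null(prox)) {
      out[[i]] <- harmonised_record(
        exp_row$variant_id, exp_row$effect_allele, exp_row$other_allele,
        exp_row$beta, exp_row$se, exp_row$eaf,
        NA_real_, NA_real_, NA_real_, "dropped", "not_in_outcome", "")
      next
    }
    pseudo <- proxy_as_target(panel, exp_row, outcome, prox)
    out[[i]] <- harmonise_pair(exp_row, pseudo, palindrome_eaf_window,
                               proxy_of = prox$variant_id)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Re-express a proxy's outcome association on the target variant's alleles,
# using the signed dosage correlation r from the panel for orientation.
proxy_as_target <- function(panel, target_row, outcome, prox) {
  out_row <- outcome[match(prox$variant_id, outcome$variant_id), , drop = FALSE]
  pv <- panel$variants
  pi_ <- match(prox$variant_id, pv$variant_id)
  ti <- match(target_row$variant_id, pv$variant_id)
  # Align the proxy's outcome record to the panel's allele_b orientation.
  beta <- out_row$beta
  eaf <- out_row$eaf
  if (identical(out_row$effect_allele, pv$allele_a[pi_])) {
    beta <- -beta
    eaf <- if (is.na(eaf)) NA_real_ else 1 - eaf
  }
  # Positive r: proxy allele_b travels with target allele_b.
  s <- sign(prox$r)
  if (s < 0) {
    beta <- -beta
    eaf <- if (is.na(eaf)) NA_real_ else 1 - eaf
  }
  # Panel allele_b of the target becomes the effect allele of the pseudo
  # record; orient to the target row's own allele labels.
  data.frame(variant_id = target_row$variant_id,
             chrom = out_row$chrom, pos = out_row$pos,
             effect_allele = pv$allele_b[ti], other_allele = pv$allele_a[ti],
             eaf = eaf, beta = beta, se = out_row$se,
             pval = out_row$pval, n = out_row$n,
             stringsAsFactors = FALSE)
}
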