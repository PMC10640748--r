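## Reference-panel genotypes: pairwise LD, greedy clumping, proxy search.

#' Construct a reference genotype panel
#'
#' Holds per-individual allele-b dosage counts (0..2) over a set of variants,
#' used for LD computation, clumping, proxy search, and the conditional scan.
#' Constant (zero-variance) dosage columns are dropped at construction with a
#' message, since no correlation is defined for them.
#'
#' @param variants data.frame with columns `variant_id, chrom, pos, allele_a,
#'   allele_b`.
#' @param dosages Numeric matrix, individuals x variants, entries in
#'   \\[0, 2\\]; column count must equal `nrow(variants)`.
#' @return An object of class `reference_panel` with elements `variants` and
#'   `dosages` (columns named by variant id).
#' @export
reference_panel <- function(variants, dosages) {
  stopifnot(is.data.frame(variants), is.matrix(dosages),
            ncol(dosages) == nrow(variants))
  need <- c("variant_id", "chrom", "pos", "allele_a", "allele_b")
  missing_cols <- setdiff(need, names(variants))
  if (length(missing_cols) > 0) {
    stop_mrphewas(sprintf("panel variant table lacks column(s): %s",
                          paste(missing_cols, collapse = ", ")),
                  "mrphewas_format_error")
  }
  variants$variant_id <- as.character(variants$variant_id)
  variants$chrom <- as.character(variants$chrom)
  colnames(dosages) <- variants$variant_id
  v <- apply(dosages, 2, stats::var)
  if (any(v == 0)) {
    message(sprintf("reference_panel: dropped %d constant dosage column(s)",
                    sum(v == 0)))
    dosages <- dosages[, v > 0, drop = FALSE]
    variants <- variants[v > 0, , drop = FALSE]
    rownames(variants) <- NULL
  }
  structure(list(variants = variants, dosages = dosages),
            class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("<reference_panel> %d individuals x %d variants\n",
              nrow(x$dosages), ncol(x$dosages)))
  invisible(x)
}

#' Read a reference panel from TSV files
#'
#' @param variants_path Variant table TSV (`variant_id, chrom, pos, allele_a,
#'   allele_b`).
#' @param dosages_path Dosage matrix TSV, individuals x variants, with a
#'   header of variant ids.
#' @return A [reference_panel()].
#' @export
read_reference_panel <- function(variants_path, dosages_path) {
  variants <- utils::read.delim(variants_path, stringsAsFactors = FALSE)
  dosages <- as.matrix(utils::read.delim(dosages_path, check.names = FALSE))
  reference_panel(variants, dosages)
}

#' Write a reference panel to TSV files
#'
#' @param panel A [reference_panel()].
#' @param variants_path,dosages_path Output paths.
#' @return `invisible(NULL)`.
#' @export
write_reference_panel <- function(panel, variants_path, dosages_path) {
  utils::write.table(panel$variants, variants_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(panel$dosages, dosages_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}

panel_col <- function(panel, id) {
  j <- match(id, panel$variants$variant_id)
  if (is.na(j)) {
    stop_mrphewas(sprintf("variant %s not in reference panel", id),
                  "mrphewas_lookup_error")
  }
  panel$dosages[, j]
}

#' Pairwise LD between two panel variants
#'
#' Signed Pearson correlation of the two dosage columns (genotype
#' correlation, unphased), together with its square.
#'
#' @param panel A [reference_panel()].
#' @param id_a,id_b Variant ids present in the panel.
#' @return A list with elements `r` and `r2`.
#' @export
ld_r <- function(panel, id_a, id_b) {
  xa <- panel_col(panel, id_a)
  xb <- panel_col(panel, id_b)
  if (stats::var(xa) == 0 || stats::var(xb) == 0) {
    stop_mrphewas("zero dosage variance; LD undefined",
                  "mrphewas_degenerate_variant_error")
  }
  r <- stats::cor(xa, xb)
  list(r = r, r2 = r^2)
}

#' Greedy LD clumping
#'
#' Iteratively retains the remaining association with the smallest p-value
#' (ties broken by variant id) and removes every remaining association on
#' the same chromosome within `window_kb` kilobases whose squared dosage
#' correlation with it exceeds `r2_threshold`. Defaults match the common
#' stringent practice of a 10,000 kb radius at r-squared 0.001. Variants not
#' present in the panel cannot be tested and pass through with a message.
#'
#' @param assoc Variant-association data.frame.
#' @param panel A [reference_panel()].
#' @param r2_threshold Retained pairs must have r-squared at or below this.
#' @param window_kb Base-pair window, in kb, within which LD is tested.
#' @return The retained associations, ordered by ascending p-value.
#' @export
clump <- function(assoc, panel, r2_threshold = 0.001, window_kb = 10000) {
  assoc <- validate_assoc(assoc)
  if (nrow(assoc) == 0) return(assoc)
  in_panel <- assoc$variant_id %in% panel$variants$variant_id
  if (any(!in_panel)) {
    message(sprintf("clump: %d variant(s) absent from panel retained untested",
                    sum(!in_panel)))
  }
  remaining <- assoc[order(assoc$pval, assoc$variant_id), , drop = FALSE]
  keep <- list()
  while (nrow(remaining) > 0) {
    index <- remaining[1, , drop = FALSE]
    keep[[length(keep) + 1]] <- index
    remaining <- remaining[-1, , drop = FALSE]
    if (nrow(remaining) == 0) break
    if (!index$variant_id %in% panel$variants$variant_id) next
    near <- remaining$chrom == index$chrom &
      abs(remaining$pos - index$pos) <= window_kb * 1000 &
      remaining$variant_id %in% panel$variants$variant_id
    if (!any(near)) next
    drop <- rep(FALSE, nrow(remaining))
    for (k in which(near)) {
      drop[k] <- ld_r(panel, index$variant_id,
                      remaining$variant_id[k])$r2 > r2_threshold
    }
    remaining <- remaining[!drop, , drop = FALSE]
  }
  res <- do.call(rbind, keep)
  rownames(res) <- NULL
  res
}

#' Find a proxy variant in high LD with a target
#'
#' Scans the candidate variants for the one with maximal squared dosage
#' correlation with the target, strictly above `r2_min` (default 0.8, the
#' conventional proxy cut-off). Ties are broken by genomic proximity to the
#' target, then lexicographic variant id. The signed correlation is returned
#' so the caller can orient the proxy's alleles relative to the target.
#'
#' @param panel A [reference_panel()].
#' @param target Variant id to be proxied; must be in the panel.
#' @param candidates Character vector of candidate variant ids (typically
#'   the outcome dataset's variants near the target).
#' @param r2_min Strict lower bound on the proxy's r-squared.
#' @return A list `(variant_id, r, r2)` or `NULL` if no candidate qualifies.
#' @export
find_proxy <- function(panel, target, candidates, r2_min = 0.8) {
  target_dos <- panel_col(panel, target)  # errors if target absent
  candidates <- unique(candidates)
  candidates <- candidates[candidates %in% panel$variants$variant_id]
  if (length(candidates) == 0) return(NULL)
  rs <- vapply(candidates, function(id) {
    xb <- panel_col(panel, id)
    if (stats::var(xb) == 0) return(NA_real_)
    stats::cor(target_dos, xb)
  }, numeric(1))
  r2s <- rs^2
  ok <- !is.na(r2s) & r2s > r2_min
  if (!any(ok)) return(NULL)
  pv <- panel$variants
  tpos <- pv$pos[match(target, pv$variant_id)]
  cpos <- pv$pos[match(candidates, pv$variant_id)]
  ord <- order(-r2s, abs(cpos - tpos), candidates)
  best <- ord[ok[ord]][1]
  list(variant_id = candidates[best], r = unname(rs[best]),
       r2 = unname(r2s[best]))
}
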