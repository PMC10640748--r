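## Per-region Bayesian colocalization via approximate Bayes factors, and a
## summary-statistic conditional scan for secondary association signals.

#' Colocalization priors
#'
#' Per-variant prior probabilities of causality: `p1` (trait 1 only), `p2`
#' (trait 2 only), `p12` (shared), and the prior variances `w1`, `w2` of
#' the causal effect on each trait's scale. Defaults are the conventional
#' ones for this analysis (1e-4, 1e-4, 1e-5, 0.2^2, 0.2^2).
#'
#' @param p1,p2,p12 Per-variant prior probabilities; `0 < p12 <= min(p1,p2)`.
#' @param w1,w2 Prior effect variances.
#' @return A list of class `coloc_priors`.
#' @export
coloc_priors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                         w1 = 0.2^2, w2 = 0.2^2) {
  stopifnot(p12 > 0, p12 <= min(p1, p2), p1 < 1, p2 < 1, w1 > 0, w2 > 0)
  structure(list(p1 = p1, p2 = p2, p12 = p12, w1 = w1, w2 = w2),
            class = "coloc_priors")
}

#' Wakefield's approximate log Bayes factor for one association
#'
#' For an observed z-score with standard error `se` and prior effect
#' variance `w`, with `V = se^2` and shrinkage `lambda = w/(V+w)`:
#' `log ABF = 0.5*(log(1-lambda) + z^2*lambda)`, the log Bayes factor of
#' the normal alternative against the point null. Monotone increasing in
#' `|z|`.
#'
#' @param z Association z-score.
#' @param se Standard error of the estimate (> 0).
#' @param w Prior effect variance (> 0).
#' @return The log approximate Bayes factor.
#' @export
wakefield_abf <- function(z, se, w) {
  if (any(se <= 0) || any(w <= 0)) {
    stop_mrphewas("wakefield_abf requires se > 0 and w > 0",
                  "mrphewas_domain_error")
  }
  V <- se^2
  lambda <- w / (V + w)
  0.5 * (log1p(-lambda) + z^2 * lambda)
}

#' Approximate-Bayes-factor colocalization of two regional profiles
#'
#' Restricts both traits to their shared variants, computes per-variant
#' log ABFs, and evaluates the posterior over the five hypotheses: H0 no
#' causal variant, H1/H2 a causal variant for one trait only, H3 two
#' distinct causal variants, H4 one shared causal variant. With
#' `S1 = sum(exp(lbf1))`, `S2 = sum(exp(lbf2))`, `S12 = sum(exp(lbf1+lbf2))`
#' (all evaluated in log space) the unnormalised masses are
#' `1, p1*S1, p2*S2, p1*p2*(S1*S2 - S12), p12*S12`; a negative H3 mass is
#' guarded to zero with a warning.
#'
#' @param region1,region2 Variant-association data.frames for the same
#'   genomic region in two traits.
#' @param priors A [coloc_priors()].
#' @return A list with `pp` (named numeric, `PP.H0` .. `PP.H4`, summing to
#'   1), `nsnp`, and `priors`.
#' @export
coloc_abf <- function(region1, region2, priors = coloc_priors()) {
  region1 <- validate_assoc(region1)
  region2 <- validate_assoc(region2)
  shared <- intersect(region1$variant_id, region2$variant_id)
  if (length(shared) == 0) {
    stop_mrphewas("no shared variants between the two regions",
                  "mrphewas_data_error")
  }
  r1 <- region1[match(shared, region1$variant_id), ]
  r2 <- region2[match(shared, region2$variant_id), ]
  lbf1 <- wakefield_abf(r1$beta / r1$se, r1$se, priors$w1)
  lbf2 <- wakefield_abf(r2$beta / r2$se, r2$se, priors$w2)

  lS1 <- logsumexp(lbf1)
  lS2 <- logsumexp(lbf2)
  lS12 <- logsumexp(lbf1 + lbf2)
  lH3_mass <- logdiffexp(lS1 + lS2, lS12)
  if (!is.finite(lH3_mass)) {
    warning("coloc_abf: non-positive H3 mass guarded to zero")
  }
  lmass <- c(H0 = 0,
             H1 = log(priors$p1) + lS1,
             H2 = log(priors$p2) + lS2,
             H3 = log(priors$p1) + log(priors$p2) + lH3_mass,
             H4 = log(priors$p12) + lS12)
  lz <- logsumexp(lmass)
  pp <- exp(lmass - lz)
  names(pp) <- paste0("PP.", names(lmass))
  list(pp = pp, nsnp = length(shared), priors = priors)
}

#' Conditional association scan around an index variant
#'
#' Approximates a joint-model conditional analysis from summary statistics:
#' for each regional variant with panel dosage correlation `r` to the index,
#' the conditional z-score is `(z - r*z_index)/sqrt(1-r^2)`. The scan
#' assumes standardized effects and an LD panel that matches the GWAS
#' population; variants effectively collinear with the index
#' (`|r| >= 0.99`) are skipped rather than errored. A secondary signal is
#' declared when any non-index, non-skipped, in-window variant stays
#' genome-wide significant (conditional p < 5e-8) after conditioning.
#'
#' @param region Variant-association data.frame for the region.
#' @param panel A [reference_panel()] covering the region.
#' @param index Variant id to condition on, or `"auto"` for the smallest
#'   marginal p-value in the window (ties by variant id).
#' @param window_kb Half-window around the index, in kb (default 500, i.e.
#'   a 1 Mb region).
#' @return A list with `index`, `table` (per-variant `variant_id, r, z_marg,
#'   z_cond, pval_cond, skipped, in_window`), and `secondary_signal`.
#' @export
conditional_scan <- function(region, panel, index = "auto", window_kb = 500) {
  region <- validate_assoc(region)
  z <- region$beta / region$se
  if (identical(index, "auto")) {
    p <- z_pval(region$beta, region$se)
    ord <- order(p, region$variant_id)
    index <- region$variant_id[ord[1]]
  }
  idx_dos <- panel_col(panel, index)  # lookup error if absent
  ii <- match(index, region$variant_id)
  if (is.na(ii)) {
    stop_mrphewas(sprintf("index variant %s not in region", index),
                  "mrphewas_lookup_error")
  }
  z_index <- z[ii]
  ipos <- region$pos[ii]
  ichrom <- region$chrom[ii]

  n <- nrow(region)
  r <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    id <- region$variant_id[k]
    if (id %in% panel$variants$variant_id) {
      xk <- panel$dosages[, match(id, panel$variants$variant_id)]
      r[k] <- stats::cor(idx_dos, xk)
    }
  }
  r[ii] <- 1
  skipped <- !is.na(r) & abs(r) >= 0.99 & region$variant_id != index
  r_eff <- ifelse(is.na(r), 0, r)  # unmappable variants keep marginal z
  z_cond <- (z - r_eff * z_index) / sqrt(1 - r_eff^2)
  z_cond[ii] <- 0
  z_cond[skipped] <- NA_real_
  pval_cond <- 2 * stats::pnorm(-abs(z_cond))
  in_window <- region$chrom == ichrom &
    abs(region$pos - ipos) <= window_kb * 1000
  tab <- data.frame(variant_id = region$variant_id, r = r,
                    z_marg = z, z_cond = z_cond, pval_cond = pval_cond,
                    skipped = skipped, in_window = in_window,
                    stringsAsFactors = FALSE)
  secondary <- any(!is.na(tab$pval_cond) & tab$in_window & !tab$skipped &
                     tab$variant_id != index & tab$pval_cond < 5e-8)
  list(index = index, table = tab, secondary_signal = secondary,
       skipped = region$variant_id[skipped])
}

#' Export a plain regional association scatter
#'
#' Writes `pos, neg_log10_p, r2_index` per variant: the minimal data needed
#' to draw a regional association plot (position against -log10 p, coloured
#' by LD with the index variant).
#'
#' @param region Variant-association data.frame.
#' @param panel A [reference_panel()].
#' @param index Index variant id or `"auto"`.
#' @param path Optional output TSV path.
#' @return The scatter data.frame (invisibly if written to `path`).
#' @export
regional_scatter <- function(region, panel, index = "auto", path = NULL) {
  scan <- conditional_scan(region, panel, index)
  region <- validate_assoc(region)
  p <- z_pval(region$beta, region$se)
  out <- data.frame(variant_id = region$variant_id, pos = region$pos,
                    neg_log10_p = -log10(p), r2_index = scan$table$r^2,
                    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
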