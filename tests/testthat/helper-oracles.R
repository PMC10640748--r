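# An independently written exhaustive greedy clump, kept deliberately naive.
brute_clump <- function(assoc, panel, r2_threshold, window_kb) {
  pool <- assoc
  kept <- assoc[0, ]
  while (nrow(pool) > 0) {
    pool <- pool[order(pool$pval, pool$variant_id), ]
    top <- pool[1, ]
    kept <- rbind(kept, top)
    pool <- pool[-1, ]
    keep_row <- rep(TRUE, nrow(pool))
    for (k in seq_len(nrow(pool))) {
      if (!top$variant_id %in% panel$variants$variant_id) next
      if (!pool$variant_id[k] %in% panel$variants$variant_id) next
      if (pool$chrom[k] != top$chrom) next
      if (abs(pool$pos[k] - top$pos) > window_kb * 1000) next
      r <- cor(panel$dosages[, top$variant_id],
               panel$dosages[, pool$variant_id[k]])
      if (r^2 > r2_threshold) keep_row[k] <- FALSE
    }
    pool <- pool[keep_row, , drop = FALSE]
  }
  rownames(kept) <- NULL
  kept
}

# Naive enumeration over causal configurations for a tiny region: each trait
# has no causal variant or exactly one of the m variants.
brute_coloc <- function(lbf1, lbf2, p1, p2, p12) {
  m <- length(lbf1)
  bf1 <- exp(lbf1)
  bf2 <- exp(lbf2)
  mass <- c(H0 = 1, H1 = 0, H2 = 0, H3 = 0, H4 = 0)
  for (i in seq_len(m)) mass["H1"] <- mass["H1"] + p1 * bf1[i]
  for (j in seq_len(m)) mass["H2"] <- mass["H2"] + p2 * bf2[j]
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i == j) {
      mass["H4"] <- mass["H4"] + p12 * bf1[i] * bf2[j]
    } else {
      mass["H3"] <- mass["H3"] + p1 * p2 * bf1[i] * bf2[j]
    }
  }
  mass / sum(mass)
}
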