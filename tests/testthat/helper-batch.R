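# Multi-exposure screening batch built from package primitives: `n_exposures`
# traits over disjoint 3-SNP instrument sets, of which the first `n_causal`
# causally raise a shared continuous outcome by `theta` per SD.
simulate_screen_batch <- function(seed, n_exposures = 20, n_causal = 3,
                                  theta = 0.4, n = 5000, h2 = 0.15) {
  set.seed(seed)
  snps_per <- 3
  m <- n_exposures * snps_per
  maf <- runif(m, 0.1, 0.5)
  vt <- data.frame(variant_id = sprintf("bs_%03d", seq_len(m)),
                   chrom = as.character(rep_len(1:22, m)),
                   pos = as.integer(ave(seq_len(m),
                                        rep_len(1:22, m),
                                        FUN = seq_along) * 11e6),
                   effect_allele = "A", other_allele = "G",
                   stringsAsFactors = FALSE)
  idx <- split(seq_len(m), rep(seq_len(n_exposures), each = snps_per))
  b <- lapply(idx, function(j) {
    raw <- sample(c(-1, 1), snps_per, TRUE) * (0.7 + abs(rnorm(snps_per)))
    raw * sqrt(h2 / sum(raw^2 * 2 * maf[j] * (1 - maf[j])))
  })
  draw_g <- function(nn) matrix(rbinom(nn * m, 2, rep(maf, each = nn)),
                                nn, m)
  scan_df <- function(G, y) {
    s <- fast_linear_gwas(G, y)
    data.frame(vt, eaf = s$eaf, beta = s$beta, se = s$se, pval = s$pval,
               n = s$n, stringsAsFactors = FALSE)
  }
  exposures <- list()
  for (e in seq_len(n_exposures)) {
    G <- draw_g(n)
    x <- as.vector(G[, idx[[e]]] %*% b[[e]]) + rnorm(n, sd = sqrt(1 - h2))
    exposures[[sprintf("exp%02d", e)]] <- scan_df(G, x)
  }
  Gy <- draw_g(n)
  y <- rnorm(n)
  for (e in seq_len(n_causal)) {
    xg <- as.vector(Gy[, idx[[e]]] %*% b[[e]])
    y <- y + theta * (xg + rnorm(n, sd = sqrt(1 - h2)))
  }
  outcome <- scan_df(Gy, y)
  Gp <- draw_g(500)
  panel <- reference_panel(data.frame(variant_id = vt$variant_id,
                                      chrom = vt$chrom, pos = vt$pos,
                                      allele_a = vt$other_allele,
                                      allele_b = vt$effect_allele,
                                      stringsAsFactors = FALSE), Gp)
  list(exposures = exposures, outcome = outcome, panel = panel,
       causal = sprintf("exp%02d", seq_len(n_causal)))
}
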