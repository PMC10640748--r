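# Small deterministic builders shared across test files.

make_assoc <- function(variant_id, beta, se,
                       chrom = "1", pos = seq_along(variant_id) * 1e6,
                       effect_allele = "A", other_allele = "G",
                       eaf = 0.3, pval = NULL, n = 10000) {
  if (is.null(pval)) pval <- 2 * pnorm(-abs(beta / se))
  data.frame(variant_id = variant_id, chrom = chrom, pos = as.integer(pos),
             effect_allele = effect_allele, other_allele = other_allele,
             eaf = eaf, beta = beta, se = se, pval = pval, n = n,
             stringsAsFactors = FALSE)
}

random_assoc <- function(m, seed = 1) {
  set.seed(seed)
  pairs <- matrix(c("A", "G", "T", "C", "C", "A", "G", "T"), ncol = 2,
                  byrow = TRUE)
  k <- sample.int(4, m, replace = TRUE)
  make_assoc(sprintf("rs%03d", seq_len(m)),
             beta = rnorm(m, 0, 0.1), se = runif(m, 0.01, 0.2),
             chrom = as.character(sample(1:3, m, replace = TRUE)),
             pos = sample.int(5e7, m),
             effect_allele = pairs[k, 1], other_allele = pairs[k, 2],
             eaf = runif(m, 0.05, 0.95), n = sample(5000:50000, m, TRUE))
}

# Panel with analytically controlled column correlations: latent AR(1)
# haplotypes, as the simulator's region generator uses.
make_block_panel <- function(n = 2000, m = 8, rho = 0.9, seed = 1,
                             maf = rep(0.3, m), spacing = 1000) {
  set.seed(seed)
  thr <- qnorm(maf)
  hap <- function() {
    Z <- matrix(0, n, m)
    Z[, 1] <- rnorm(n)
    if (m > 1) for (j in 2:m) Z[, j] <- rho * Z[, j - 1] +
        sqrt(1 - rho^2) * rnorm(n)
    sweep(Z, 2, thr, "<") + 0
  }
  dos <- hap() + hap()
  variants <- data.frame(variant_id = sprintf("pv%02d", seq_len(m)),
                         chrom = "1", pos = as.integer(1e6 + spacing *
                                                         (seq_len(m) - 1)),
                         allele_a = "G", allele_b = "A",
                         stringsAsFactors = FALSE)
  reference_panel(variants, dos)
}

# A harmonised-instrument table straight from known effect vectors.
make_harmonised <- function(bx, bxse, by, byse) {
  data.frame(variant_id = sprintf("h%03d", seq_along(bx)),
             effect_allele = "A", other_allele = "G",
             exposure_beta = bx, exposure_se = bxse, exposure_eaf = 0.3,
             outcome_beta = by, outcome_se = byse, outcome_eaf = 0.3,
             action = "kept", drop_reason = "", proxy_of = "",
             stringsAsFactors = FALSE)
}

make_input <- function(bx, bxse, by, byse) {
  mr_input(make_harmonised(bx, bxse, by, byse))
}
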