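## Synthetic two-sample GWAS cohorts with known causal structure.
##
## The generator produces individual-level cohorts and reduces them to
## summary statistics with the same per-variant regressions a GWAS would
## run, so every downstream stage (selection, clumping, harmonisation,
## estimation, mediation, colocalization, conditional scan) is exercised on
## data whose truth is known.

NONPALINDROMIC_PAIRS <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C",
                                 "G", "A", "C", "A", "G", "T", "C", "T"),
                               ncol = 2, byrow = TRUE)

#' Simulation configuration
#'
#' Defaults describe the study conditions the package targets: two
#' non-overlapping cohorts of 20,000, a polygenic continuous exposure in SD
#' units instrumented by 30 variants explaining 20% of its variance, and a
#' rare binary outcome (prevalence 2%, the DVT-like case fraction) analysed
#' on the log-odds scale. Effect-size magnitudes are drawn as
#' `0.7 + |N(0,1)|` with random sign, so every causal variant is a
#' plausibly discoverable instrument rather than a near-null straggler.
#'
#' @param seed RNG seed; the generator is fully deterministic given the
#'   config.
#' @param n_exposure,n_outcome,n_panel Cohort sizes (exposure GWAS, outcome
#'   GWAS, held-out LD reference panel).
#' @param m_snps Total simulated variants; the first `n_causal` are causal
#'   for the exposure.
#' @param n_causal Number of exposure-causal variants.
#' @param maf_range Minor-allele-frequency range, uniform draw.
#' @param h2_exposure Exposure variance explained by the causal variants.
#' @param theta Causal exposure-to-outcome effect (per SD of exposure; on
#'   the log-odds scale for a binary outcome).
#' @param confounder_exposure,confounder_outcome Effects of a shared
#'   standard-normal confounder on exposure and outcome.
#' @param pleiotropy `"none"`, `"balanced"` (direct variant-outcome effects
#'   centred on zero) or `"directional"` (centred on `pleiotropy_magnitude`).
#' @param pleiotropy_magnitude Scale of the direct effects.
#' @param outcome_type `"binary"` or `"continuous"`.
#' @param prevalence Target case fraction for a binary outcome; the
#'   logistic intercept is solved numerically to hit it.
#' @param mediation List of `step1` (exposure to mediator), `step2`
#'   (mediator to outcome), `direct` (residual direct exposure-outcome
#'   path), `m_mediator_snps`, `h2_mediator` for mediator-specific
#'   instruments.
#' @param region List of `m_variants`, `spacing_bp`, `rho` (latent AR(1) LD
#'   decay), `sharing` (`"shared"`, `"distinct"` or `"none"`),
#'   `n_per_trait`, `z_target` (expected association z at the causal
#'   variant).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_exposure = 20000, n_outcome = 20000, n_panel = 2000,
                       m_snps = 60, n_causal = 30,
                       maf_range = c(0.05, 0.5),
                       h2_exposure = 0.2,
                       theta = 0.4,
                       confounder_exposure = 0.3, confounder_outcome = 0.2,
                       pleiotropy = c("none", "balanced", "directional"),
                       pleiotropy_magnitude = 0.05,
                       outcome_type = c("binary", "continuous"),
                       prevalence = 0.02,
                       mediation = list(step1 = 0.3, step2 = 0.4, direct = 0,
                                        m_mediator_snps = 30,
                                        h2_mediator = 0.2),
                       region = list(m_variants = 100, spacing_bp = 5000,
                                     rho = 0.9, sharing = "shared",
                                     n_per_trait = 10000, z_target = 8)) {
  pleiotropy <- match.arg(pleiotropy)
  outcome_type <- match.arg(outcome_type)
  stopifnot(prevalence > 0, prevalence < 0.5,
            h2_exposure > 0, h2_exposure < 1,
            n_causal <= m_snps,
            maf_range[1] > 0, maf_range[2] <= 0.5)
  defaults_med <- list(step1 = 0.3, step2 = 0.4, direct = 0,
                       m_mediator_snps = 30, h2_mediator = 0.2)
  defaults_reg <- list(m_variants = 100, spacing_bp = 5000, rho = 0.9,
                       sharing = "shared", n_per_trait = 10000, z_target = 8)
  mediation <- utils::modifyList(defaults_med, mediation)
  region <- utils::modifyList(defaults_reg, region)
  stopifnot(region$sharing %in% c("shared", "distinct", "none"))
  structure(list(seed = seed, n_exposure = n_exposure, n_outcome = n_outcome,
                 n_panel = n_panel, m_snps = m_snps, n_causal = n_causal,
                 maf_range = maf_range, h2_exposure = h2_exposure,
                 theta = theta,
                 confounder_exposure = confounder_exposure,
                 confounder_outcome = confounder_outcome,
                 pleiotropy = pleiotropy,
                 pleiotropy_magnitude = pleiotropy_magnitude,
                 outcome_type = outcome_type, prevalence = prevalence,
                 mediation = mediation, region = region),
            class = "sim_config")
}

# Variant metadata for m independent variants: round-robin over autosomes,
# spaced 11 Mb apart within a chromosome so they fall outside any clumping
# window of each other.
independent_variant_table <- function(m, maf) {
  chrom <- as.character(rep_len(1:22, m))
  idx_within <- stats::ave(seq_len(m), chrom, FUN = seq_along)
  pair <- NONPALINDROMIC_PAIRS[sample.int(nrow(NONPALINDROMIC_PAIRS), m,
                                          replace = TRUE), , drop = FALSE]
  data.frame(variant_id = sprintf("snp_%04d", seq_len(m)),
             chrom = chrom, pos = as.integer(idx_within * 11e6),
             effect_allele = pair[, 1], other_allele = pair[, 2],
             maf = maf, stringsAsFactors = FALSE)
}

assoc_from_scan <- function(vt, scan) {
  data.frame(variant_id = vt$variant_id, chrom = vt$chrom, pos = vt$pos,
             effect_allele = vt$effect_allele, other_allele = vt$other_allele,
             eaf = scan$eaf, beta = scan$beta, se = scan$se,
             pval = scan$pval, n = scan$n, stringsAsFactors = FALSE)
}

panel_from_variants <- function(vt, dosages) {
  reference_panel(data.frame(variant_id = vt$variant_id, chrom = vt$chrom,
                             pos = vt$pos, allele_a = vt$other_allele,
                             allele_b = vt$effect_allele,
                             stringsAsFactors = FALSE),
                  dosages)
}

draw_genotypes <- function(n, maf) {
  m <- length(maf)
  matrix(stats::rbinom(n * m, 2, rep(maf, each = n)), nrow = n, ncol = m)
}

# Effect sizes scaled so the genetic score explains h2 of a unit-variance
# trait given the allele frequencies.
scaled_effects <- function(raw, maf, h2) {
  var_raw <- sum(raw^2 * 2 * maf * (1 - maf))
  raw * sqrt(h2 / var_raw)
}

# Logistic intercept hitting the target prevalence on the realised sample.
solve_intercept <- function(eta, prevalence) {
  f <- function(a) mean(stats::plogis(a + eta)) - prevalence
  lo <- stats::qlogis(prevalence) - 10
  hi <- stats::qlogis(prevalence) + 10
  if (f(lo) > 0 || f(hi) < 0) {
    stop_mrphewas("target prevalence unreachable at these effect sizes",
                  "mrphewas_configuration_error")
  }
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Simulate a two-sample GWAS pair with known causal effect
#'
#' Draws disjoint exposure and outcome cohorts (plus a held-out reference
#' panel) over independent variants, builds a unit-variance exposure from a
#' genetic score, a shared confounder and noise, builds the outcome from the
#' causal effect `theta`, the confounder and optional direct (pleiotropic)
#' variant effects, and reduces each cohort to per-variant summary
#' statistics by linear (exposure) and linear or logistic (outcome)
#' regression.
#'
#' @param config A [sim_config()].
#' @return A list `exposure`, `outcome` (variant-association data.frames),
#'   `panel` (a [reference_panel()]), and `truth` (generative parameters:
#'   per-variant exposure effects, pleiotropic effects, causal ids, realised
#'   case fraction for a binary outcome).
#' @export
simulate_two_sample <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  m <- config$m_snps
  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  vt <- independent_variant_table(m, maf)
  causal <- seq_len(config$n_causal)
  b <- rep(0, m)
  b[causal] <- scaled_effects(
    sample(c(-1, 1), config$n_causal, replace = TRUE) *
      (0.7 + abs(stats::rnorm(config$n_causal))),
    maf[causal], config$h2_exposure)

  a <- rep(0, m)  # direct variant-outcome effects
  if (config$pleiotropy == "balanced") {
    a[causal] <- stats::runif(config$n_causal, -config$pleiotropy_magnitude,
                              config$pleiotropy_magnitude)
  } else if (config$pleiotropy == "directional") {
    a[causal] <- stats::runif(config$n_causal, 0,
                              2 * config$pleiotropy_magnitude)
  }

  make_exposure <- function(G) {
    n <- nrow(G)
    C <- stats::rnorm(n)
    var_e <- 1 - config$h2_exposure - config$confounder_exposure^2
    if (var_e <= 0) {
      stop_mrphewas("h2_exposure + confounder^2 must stay below 1",
                    "mrphewas_configuration_error")
    }
    x <- as.vector(G %*% b) + config$confounder_exposure * C +
      stats::rnorm(n, sd = sqrt(var_e))
    list(x = x, C = C)
  }

  # Exposure cohort
  Gx <- draw_genotypes(config$n_exposure, maf)
  exp_ph <- make_exposure(Gx)
  exposure <- assoc_from_scan(vt, fast_linear_gwas(Gx, exp_ph$x))

  # Outcome cohort (independent sample)
  Gy <- draw_genotypes(config$n_outcome, maf)
  out_ph <- make_exposure(Gy)
  eta <- config$theta * out_ph$x + config$confounder_outcome * out_ph$C +
    as.vector(Gy %*% a)
  if (config$outcome_type == "binary") {
    alpha <- solve_intercept(eta, config$prevalence)
    y <- stats::rbinom(config$n_outcome, 1, stats::plogis(alpha + eta))
    outcome <- assoc_from_scan(vt, fast_logistic_gwas(Gy, y))
    case_fraction <- mean(y)
  } else {
    y <- eta + stats::rnorm(config$n_outcome,
                            sd = sqrt(max(0.1, 1 - stats::var(eta))))
    outcome <- assoc_from_scan(vt, fast_linear_gwas(Gy, y))
    case_fraction <- NA_real_
  }

  panel <- panel_from_variants(vt, draw_genotypes(config$n_panel, maf))
  truth <- list(theta = config$theta, b = b, pleiotropy = a,
                causal_ids = vt$variant_id[causal], maf = maf,
                case_fraction = case_fraction, config = config)
  list(exposure = exposure, outcome = outcome, panel = panel, truth = truth)
}

#' Simulate an exposure / mediator / outcome summary-statistic triplet
#'
#' Emulates a two-step mediation design: the exposure has its own
#' instruments; the mediator inherits `step1` times the exposure's genetic
#' component and adds mediator-specific instruments; the outcome receives
#' `step2` times the mediator plus an optional residual direct exposure
#' path. Three disjoint cohorts are reduced to summary statistics, one per
#' trait, so all MR steps are honestly two-sample. The generative
#' proportion mediated is `step1*step2 / (step1*step2 + direct)`.
#'
#' @param config A [sim_config()]; the `mediation` block supplies `step1`,
#'   `step2`, `direct` and the mediator-specific architecture.
#' @return A list `exposure`, `mediator`, `outcome` (variant-association
#'   data.frames over the union of both variant sets), `panel`, and `truth`
#'   (including `proportion_mediated`, the ids instrumenting each trait).
#' @export
simulate_mediation_triplet <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  med <- config$mediation
  m_x <- config$m_snps
  m_m <- med$m_mediator_snps
  m <- m_x + m_m
  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  vt <- independent_variant_table(m, maf)
  x_idx <- seq_len(config$n_causal)
  m_idx <- m_x + seq_len(m_m)

  b <- rep(0, m)
  b[x_idx] <- scaled_effects(
    sample(c(-1, 1), config$n_causal, replace = TRUE) *
      (0.7 + abs(stats::rnorm(config$n_causal))),
    maf[x_idx], config$h2_exposure)
  cc <- rep(0, m)
  cc[m_idx] <- scaled_effects(
    sample(c(-1, 1), m_m, replace = TRUE) * (0.7 + abs(stats::rnorm(m_m))),
    maf[m_idx], med$h2_mediator)

  var_ex <- 1 - config$h2_exposure - config$confounder_exposure^2
  var_em <- 1 - med$step1^2 * config$h2_exposure - med$h2_mediator
  if (var_ex <= 0 || var_em <= 0) {
    stop_mrphewas("mediation variance budget exceeds 1",
                  "mrphewas_configuration_error")
  }

  draw_cohort <- function(n) {
    G <- draw_genotypes(n, maf)
    C <- stats::rnorm(n)
    xg <- as.vector(G %*% b)
    x <- xg + config$confounder_exposure * C +
      stats::rnorm(n, sd = sqrt(var_ex))
    m_trait <- med$step1 * xg + as.vector(G %*% cc) +
      stats::rnorm(n, sd = sqrt(var_em))
    y_lin <- med$step2 * m_trait + med$direct * x +
      config$confounder_outcome * C
    list(G = G, x = x, m = m_trait, y_lin = y_lin)
  }

  c1 <- draw_cohort(config$n_exposure)
  exposure <- assoc_from_scan(vt, fast_linear_gwas(c1$G, c1$x))
  c2 <- draw_cohort(config$n_exposure)
  mediator <- assoc_from_scan(vt, fast_linear_gwas(c2$G, c2$m))
  c3 <- draw_cohort(config$n_outcome)
  if (config$outcome_type == "binary") {
    alpha <- solve_intercept(c3$y_lin, config$prevalence)
    y <- stats::rbinom(length(c3$y_lin), 1, stats::plogis(alpha + c3$y_lin))
    outcome <- assoc_from_scan(vt, fast_logistic_gwas(c3$G, y))
  } else {
    y <- c3$y_lin + stats::rnorm(length(c3$y_lin),
                                 sd = sqrt(max(0.1, 1 - stats::var(c3$y_lin))))
    outcome <- assoc_from_scan(vt, fast_linear_gwas(c3$G, y))
  }

  panel <- panel_from_variants(vt, draw_genotypes(config$n_panel, maf))
  denom <- med$step1 * med$step2 + med$direct
  truth <- list(step1 = med$step1, step2 = med$step2, direct = med$direct,
                proportion_mediated = if (denom == 0) NA_real_ else
                  100 * med$step1 * med$step2 / denom,
                exposure_instrument_ids = vt$variant_id[x_idx],
                mediator_instrument_ids = vt$variant_id[m_idx],
                config = config)
  list(exposure = exposure, mediator = mediator, outcome = outcome,
       panel = panel, truth = truth)
}

# Dosages for an LD block: two latent AR(1) Gaussian haplotypes per
# individual thresholded at the allele frequency, giving LD that decays as
# rho^|i-j| on the latent scale.
draw_ld_block <- function(n, maf, rho) {
  m <- length(maf)
  thr <- stats::qnorm(maf)
  hap <- function() {
    Z <- matrix(0, n, m)
    Z[, 1] <- stats::rnorm(n)
    for (j in 2:m) {
      Z[, j] <- rho * Z[, j - 1] + sqrt(1 - rho^2) * stats::rnorm(n)
    }
    sweep(Z, 2, thr, "<") + 0
  }
  hap() + hap()
}

#' Simulate a pair of regional association profiles over one LD block
#'
#' Builds a single LD block (latent AR(1) correlation `rho^|i-j|`) and two
#' independent cohorts, each measuring one quantitative trait with at most
#' one causal variant in the region: the same variant for both traits
#' (`sharing = "shared"`), two well-separated variants (`"distinct"`), or
#' none (`"none"`). The causal effect size targets an association z-score
#' of `z_target` at the causal variant. Feeds the colocalization and
#' conditional-scan machinery.
#'
#' @param config A [sim_config()]; the `region` block supplies the shape.
#' @return A list `trait1`, `trait2` (variant-association data.frames),
#'   `panel`, and `truth` (`causal1`, `causal2` variant ids or `NA`).
#' @export
simulate_region_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  reg <- config$region
  m <- reg$m_variants
  maf <- stats::runif(m, max(config$maf_range[1], 0.1), config$maf_range[2])
  pair <- NONPALINDROMIC_PAIRS[sample.int(nrow(NONPALINDROMIC_PAIRS), m,
                                          replace = TRUE), , drop = FALSE]
  vt <- data.frame(variant_id = sprintf("rv_%04d", seq_len(m)),
                   chrom = "1",
                   pos = as.integer(1e6 + (seq_len(m) - 1) * reg$spacing_bp),
                   effect_allele = pair[, 1], other_allele = pair[, 2],
                   maf = maf, stringsAsFactors = FALSE)
  i1 <- if (reg$sharing == "none") NA_integer_ else round(m * 0.4)
  i2 <- switch(reg$sharing, shared = i1, distinct = round(m * 0.8),
               none = NA_integer_)

  sim_trait <- function(ci) {
    G <- draw_ld_block(reg$n_per_trait, maf, reg$rho)
    y <- stats::rnorm(reg$n_per_trait)
    if (!is.na(ci)) {
      sd_g <- stats::sd(G[, ci])
      beta <- reg$z_target / (sd_g * sqrt(reg$n_per_trait))
      y <- y + beta * G[, ci]
    }
    assoc_from_scan(vt, fast_linear_gwas(G, y))
  }
  trait1 <- sim_trait(i1)
  trait2 <- sim_trait(i2)
  panel <- panel_from_variants(vt, draw_ld_block(config$n_panel, maf, reg$rho))
  truth <- list(sharing = reg$sharing,
                causal1 = if (is.na(i1)) NA_character_ else vt$variant_id[i1],
                causal2 = if (is.na(i2)) NA_character_ else vt$variant_id[i2],
                config = config)
  list(trait1 = trait1, trait2 = trait2, panel = panel, truth = truth)
}
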