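## Batch MR screening across many exposures, spectral multiple-testing
## correction, and reverse-direction MR.

screen_row_names <- c("exposure_id", "outcome_id", "method", "nsnp", "beta",
                      "se", "ci_low", "ci_high", "pval", "q_pval",
                      "ml_het_pval", "egger_intercept", "egger_intercept_pval",
                      "n_selected", "n_dropped", "n_proxied",
                      "harmonisation_failed", "passes_threshold", "error")

empty_screen_row <- function(exposure_id, outcome_id, n_selected = 0L,
                             harmonisation_failed = FALSE, error = "") {
  data.frame(exposure_id = exposure_id, outcome_id = outcome_id,
             method = NA_character_, nsnp = NA_integer_, beta = NA_real_,
             se = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
             pval = NA_real_, q_pval = NA_real_, ml_het_pval = NA_real_,
             egger_intercept = NA_real_, egger_intercept_pval = NA_real_,
             n_selected = n_selected, n_dropped = n_selected,
             n_proxied = 0L,
             harmonisation_failed = harmonisation_failed,
             passes_threshold = NA, error = error,
             stringsAsFactors = FALSE)
}

# One exposure-outcome MR chain: select -> clump -> harmonise -> estimate
# -> sensitivity statistics. Never throws for per-exposure analysis
# failures; they are captured in the `error` column.
screen_one <- function(exposure_id, exposure_stats, outcome_id, outcome_stats,
                       panel, config) {
  tryCatch({
    inst <- select_instruments(exposure_stats, config$instrument_p)
    if (nrow(inst) == 0) {
      return(empty_screen_row(exposure_id, outcome_id, 0L,
                              error = "no_instruments"))
    }
    inst <- clump(inst, panel, config$clump_r2, config$clump_window_kb)
    harm <- harmonise(inst, outcome_stats, panel, config$proxy_r2_min,
                      config$clump_window_kb, config$palindrome_eaf_window)
    usable <- harm[harm$action != "dropped", , drop = FALSE]
    if (nrow(usable) == 0) {
      return(empty_screen_row(exposure_id, outcome_id, nrow(inst),
                              harmonisation_failed = TRUE,
                              error = "all_instruments_dropped"))
    }
    input <- mr_input(usable)
    nsnp <- nrow(usable)
    est <- if (nsnp == 1) {
      wald_ratio(usable[1, , drop = FALSE])
    } else {
      ivw(input)
    }
    q_pval <- ml_het_pval <- NA_real_
    eg_int <- eg_int_p <- NA_real_
    if (nsnp >= 2) {
      q_pval <- cochran_q(input)$pval
      ml_het_pval <- max_likelihood(input)$heterogeneity$pval
    }
    if (nsnp >= 3) {
      eg <- egger(input)
      eg_int <- eg$intercept
      eg_int_p <- eg$intercept_pval
    }
    data.frame(exposure_id = exposure_id, outcome_id = outcome_id,
               method = est$method, nsnp = nsnp, beta = est$beta,
               se = est$se, ci_low = est$ci_low, ci_high = est$ci_high,
               pval = est$pval, q_pval = q_pval, ml_het_pval = ml_het_pval,
               egger_intercept = eg_int, egger_intercept_pval = eg_int_p,
               n_selected = nrow(inst),
               n_dropped = sum(harm$action == "dropped"),
               n_proxied = sum(nzchar(harm$proxy_of)),
               harmonisation_failed = FALSE, passes_threshold = NA,
               error = "", stringsAsFactors = FALSE)
  }, error = function(e) {
    empty_screen_row(exposure_id, outcome_id, error = conditionMessage(e))
  })
}

resolve_stats <- function(x) {
  if (is.character(x)) read_summary_stats(x) else validate_assoc(x)
}

#' Phenome-wide MR screen of many exposures against one outcome
#'
#' For each exposure: select genome-wide significant instruments, clump
#' them against the reference panel, harmonise against the outcome (with
#' proxy substitution for instruments missing from the outcome dataset),
#' estimate the causal effect (Wald ratio for a single instrument,
#' otherwise IVW), and attach sensitivity statistics (Cochran's Q,
#' maximum-likelihood heterogeneity, MR-Egger intercept where three or more
#' instruments allow it). Exposures whose every instrument is lost in
#' harmonisation are emitted with `harmonisation_failed = TRUE`; any other
#' per-exposure failure is captured in the `error` column and never aborts
#' the batch.
#'
#' @param exposures Named list of variant-association data.frames or file
#'   paths; names are the exposure ids.
#' @param outcome Outcome variant-association data.frame or path.
#' @param panel A [reference_panel()].
#' @param config A [pipeline_config()].
#' @param p_threshold Corrected significance threshold used to fill
#'   `passes_threshold`; typically from [effective_tests()] or
#'   [bonferroni_threshold()]. Defaults to plain Bonferroni over the batch.
#' @param outcome_id Label recorded in the `outcome_id` column.
#' @return data.frame of screen rows, sorted by ascending p-value (failed
#'   rows last).
#' @export
run_screen <- function(exposures, outcome, panel, config = pipeline_config(),
                       p_threshold = NULL, outcome_id = "outcome") {
  stopifnot(length(exposures) >= 1, !is.null(names(exposures)))
  outcome_stats <- resolve_stats(outcome)
  rows <- lapply(names(exposures), function(id) {
    screen_one(id, resolve_stats(exposures[[id]]), outcome_id, outcome_stats,
               panel, config)
  })
  res <- do.call(rbind, rows)
  if (is.null(p_threshold)) p_threshold <- config$alpha / length(exposures)
  res$passes_threshold <- !is.na(res$pval) & res$pval < p_threshold
  res <- res[order(res$pval, res$exposure_id, na.last = TRUE), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "p_threshold") <- p_threshold
  res
}

#' Effective number of independent tests by spectral decomposition
#'
#' Estimates the trait-trait correlation matrix as the Pearson correlation
#' of per-trait z-score columns over a common set of independent variants,
#' eigen-decomposes it, and converts the eigenvalue spectrum into an
#' effective test count: Nyholt's spectral decomposition
#' `meff = 1 + (M-1)*(1 - var(lambda)/M)` or the Li-Ji estimator
#' `meff = sum(I(lambda >= 1) + (lambda - floor(lambda)))`. The corrected
#' significance threshold is `alpha / meff`, never below the plain
#' Bonferroni `alpha / M`.
#'
#' @param z_table Numeric matrix of z-scores, shared variants x traits.
#' @param method `"nyholt_spd"` (default) or `"li_ji"`.
#' @param alpha Family-wise level to convert into a threshold.
#' @return A list with `m_traits`, `eigenvalues` (descending), `meff`,
#'   `threshold`, `method`.
#' @export
effective_tests <- function(z_table, method = c("nyholt_spd", "li_ji"),
                            alpha = 0.05) {
  method <- match.arg(method)
  z_table <- as.matrix(z_table)
  M <- ncol(z_table)
  if (M < 2) {
    stop_mrphewas("effective_tests needs at least 2 traits",
                  "mrphewas_input_error")
  }
  if (nrow(z_table) < 30) {
    warning(sprintf("only %d shared variants; trait correlations will be noisy",
                    nrow(z_table)))
  }
  R <- stats::cor(z_table)
  if (any(!is.finite(R))) {
    stop_mrphewas("non-finite trait correlations", "mrphewas_data_error")
  }
  lambda <- sort(eigen(R, symmetric = TRUE, only.values = TRUE)$values,
                 decreasing = TRUE)
  meff <- switch(method,
    nyholt_spd = 1 + (M - 1) * (1 - stats::var(lambda) / M),
    li_ji = {
      al <- abs(lambda)
      sum((al >= 1) + (al - floor(al)))
    })
  meff <- min(max(meff, 1), M)
  list(m_traits = M, eigenvalues = lambda, meff = meff,
       threshold = alpha / meff, method = method)
}

#' Build a variant-by-trait z-score table over shared variants
#'
#' Helper feeding [effective_tests()]: intersects the variant ids of all
#' supplied summary-statistic sets and returns the matrix of z-scores
#' (`beta/se`) over the intersection.
#'
#' @param traits Named list of variant-association data.frames.
#' @return Numeric matrix, shared variants x traits.
#' @export
exposure_z_table <- function(traits) {
  stats_list <- lapply(traits, validate_assoc)
  shared <- Reduce(intersect, lapply(stats_list, `[[`, "variant_id"))
  if (length(shared) == 0) {
    stop_mrphewas("no variants shared by all traits", "mrphewas_data_error")
  }
  z <- vapply(stats_list, function(s) {
    s <- s[match(shared, s$variant_id), ]
    s$beta / s$se
  }, numeric(length(shared)))
  rownames(z) <- shared
  z
}

#' Reverse-direction MR screen
#'
#' Runs the identical screening machinery with the roles swapped: the
#' former outcome trait supplies the instruments and each former exposure
#' is analysed as an outcome. A forward hit whose reverse estimate also
#' passes `reverse_p_threshold` is flagged as possible reverse causation.
#'
#' @param outcome_as_exposure Summary statistics of the disease trait, now
#'   used as the exposure (data.frame or path).
#' @param former_exposures Named list of the traits to screen as outcomes.
#' @param panel A [reference_panel()].
#' @param config A [pipeline_config()].
#' @param reverse_p_threshold Threshold for the reverse-causation flag;
#'   defaults to the forward corrected threshold passed by the caller, or
#'   0.05 if none.
#' @param exposure_id Label for the instrumenting trait.
#' @return data.frame of screen rows (one per former exposure, identified
#'   by `outcome_id`) with an extra `possible_reverse_causation` column.
#' @export
reverse_screen <- function(outcome_as_exposure, former_exposures, panel,
                           config = pipeline_config(),
                           reverse_p_threshold = 0.05,
                           exposure_id = "outcome_trait") {
  stopifnot(length(former_exposures) >= 1, !is.null(names(former_exposures)))
  expo_stats <- resolve_stats(outcome_as_exposure)
  rows <- lapply(names(former_exposures), function(id) {
    screen_one(exposure_id, expo_stats, id,
               resolve_stats(former_exposures[[id]]), panel, config)
  })
  res <- do.call(rbind, rows)
  res$passes_threshold <- !is.na(res$pval) & res$pval < reverse_p_threshold
  res$possible_reverse_causation <- res$passes_threshold
  rownames(res) <- NULL
  attr(res, "p_threshold") <- reverse_p_threshold
  res
}
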