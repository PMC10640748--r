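## Two-step MR mediation: indirect effect through a mediating trait and the
## proportion of the total effect it accounts for.

#' Two-step MR mediation by product of coefficients
#'
#' Combines the total exposure-outcome MR estimate with the
#' exposure-mediator effect (`step1`, externally supplied or estimated by
#' MR) and the mediator-outcome MR estimate (`step2`). The indirect effect
#' is `step1 * step2`; the proportion mediated is `100 * indirect / total`
#' on the log-risk (beta) scale. When the indirect and total effects
#' disagree in sign the decomposition is not interpretable: the row is
#' flagged "Effect not consistent" and no proportion is reported.
#' Proportions outside 0-100% (a weak-total-effect pathology) are reported
#' verbatim with a warning rather than truncated. The SE of the indirect
#' effect uses the product delta method
#' `sqrt(step1^2*se2^2 + step2^2*se1^2)`.
#'
#' @param total One-row MR-estimate data.frame for the exposure-outcome
#'   total effect; its beta must be nonzero.
#' @param step1_beta,step1_se Exposure-mediator effect and SE.
#' @param step2 One-row MR-estimate data.frame for the mediator-outcome
#'   effect.
#' @return A list with `indirect`, `indirect_se`, `proportion_pct` (`NA`
#'   when inconsistent), `consistent`, `label`, and the inputs.
#' @export
two_step_mediation <- function(total, step1_beta, step1_se, step2) {
  if (total$beta == 0) {
    stop_mrphewas("proportion mediated undefined: total effect is zero",
                  "mrphewas_undefined_proportion_error")
  }
  indirect <- step1_beta * step2$beta
  indirect_se <- sqrt(step1_beta^2 * step2$se^2 + step2$beta^2 * step1_se^2)
  consistent <- indirect == 0 || sign(indirect) == sign(total$beta)
  proportion <- if (consistent) 100 * indirect / total$beta else NA_real_
  if (consistent && (proportion < 0 || proportion > 100)) {
    warning(sprintf("proportion mediated %.1f%% outside [0, 100]%%: weak or unstable total effect",
                    proportion))
  }
  list(total = total, step1_beta = step1_beta, step1_se = step1_se,
       step2 = step2, indirect = indirect, indirect_se = indirect_se,
       proportion_pct = proportion, consistent = consistent,
       label = if (consistent) "" else "Effect not consistent")
}

#' Run a mediation batch from a mediator manifest
#'
#' For each mediator: select and clump its instruments, harmonise against
#' the outcome, estimate the mediator-outcome effect (Wald ratio or IVW),
#' and combine with the supplied exposure-mediator effect and the total
#' exposure-outcome estimate via [two_step_mediation()]. Mediators whose
#' step-2 p-value misses `step2_p_threshold` (e.g. a Bonferroni level for
#' the mediator family) are reported but flagged not significant.
#'
#' @param total One-row MR-estimate data.frame for the total effect.
#' @param mediators data.frame with columns `mediator_id, step1_beta,
#'   step1_se` plus either `path` (summary-stat TSV) or a list-column
#'   `stats` of variant-association data.frames.
#' @param outcome Outcome variant-association data.frame.
#' @param panel A [reference_panel()] for clumping/proxies.
#' @param config A [pipeline_config()] (thresholds).
#' @param step2_p_threshold Significance level applied to the step-2 MR.
#' @return data.frame, one row per mediator: step-2 estimate, indirect
#'   effect, proportion mediated, consistency label.
#' @export
run_mediation <- function(total, mediators, outcome, panel,
                          config = pipeline_config(),
                          step2_p_threshold = 0.05) {
  rows <- lapply(seq_len(nrow(mediators)), function(i) {
    mid <- mediators$mediator_id[i]
    stats_i <- if ("stats" %in% names(mediators)) {
      mediators$stats[[i]]
    } else {
      read_summary_stats(mediators$path[i])
    }
    base <- data.frame(mediator_id = mid,
                       step1_beta = mediators$step1_beta[i],
                       step1_se = mediators$step1_se[i],
                       stringsAsFactors = FALSE)
    res <- tryCatch({
      inst <- select_instruments(stats_i, config$instrument_p)
      inst <- clump(inst, panel, config$clump_r2, config$clump_window_kb)
      harm <- harmonise(inst, outcome, panel, config$proxy_r2_min,
                        config$clump_window_kb)
      input <- mr_input(harm)
      est <- if (length(input$bx) == 1) {
        wald_ratio(input$instruments[1, , drop = FALSE])
      } else {
        ivw(input)
      }
      med <- two_step_mediation(total, mediators$step1_beta[i],
                                mediators$step1_se[i], est)
      cbind(base,
            data.frame(method = est$method, nsnp = est$nsnp,
                       step2_beta = est$beta, step2_se = est$se,
                       step2_pval = est$pval,
                       step2_significant = est$pval < step2_p_threshold,
                       indirect = med$indirect,
                       indirect_se = med$indirect_se,
                       proportion_pct = med$proportion_pct,
                       consistent = med$consistent, label = med$label,
                       error = "", stringsAsFactors = FALSE))
    }, error = function(e) {
      cbind(base,
            data.frame(method = NA_character_, nsnp = NA_integer_,
                       step2_beta = NA_real_, step2_se = NA_real_,
                       step2_pval = NA_real_, step2_significant = NA,
                       indirect = NA_real_, indirect_se = NA_real_,
                       proportion_pct = NA_real_, consistent = NA,
                       label = "", error = conditionMessage(e),
                       stringsAsFactors = FALSE))
    })
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
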