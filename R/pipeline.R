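## Configuration-driven orchestration of the full study: forward screen,
## reverse MR, mediation, and regional (conditional + colocalization)
## follow-up of single-instrument hits.

#' Pipeline configuration
#'
#' Thresholds and stage toggles for [run_pipeline()]. Defaults are the
#' conventional values for this analysis: instruments at genome-wide
#' significance 5e-8, clumping at r-squared 0.001 in a 10,000 kb window,
#' proxies at r-squared > 0.8, spectral-decomposition multiple-testing
#' correction at family-wise level 0.05, a 500 kb colocalization window and
#' a 1 Mb conditional window.
#'
#' @param instrument_p Instrument selection p-value threshold, in (0, 1).
#' @param clump_r2 Clumping r-squared threshold, in \\[0, 1\\).
#' @param clump_window_kb Clumping window, kb.
#' @param proxy_r2_min Minimum proxy r-squared, in (0, 1).
#' @param palindrome_eaf_window Harmonisation frequency ambiguity
#'   half-width.
#' @param correction_method `"nyholt_spd"`, `"li_ji"`, or `"bonferroni"`.
#' @param alpha Family-wise significance level.
#' @param coloc_window_kb Half-window around an index variant for
#'   colocalization, kb.
#' @param conditional_window_kb Half-window for the conditional scan, kb.
#' @param stages Character vector of enabled stages, a subset of
#'   `c("screen", "reverse", "mediate", "regional")`.
#' @param seed Seed recorded for provenance.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(instrument_p = 5e-8, clump_r2 = 0.001,
                            clump_window_kb = 10000, proxy_r2_min = 0.8,
                            palindrome_eaf_window = 0.08,
                            correction_method = "nyholt_spd", alpha = 0.05,
                            coloc_window_kb = 250,
                            conditional_window_kb = 500,
                            stages = c("screen", "reverse", "mediate",
                                       "regional"),
                            seed = 1L) {
  stopifnot(instrument_p > 0, instrument_p < 1,
            clump_r2 >= 0, clump_r2 < 1,
            clump_window_kb > 0, proxy_r2_min > 0, proxy_r2_min < 1,
            palindrome_eaf_window >= 0, palindrome_eaf_window < 0.5,
            alpha > 0, alpha < 1,
            correction_method %in% c("nyholt_spd", "li_ji", "bonferroni"),
            all(stages %in% c("screen", "reverse", "mediate", "regional")))
  structure(list(instrument_p = instrument_p, clump_r2 = clump_r2,
                 clump_window_kb = clump_window_kb,
                 proxy_r2_min = proxy_r2_min,
                 palindrome_eaf_window = palindrome_eaf_window,
                 correction_method = correction_method, alpha = alpha,
                 coloc_window_kb = coloc_window_kb,
                 conditional_window_kb = conditional_window_kb,
                 stages = stages, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; unknown keys are
#' rejected so typos cannot silently fall back to defaults.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop_mrphewas(sprintf("unknown configuration key(s): %s",
                          paste(unknown, collapse = ", ")),
                  "mrphewas_usage_error")
  }
  do.call(pipeline_config, vals)
}

#' Bonferroni-corrected significance threshold
#'
#' `alpha / n_tests`. Reports conventionally round this to one significant
#' figure for display (`signif(x, 1)`); the full-precision value is
#' returned.
#'
#' @param n_tests Number of tests in the family (>= 1).
#' @param alpha Family-wise level, in (0, 1).
#' @return The corrected threshold.
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  if (!is.numeric(n_tests) || length(n_tests) != 1 || n_tests < 1) {
    stop_mrphewas("n_tests must be a positive count",
                  "mrphewas_domain_error")
  }
  stopifnot(alpha > 0, alpha < 1)
  alpha / n_tests
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full screening study
#'
#' Executes the enabled stages in order:
#'
#' 1. **screen** - forward MR-PheWAS of every exposure on the outcome, with
#'    the corrected threshold from the configured multiple-testing method
#'    (spectral decomposition over the exposures' shared-variant z-score
#'    table, or plain Bonferroni);
#' 2. **reverse** - reverse-direction MR of the outcome on every forward
#'    hit, flagging possible reverse causation;
#' 3. **mediate** - two-step mediation of a designated exposure's effect
#'    through the supplied mediators;
#' 4. **regional** - for every single-instrument forward hit, a conditional
#'    scan for secondary signals and an approximate-Bayes-factor
#'    colocalization of the exposure and outcome profiles around the
#'    instrument.
#'
#' Per-stage failures are recorded in the log and do not prevent later
#' independent stages from running. All outputs (screen/reverse/mediation
#' TSVs, per-region JSON and conditional tables, a log with per-stage
#' counts, and a machine-readable summary) are written under `out_dir`, and
#' identical inputs plus configuration yield identical outputs.
#'
#' @param exposures Named list of exposure summary statistics (data.frames
#'   or paths).
#' @param outcome Outcome summary statistics (data.frame or path).
#' @param panel A [reference_panel()].
#' @param out_dir Output directory, created if needed.
#' @param config A [pipeline_config()].
#' @param mediators Optional mediator manifest for [run_mediation()]
#'   (`mediator_id, step1_beta, step1_se` plus `path` or `stats`).
#' @param mediation_exposure Exposure id whose screen estimate is the total
#'   effect for mediation; defaults to the strongest hit.
#' @return A list with the stage results (`screen`, `meff`, `reverse`,
#'   `mediation`, `regional`, `summary`), invisibly; `summary` is also
#'   written as JSON.
#' @export
run_pipeline <- function(exposures, outcome, panel, out_dir,
                         config = pipeline_config(), mediators = NULL,
                         mediation_exposure = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  log_add <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }
  log_add("pipeline start; stages: %s", paste(config$stages, collapse = ", "))
  for (key in c("instrument_p", "clump_r2", "clump_window_kb",
                "proxy_r2_min", "palindrome_eaf_window", "correction_method",
                "alpha", "coloc_window_kb", "conditional_window_kb",
                "seed")) {
    log_add("config %s = %s", key, format(config[[key]]))
  }
  results <- list(screen = NULL, meff = NULL, reverse = NULL,
                  mediation = NULL, regional = NULL)
  failures <- character(0)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      failures <<- c(failures, name)
      log_add("stage %s FAILED: %s", name, conditionMessage(e))
      NULL
    })
  }

  outcome_stats <- resolve_stats(outcome)
  exposure_stats <- lapply(exposures, resolve_stats)

  if ("screen" %in% config$stages) {
    results$screen <- run_stage("screen", {
      threshold <- config$alpha / length(exposures)
      if (config$correction_method != "bonferroni" &&
          length(exposures) >= 2) {
        meff <- tryCatch(
          suppressWarnings(
            effective_tests(exposure_z_table(exposure_stats),
                            config$correction_method, config$alpha)),
          error = function(e) NULL)
        if (!is.null(meff)) {
          results$meff <- meff
          threshold <- meff$threshold
          log_add("meff = %.3f of %d traits (%s); threshold = %.3g",
                  meff$meff, meff$m_traits, meff$method, threshold)
          jsonlite::write_json(
            meff[c("m_traits", "eigenvalues", "meff", "threshold", "method")],
            file.path(out_dir, "meff.json"), auto_unbox = TRUE, digits = NA)
        }
      }
      scr <- run_screen(exposure_stats, outcome_stats, panel, config,
                        p_threshold = threshold)
      log_add("screen: %d exposures, %d hits, %d harmonisation failures, %d proxied instruments, %d dropped instruments",
              nrow(scr), sum(scr$passes_threshold),
              sum(scr$harmonisation_failed), sum(scr$n_proxied),
              sum(scr$n_dropped))
      write_tsv(scr, file.path(out_dir, "screen.tsv"))
      scr
    })
  }
  hits <- if (!is.null(results$screen)) {
    results$screen[results$screen$passes_threshold, , drop = FALSE]
  } else {
    NULL
  }

  if ("reverse" %in% config$stages && !is.null(hits) && nrow(hits) > 0) {
    results$reverse <- run_stage("reverse", {
      thr <- attr(results$screen, "p_threshold")
      rev <- reverse_screen(outcome_stats,
                            exposure_stats[hits$exposure_id], panel, config,
                            reverse_p_threshold = thr)
      log_add("reverse: %d traits tested, %d flagged", nrow(rev),
              sum(rev$possible_reverse_causation))
      write_tsv(rev, file.path(out_dir, "reverse.tsv"))
      rev
    })
  }

  if ("mediate" %in% config$stages && !is.null(mediators) &&
      !is.null(hits) && nrow(hits) > 0) {
    results$mediation <- run_stage("mediate", {
      med_id <- mediation_exposure %||% hits$exposure_id[1]
      total_row <- results$screen[results$screen$exposure_id == med_id, ,
                                  drop = FALSE]
      if (nrow(total_row) == 0 || is.na(total_row$beta[1])) {
        stop_mrphewas(sprintf("no usable total effect for exposure %s",
                              med_id), "mrphewas_input_error")
      }
      med <- run_mediation(total_row[1, , drop = FALSE], mediators,
                           outcome_stats, panel, config,
                           step2_p_threshold =
                             bonferroni_threshold(nrow(mediators),
                                                  config$alpha))
      log_add("mediation (total effect from %s): %d mediators, %d consistent",
              med_id, nrow(med), sum(med$consistent, na.rm = TRUE))
      write_tsv(med, file.path(out_dir, "mediation.tsv"))
      med
    })
  }

  if ("regional" %in% config$stages && !is.null(hits) && nrow(hits) > 0) {
    results$regional <- run_stage("regional", {
      single <- hits[!is.na(hits$nsnp) & hits$nsnp == 1, , drop = FALSE]
      log_add("regional: %d single-instrument hit(s) queued", nrow(single))
      regional <- lapply(single$exposure_id, function(id) {
        stats_i <- exposure_stats[[id]]
        inst <- select_instruments(stats_i, config$instrument_p)
        inst <- clump(inst, panel, config$clump_r2, config$clump_window_kb)
        idx <- inst$variant_id[1]
        in_reg <- function(s, w_kb) {
          ipos <- s$pos[match(idx, s$variant_id)]
          ichr <- s$chrom[match(idx, s$variant_id)]
          s[s$chrom == ichr & abs(s$pos - ipos) <= w_kb * 1000, ,
            drop = FALSE]
        }
        cl <- coloc_abf(in_reg(stats_i, config$coloc_window_kb),
                        in_reg(outcome_stats, config$coloc_window_kb))
        cs <- conditional_scan(in_reg(stats_i, config$conditional_window_kb),
                               panel, idx, config$conditional_window_kb)
        write_tsv(cs$table,
                  file.path(out_dir, sprintf("conditional_%s.tsv", id)))
        jsonlite::write_json(
          list(exposure_id = id, index = idx, pp = as.list(cl$pp),
               nsnp = cl$nsnp, secondary_signal = cs$secondary_signal),
          file.path(out_dir, sprintf("coloc_%s.json", id)),
          auto_unbox = TRUE, digits = NA)
        list(exposure_id = id, index = idx, coloc = cl, conditional = cs)
      })
      names(regional) <- single$exposure_id
      regional
    })
  }

  summary <- list(
    n_exposures = length(exposures),
    n_hits = if (is.null(results$screen)) 0L else
      sum(results$screen$passes_threshold),
    p_threshold = if (is.null(results$screen)) NA else
      attr(results$screen, "p_threshold"),
    reverse_flags = if (is.null(results$reverse)) character(0) else
      results$reverse$outcome_id[results$reverse$possible_reverse_causation],
    consistent_mediators = if (is.null(results$mediation)) character(0) else
      results$mediation$mediator_id[results$mediation$consistent %in% TRUE],
    colocalizing = if (is.null(results$regional)) character(0) else
      names(results$regional)[vapply(results$regional, function(r)
        r$coloc$pp[["PP.H4"]] > 0.8, logical(1))],
    failed_stages = failures)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  log_add("pipeline end; %d failed stage(s)", length(failures))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  results$summary <- summary
  invisible(results)
}
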