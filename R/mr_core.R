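## Two-sample MR estimators and sensitivity statistics on a harmonised
## instrument set.
##
## All estimators consume a `mr_input` built from non-dropped harmonised
## instruments. For a binary outcome the effect is on the log-odds scale,
## reported as a log risk ratio under the rare-outcome approximation.

#' Assemble an MR input from harmonised instruments
#'
#' @param instruments Harmonised-instrument data.frame (from [harmonise()]);
#'   dropped rows are removed here.
#' @param exposure,outcome Optional [trait_info()] metadata.
#' @return An object of class `mr_input` with the estimation vectors
#'   `bx, bxse, by, byse` and the retained instrument table.
#' @export
mr_input <- function(instruments, exposure = NULL, outcome = NULL) {
  inst <- instruments[instruments$action != "dropped", , drop = FALSE]
  if (nrow(inst) < 1) {
    stop_mrphewas("no usable (non-dropped) instruments", "mrphewas_input_error")
  }
  structure(list(exposure = exposure, outcome = outcome,
                 instruments = inst,
                 bx = inst$exposure_beta, bxse = inst$exposure_se,
                 by = inst$outcome_beta, byse = inst$outcome_se),
            class = "mr_input")
}

#' @export
print.mr_input <- function(x, ...) {
  cat(sprintf("<mr_input> %d instruments\n", length(x$bx)))
  invisible(x)
}

mr_estimate <- function(method, beta, se, nsnp) {
  data.frame(method = method, nsnp = nsnp, beta = beta, se = se,
             ci_low = beta - Z95 * se, ci_high = beta + Z95 * se,
             pval = z_pval(beta, se), stringsAsFactors = FALSE)
}

#' Wald-ratio causal estimate from a single instrument
#'
#' The ratio of the outcome to the exposure association, with a first-order
#' delta-method standard error `outcome_se / |exposure_beta|`.
#'
#' @param inst One-row harmonised-instrument data.frame.
#' @return A one-row MR-estimate data.frame (`method, nsnp, beta, se,
#'   ci_low, ci_high, pval`).
#' @export
wald_ratio <- function(inst) {
  stopifnot(nrow(inst) == 1)
  if (inst$exposure_beta == 0) {
    stop_mrphewas("Wald ratio undefined: exposure beta is zero",
                  "mrphewas_division_error")
  }
  beta <- inst$outcome_beta / inst$exposure_beta
  se <- inst$outcome_se / abs(inst$exposure_beta)
  mr_estimate("wald_ratio", beta, se, 1L)
}

#' Inverse-variance weighted causal estimate
#'
#' Weighted regression of the outcome betas on the exposure betas through
#' the origin with weights `1/outcome_se^2`. The standard error uses a
#' multiplicative-dispersion model in which the residual scale may inflate
#' the fixed-effect SE but never deflate it. A single instrument delegates
#' to the Wald ratio.
#'
#' @param input An [mr_input()].
#' @return A one-row MR-estimate data.frame.
#' @export
ivw <- function(input) {
  stopifnot(inherits(input, "mr_input"))
  n <- length(input$bx)
  if (n == 1) return(wald_ratio(input$instruments[1, , drop = FALSE]))
  if (all(input$bx == 0)) {
    stop_mrphewas("all exposure betas are zero", "mrphewas_degenerate_input_error")
  }
  w <- 1 / input$byse^2
  sxx <- sum(w * input$bx^2)
  beta <- sum(w * input$bx * input$by) / sxx
  se_fixed <- sqrt(1 / sxx)
  sigma <- sqrt(sum(w * (input$by - beta * input$bx)^2) / (n - 1))
  mr_estimate("ivw", beta, se_fixed * max(sigma, 1), n)
}

# Weighted least squares with intercept; returns coefficients, their
# unit-dispersion SEs, and the residual scale sigma-hat.
wls_fit <- function(x, y, w) {
  X <- cbind(1, x)
  XtWX <- crossprod(X, w * X)
  XtWy <- crossprod(X, w * y)
  coef <- solve(XtWX, XtWy)
  resid <- y - X %*% coef
  sigma2 <- sum(w * resid^2) / (length(y) - 2)
  se_unit <- unname(sqrt(diag(solve(XtWX))))
  list(intercept = coef[1], slope = coef[2],
       intercept_se_unit = se_unit[1], slope_se_unit = se_unit[2],
       sigma = sqrt(sigma2))
}

#' MR-Egger regression
#'
#' Weighted regression of the outcome betas on the exposure betas with a
#' free intercept, weights `1/outcome_se^2`. The intercept estimates the
#' average directional pleiotropic effect and its p-value is the pleiotropy
#' test. Standard errors are multiplied by the residual scale, floored at 1,
#' so dispersion can only widen them.
#'
#' @param input An [mr_input()] with at least three instruments.
#' @return A list with `slope` (MR-estimate data.frame) and `intercept,
#'   intercept_se, intercept_pval`.
#' @export
egger <- function(input) {
  stopifnot(inherits(input, "mr_input"))
  n <- length(input$bx)
  if (n < 3) {
    stop_mrphewas("MR-Egger needs at least 3 instruments",
                  "mrphewas_insufficient_instruments_error")
  }
  fit <- wls_fit(input$bx, input$by, 1 / input$byse^2)
  scale <- max(fit$sigma, 1)
  slope_se <- fit$slope_se_unit * scale
  int_se <- fit$intercept_se_unit * scale
  list(slope = mr_estimate("egger", fit$slope, slope_se, n),
       intercept = fit$intercept, intercept_se = int_se,
       intercept_pval = z_pval(fit$intercept, int_se))
}

# Profile negative log-likelihood contribution at causal effect theta, the
# per-instrument nuisance means maximised out analytically:
# sum (by - theta*bx)^2 / (byse^2 + theta^2 * bxse^2).
ml_profile_stat <- function(theta, bx, bxse, by, byse) {
  sum((by - theta * bx)^2 / (byse^2 + theta^2 * bxse^2))
}

#' Maximum-likelihood causal estimate with heterogeneity likelihood-ratio test
#'
#' Maximises the joint normal likelihood of the observed exposure and
#' outcome betas over the per-instrument true exposure effects and a single
#' causal effect. The nuisance effects are profiled out analytically,
#' leaving a one-dimensional optimisation; the SE comes from the observed
#' information at the optimum. Heterogeneity is tested by the likelihood
#' ratio against the saturated model that fits every instrument exactly
#' (chi-square, `nsnp - 1` degrees of freedom).
#'
#' @param input An [mr_input()] with at least two instruments.
#' @return A list with `estimate` (MR-estimate data.frame) and
#'   `heterogeneity` (`method, stat, df, pval`).
#' @export
max_likelihood <- function(input) {
  stopifnot(inherits(input, "mr_input"))
  n <- length(input$bx)
  if (n < 2) {
    stop_mrphewas("maximum likelihood needs at least 2 instruments",
                  "mrphewas_insufficient_instruments_error")
  }
  nll <- function(theta) {
    0.5 * ml_profile_stat(theta, input$bx, input$bxse, input$by, input$byse)
  }
  start <- ivw(input)$beta
  opt <- stats::optim(start, nll, method = "Brent",
                      lower = start - 10 - 10 * abs(start),
                      upper = start + 10 + 10 * abs(start),
                      hessian = TRUE)
  if (opt$convergence != 0) {
    stop_mrphewas(sprintf("ML optimisation failed to converge (code %d)",
                          opt$convergence), "mrphewas_estimation_error")
  }
  theta <- opt$par
  info <- opt$hessian[1, 1]
  if (!is.finite(info) || info <= 0) {
    stop_mrphewas("ML observed information not positive definite",
                  "mrphewas_estimation_error")
  }
  se <- sqrt(1 / info)
  stat <- 2 * opt$value  # saturated log-likelihood term is zero
  het <- data.frame(method = "lrt_ml", stat = stat, df = n - 1L,
                    pval = stats::pchisq(stat, n - 1L, lower.tail = FALSE),
                    stringsAsFactors = FALSE)
  list(estimate = mr_estimate("max_likelihood", theta, se, n),
       heterogeneity = het)
}

#' Cochran's Q heterogeneity test for the IVW model
#'
#' Q is the weighted sum of squared deviations of the per-instrument Wald
#' ratios from the fixed-effect IVW estimate, with weights
#' `(exposure_beta/outcome_se)^2`; chi-square with `nsnp - 1` degrees of
#' freedom.
#'
#' @param input An [mr_input()] with at least two instruments.
#' @return A data.frame `method, stat, df, pval`.
#' @export
cochran_q <- function(input) {
  stopifnot(inherits(input, "mr_input"))
  n <- length(input$bx)
  if (n < 2) {
    stop_mrphewas("Cochran's Q needs at least 2 instruments",
                  "mrphewas_insufficient_instruments_error")
  }
  if (all(input$bx == 0)) {
    stop_mrphewas("all exposure betas are zero", "mrphewas_degenerate_input_error")
  }
  w <- (input$bx / input$byse)^2
  r <- input$by / input$bx
  beta_fixed <- sum(w * r) / sum(w)
  q <- sum(w * (r - beta_fixed)^2)
  data.frame(method = "cochran_q_ivw", stat = q, df = n - 1L,
             pval = stats::pchisq(q, n - 1L, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' Convert a log-risk estimate to a risk ratio
#'
#' Exponentiates the causal estimate and its confidence bounds. For a rare
#' binary outcome the log-odds estimate is interpreted as a log risk ratio.
#'
#' @param est A one-row MR-estimate data.frame.
#' @return A list `(rr, rr_ci_low, rr_ci_high)`.
#' @export
to_risk_ratio <- function(est) {
  list(rr = exp(est$beta), rr_ci_low = exp(est$ci_low),
       rr_ci_high = exp(est$ci_high))
}
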