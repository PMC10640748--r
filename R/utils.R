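#' @keywords internal
"_PACKAGE"

## Shared numerical helpers.

# 95% CI multiplier, fixed at qnorm(0.975).
Z95 <- 1.959964

# Two-sided normal p-value from an estimate and its standard error.
# p-values used downstream of file input are always recomputed this way so
# the pipeline is internally consistent; the pval column of a summary-stat
# file is only used for instrument selection.
z_pval <- function(beta, se) {
  2 * stats::pnorm(-abs(beta / se))
}

# log(sum(exp(x))) without overflow.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b, -Inf when the difference is not positive.
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_mrphewas <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "mrphewas_error")))
}
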