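## Vectorised per-variant association scans used by the simulator to turn
## individual-level cohorts into GWAS summary statistics.

#' Per-variant simple linear regression scan
#'
#' Fits `y ~ g` separately for every dosage column by closed form, as a
#' GWAS of a continuous trait would.
#'
#' @param G Dosage matrix, individuals x variants.
#' @param y Numeric phenotype vector.
#' @return data.frame with per-variant `beta, se, pval, eaf, n` (p-values
#'   two-sided normal).
#' @export
fast_linear_gwas <- function(G, y) {
  n <- length(y)
  stopifnot(nrow(G) == n)
  gbar <- colMeans(G)
  Gc <- sweep(G, 2, gbar)
  yc <- y - mean(y)
  sxx <- colSums(Gc^2)
  sxy <- as.vector(crossprod(Gc, yc))
  syy <- sum(yc^2)
  beta <- sxy / sxx
  rss <- pmax(syy - sxy^2 / sxx, 0)
  sigma2 <- rss / (n - 2)
  se <- sqrt(sigma2 / sxx)
  data.frame(beta = beta, se = se, pval = z_pval(beta, se),
             eaf = gbar / 2, n = n)
}

#' Per-variant logistic regression scan
#'
#' Fits `y ~ g` by logistic regression separately for every dosage column,
#' as a GWAS of a binary trait would. All variants are updated together by
#' Newton-Raphson on the two-parameter (intercept, slope) models, so the
#' scan stays fast for thousands of individuals.
#'
#' @param G Dosage matrix, individuals x variants.
#' @param y 0/1 phenotype vector.
#' @param max_iter,tol Newton-Raphson controls.
#' @return data.frame with per-variant `beta, se, pval, eaf, n` on the
#'   log-odds scale.
#' @export
fast_logistic_gwas <- function(G, y, max_iter = 25, tol = 1e-8) {
  n <- length(y)
  m <- ncol(G)
  stopifnot(nrow(G) == n, all(y %in% c(0, 1)))
  a <- rep(stats::qlogis(mean(y)), m)
  b <- rep(0, m)
  for (iter in seq_len(max_iter)) {
    eta <- sweep(sweep(G, 2, b, "*"), 2, a, "+")
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    resid <- y - p
    U1 <- colSums(resid)
    U2 <- colSums(G * resid)
    H11 <- colSums(w)
    H12 <- colSums(G * w)
    H22 <- colSums(G^2 * w)
    det <- H11 * H22 - H12^2
    da <- (H22 * U1 - H12 * U2) / det
    db <- (H11 * U2 - H12 * U1) / det
    a <- a + da
    b <- b + db
    if (max(abs(da), abs(db)) < tol) break
  }
  se <- sqrt(H11 / det)
  data.frame(beta = b, se = se, pval = z_pval(b, se),
             eaf = colMeans(G) / 2, n = n)
}
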