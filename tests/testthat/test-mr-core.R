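# MR estimators and sensitivity statistics.

test_that("Wald ratio arithmetic and its degenerate cases", {
  inst <- make_harmonised(0.5, 0.1, 0.25, 0.05)
  est <- wald_ratio(inst)
  expect_equal(est$beta, 0.5)
  expect_equal(est$se, 0.1)
  expect_equal(est$ci_low, 0.5 - 1.959964 * 0.1)
  expect_identical(est$nsnp, 1L)

  zero <- make_harmonised(0.5, 0.1, 0, 0.05)
  est0 <- wald_ratio(zero)
  expect_equal(est0$beta, 0)
  expect_equal(est0$pval, 1)

  expect_error(wald_ratio(make_harmonised(0, 0.1, 0.2, 0.05)),
               class = "mrphewas_division_error")

  # equals IVW on the singleton set
  set.seed(4)
  for (i in 1:10) {
    one <- make_harmonised(rnorm(1, 0.3, 0.1), runif(1, 0.01, 0.1),
                           rnorm(1, 0.1, 0.05), runif(1, 0.01, 0.1))
    expect_equal(wald_ratio(one)$beta, ivw(mr_input(one))$beta,
                 tolerance = 1e-12)
    expect_equal(wald_ratio(one)$se, ivw(mr_input(one))$se,
                 tolerance = 1e-12)
  }
})

test_that("IVW reduces to the weighted mean of Wald ratios", {
  # two identical instruments: their common ratio
  inp <- make_input(c(0.4, 0.4), c(0.05, 0.05), c(0.16, 0.16), c(0.04, 0.04))
  expect_equal(ivw(inp)$beta, 0.4, tolerance = 1e-12)

  # collinear triple: exact slope, zero heterogeneity
  inp3 <- make_input(c(1, 2, 0.5), c(0.1, 0.1, 0.1),
                     c(0.4, 0.8, 0.2), c(0.1, 0.1, 0.1))
  expect_equal(ivw(inp3)$beta, 0.4, tolerance = 1e-14)
  expect_equal(cochran_q(inp3)$stat, 0, tolerance = 1e-20)

  # closed-form identity on random inputs
  set.seed(7)
  for (i in 1:20) {
    m <- sample(2:30, 1)
    inp <- make_input(rnorm(m, 0.2, 0.1), runif(m, 0.01, 0.1),
                      rnorm(m, 0.05, 0.1), runif(m, 0.01, 0.1))
    w <- (inp$bx / inp$byse)^2
    r <- inp$by / inp$bx
    expect_equal(ivw(inp)$beta, sum(w * r) / sum(w), tolerance = 1e-10)
  }

  expect_error(ivw(make_input(c(0, 0), c(1, 1), c(1, 1), c(1, 1))),
               class = "mrphewas_degenerate_input_error")
})

test_that("Egger regression matches an independent WLS oracle", {
  set.seed(12)
  for (i in 1:10) {
    m <- sample(3:25, 1)
    bx <- rnorm(m, 0.3, 0.15)
    by <- 0.02 + 0.4 * bx + rnorm(m, 0, 0.05)
    byse <- runif(m, 0.02, 0.1)
    eg <- egger(make_input(bx, runif(m, 0.01, 0.05), by, byse))
    fit <- lm(by ~ bx, weights = 1 / byse^2)
    expect_equal(eg$slope$beta, unname(coef(fit)[2]), tolerance = 1e-10)
    expect_equal(eg$intercept, unname(coef(fit)[1]), tolerance = 1e-10)
    # lm SEs embed sigma-hat; the estimator floors the dispersion at 1
    sm <- summary(fit)
    adj <- max(sm$sigma, 1) / sm$sigma
    expect_equal(eg$slope$se, unname(sm$coefficients[2, 2]) * adj,
                 tolerance = 1e-10)
    expect_equal(eg$intercept_se, unname(sm$coefficients[1, 2]) * adj,
                 tolerance = 1e-10)
  }
})

test_that("Egger intercept behaves as a regression intercept", {
  # points exactly on a line through the origin: zero intercept
  bx <- c(0.1, 0.2, 0.3, 0.4)
  eg <- egger(make_input(bx, rep(0.02, 4), 0.5 * bx, rep(0.05, 4)))
  expect_lt(abs(eg$intercept), 1e-10)

  # adding a constant to every outcome beta shifts only the intercept
  by <- 0.5 * bx + c(0.01, -0.02, 0.015, -0.005)
  e1 <- egger(make_input(bx, rep(0.02, 4), by, rep(0.05, 4)))
  e2 <- egger(make_input(bx, rep(0.02, 4), by + 0.03, rep(0.05, 4)))
  expect_equal(e2$intercept, e1$intercept + 0.03, tolerance = 1e-10)
  expect_equal(e2$slope$beta, e1$slope$beta, tolerance = 1e-10)

  expect_error(egger(make_input(c(1, 2), c(1, 1), c(1, 1), c(1, 1))),
               class = "mrphewas_insufficient_instruments_error")
})

test_that("maximum likelihood agrees with a dense grid search", {
  # identical Wald ratios: theta equals the ratio, no heterogeneity
  inp <- make_input(c(0.2, 0.4, 0.5), c(0.02, 0.02, 0.02),
                    c(0.1, 0.2, 0.25), c(0.02, 0.02, 0.02))
  ml <- max_likelihood(inp)
  expect_equal(ml$estimate$beta, 0.5, tolerance = 1e-6)
  expect_lt(ml$heterogeneity$stat, 1e-6)
  expect_equal(ml$heterogeneity$pval, 1, tolerance = 1e-6)
  expect_identical(ml$heterogeneity$df, 2L)

  # grid-search oracle over the profiled objective
  set.seed(31)
  for (i in 1:5) {
    bx <- rnorm(3, 0.3, 0.1)
    by <- 0.4 * bx + rnorm(3, 0, 0.05)
    bxse <- runif(3, 0.02, 0.08)
    byse <- runif(3, 0.02, 0.08)
    inp <- make_input(bx, bxse, by, byse)
    grid <- seq(-2, 2, by = 1e-4)
    prof <- sapply(grid, function(th)
      sum((by - th * bx)^2 / (byse^2 + th^2 * bxse^2)))
    expect_lt(abs(max_likelihood(inp)$estimate$beta - grid[which.min(prof)]),
              1.1e-4)
  }
})

test_that("Cochran's Q follows its hand-computable form", {
  # ratios 0.4 and 0.6 with weights 100 each: Q = 2
  inp <- make_input(c(1, 1), c(0.01, 0.01), c(0.4, 0.6), c(0.1, 0.1))
  q <- cochran_q(inp)
  expect_equal(q$stat, 2, tolerance = 1e-12)
  expect_identical(q$df, 1L)
  # independent one-liner
  expect_equal(q$stat,
               {
                 w <- (c(1, 1) / c(0.1, 0.1))^2
                 r <- c(0.4, 0.6)
                 sum(w * (r - weighted.mean(r, w))^2)
               }, tolerance = 1e-12)

  # identical ratios: Q = 0, p = 1
  same <- make_input(c(1, 2), c(0.1, 0.1), c(0.4, 0.8), c(0.1, 0.1))
  expect_equal(cochran_q(same)$stat, 0, tolerance = 1e-20)
  expect_equal(cochran_q(same)$pval, 1)
})

test_that("estimators are sign-equivariant", {
  set.seed(55)
  bx <- rnorm(10, 0.3, 0.1)
  by <- 0.4 * bx + rnorm(10, 0, 0.03)
  bxse <- runif(10, 0.02, 0.05)
  byse <- runif(10, 0.02, 0.05)
  base_ivw <- ivw(make_input(bx, bxse, by, byse))$beta
  base_ml <- max_likelihood(make_input(bx, bxse, by, byse))$estimate$beta
  # negate exposure betas: estimates negate
  expect_equal(ivw(make_input(-bx, bxse, by, byse))$beta, -base_ivw,
               tolerance = 1e-10)
  expect_equal(max_likelihood(make_input(-bx, bxse, by, byse))$estimate$beta,
               -base_ml, tolerance = 1e-6)
  # negate both: unchanged
  expect_equal(ivw(make_input(-bx, bxse, -by, byse))$beta, base_ivw,
               tolerance = 1e-10)
  expect_equal(max_likelihood(make_input(-bx, bxse, -by, byse))$estimate$beta,
               base_ml, tolerance = 1e-6)
})

test_that("ML and IVW agree closely on strong homogeneous instruments", {
  sim <- simulate_two_sample(sim_config(seed = 314, m_snps = 100,
                                        n_causal = 100, n_panel = 200,
                                        h2_exposure = 0.5,
                                        outcome_type = "continuous"))
  harm <- harmonise(sim$exposure, sim$outcome)
  inp <- mr_input(harm)
  b_ivw <- ivw(inp)$beta
  b_ml <- max_likelihood(inp)$estimate$beta
  expect_lt(abs(b_ml - b_ivw) / abs(b_ivw), 0.02)
})

test_that("risk-ratio conversion exponentiates estimate and bounds", {
  est <- data.frame(beta = 0, se = 0.1, ci_low = -0.196, ci_high = 0.196)
  rr <- to_risk_ratio(est)
  expect_equal(rr$rr, 1)
  expect_equal(rr$rr_ci_low, exp(-0.196))
  expect_lt(rr$rr_ci_low, rr$rr)
})
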