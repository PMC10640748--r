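# Batch screening, effective-test correction, reverse MR.

test_that("effective_tests reproduces hand eigen-algebra", {
  # independent traits: meff = M
  set.seed(1)
  z <- matrix(rnorm(200 * 4), 200, 4)
  z <- scale(z, center = TRUE, scale = FALSE)
  z <- z %*% solve(chol(cov(z)))  # exactly decorrelated columns
  res <- effective_tests(z)
  expect_equal(res$meff, 4, tolerance = 1e-8)
  expect_equal(res$threshold, 0.05 / 4, tolerance = 1e-8)
  expect_equal(sum(res$eigenvalues), 4, tolerance = 1e-8)

  # two perfectly correlated traits: Nyholt meff = 1
  u <- rnorm(50)
  res2 <- effective_tests(cbind(u, u))
  expect_equal(res2$meff, 1, tolerance = 1e-8)

  # exact correlation 0.5: lambda = {1.5, 0.5}, meff = 1.75
  u <- rep(c(1, -1), 8)
  w <- rep(c(1, 1, -1, -1), 4)
  v <- 0.5 * u + sqrt(3) / 2 * w
  expect_warning(res3 <- effective_tests(cbind(u, v)))
  expect_equal(res3$eigenvalues, c(1.5, 0.5), tolerance = 1e-8)
  expect_equal(res3$meff, 1.75, tolerance = 1e-8)
  expect_equal(res3$threshold, 0.05 / 1.75, tolerance = 1e-8)
  # Li-Ji on the same spectrum: f(1.5) + f(0.5) = 1.5 + 0.5 = 2
  # (Li-Ji is conservative for moderate correlation)
  expect_warning(res4 <- effective_tests(cbind(u, v), method = "li_ji"))
  expect_equal(res4$meff, 2, tolerance = 1e-8)
})

test_that("corrected thresholds never beat plain Bonferroni", {
  set.seed(9)
  for (i in 1:10) {
    M <- sample(2:8, 1)
    base <- matrix(rnorm(100 * M), 100, M)
    mix <- matrix(runif(M * M, -0.3, 0.3), M, M)
    diag(mix) <- 1
    z <- base %*% mix
    res <- suppressWarnings(effective_tests(z))
    expect_lte(res$meff, M)
    expect_gte(res$meff, 1)
    expect_gte(res$threshold, 0.05 / M)
    expect_equal(sum(res$eigenvalues), M, tolerance = 1e-8)
  }
  expect_error(effective_tests(matrix(1:10, ncol = 1)),
               class = "mrphewas_input_error")
})

test_that("a one-exposure screen equals the manual operation chain", {
  sim <- simulate_two_sample(sim_config(seed = 71, n_exposure = 4000,
                                        n_outcome = 4000, n_panel = 500,
                                        m_snps = 30, n_causal = 15,
                                        outcome_type = "continuous"))
  cfg <- pipeline_config()
  scr <- run_screen(list(trait = sim$exposure), sim$outcome, sim$panel, cfg)
  expect_identical(nrow(scr), 1L)

  inst <- select_instruments(sim$exposure, cfg$instrument_p)
  inst <- clump(inst, sim$panel, cfg$clump_r2, cfg$clump_window_kb)
  harm <- harmonise(inst, sim$outcome, sim$panel, cfg$proxy_r2_min,
                    cfg$clump_window_kb)
  est <- ivw(mr_input(harm))
  expect_equal(scr$beta, est$beta, tolerance = 1e-12)
  expect_equal(scr$se, est$se, tolerance = 1e-12)
  expect_identical(scr$nsnp, est$nsnp)
  expect_equal(scr$q_pval, cochran_q(mr_input(harm))$pval, tolerance = 1e-12)
})

test_that("exposures sharing no variants with the outcome fail harmonisation", {
  expo <- make_assoc(c("x1", "x2"), c(0.3, -0.25), c(0.02, 0.02),
                     pval = c(1e-40, 1e-30))
  outc <- make_assoc(c("y1", "y2"), c(0.1, 0.1), c(0.05, 0.05))
  panel <- make_block_panel(n = 200, m = 2, seed = 1)
  scr <- run_screen(list(orphan = expo), outc, panel)
  expect_true(scr$harmonisation_failed)
  expect_true(is.na(scr$beta))
  expect_identical(scr$error, "all_instruments_dropped")
})

test_that("causal exposures dominate the top of the screen ranking", {
  top5_hits <- integer(0)
  for (seed in 1:30) {
    batch <- simulate_screen_batch(seed, n_exposures = 20, n_causal = 3,
                                   theta = 0.4, n = 5000)
    scr <- run_screen(batch$exposures, batch$outcome, batch$panel)
    top5 <- scr$exposure_id[1:5]
    top5_hits <- c(top5_hits, sum(batch$causal %in% top5))
  }
  # the 3 causal exposures rank in the top 5 in >= 90% of runs
  expect_gte(mean(top5_hits == 3), 0.9)
})

test_that("reverse screening distinguishes direction", {
  # X -> Y only, binary rare outcome: the disease trait's per-variant
  # associations (theta * b_j on the log-odds scale) stay far below
  # genome-wide significance, so instruments exist in one direction only.
  fwd_p <- rev_p <- mir_rev_p <- mir_fwd_p <- numeric(0)
  for (seed in 1:10) {
    sim <- simulate_two_sample(sim_config(seed = 600 + seed,
                                          n_outcome = 40000, n_panel = 300))
    fwd <- run_screen(list(x = sim$exposure), sim$outcome, sim$panel)
    rev <- reverse_screen(sim$outcome, list(x = sim$exposure), sim$panel)
    fwd_p <- c(fwd_p, fwd$pval)
    rev_p <- c(rev_p, rev$pval)
    # mirrored roles: the trait with instruments is the one detected
    mir_rev_p <- c(mir_rev_p,
                   reverse_screen(sim$exposure, list(y = sim$outcome),
                                  sim$panel)$pval)
    mir_fwd_p <- c(mir_fwd_p,
                   run_screen(list(y = sim$outcome), sim$exposure,
                              sim$panel)$pval)
  }
  expect_gte(mean(fwd_p < 0.05, na.rm = TRUE), 0.9)
  expect_gte(mean(is.na(rev_p) | rev_p > 0.05), 0.9)
  expect_gte(mean(mir_rev_p < 0.05, na.rm = TRUE), 0.9)
  expect_gte(mean(is.na(mir_fwd_p) | mir_fwd_p > 0.05), 0.9)
})

test_that("swapping roles twice reproduces the forward screen", {
  sim <- simulate_two_sample(sim_config(seed = 88, n_exposure = 4000,
                                        n_outcome = 4000, n_panel = 300,
                                        m_snps = 20, n_causal = 10,
                                        outcome_type = "continuous"))
  fwd <- run_screen(list(x = sim$exposure), sim$outcome, sim$panel)
  back <- reverse_screen(sim$exposure, list(x = sim$outcome), sim$panel,
                         reverse_p_threshold = attr(fwd, "p_threshold"))
  for (col in c("method", "nsnp", "beta", "se", "pval")) {
    expect_equal(back[[col]], fwd[[col]], tolerance = 1e-14)
  }
})
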