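# Summary-statistic I/O, instrument selection, and allele harmonisation.

test_that("summary statistics survive a write/read round trip exactly", {
  assoc <- random_assoc(50, seed = 11)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(assoc, path)
  back <- read_summary_stats(path)
  expect_equal(back, assoc, ignore_attr = TRUE, tolerance = 0)

  # header-only and single-record files
  write_summary_stats(assoc[0, ], path)
  expect_identical(length(readLines(path)), 1L)
  write_summary_stats(assoc[1, ], path)
  expect_identical(length(readLines(path)), 2L)
})

test_that("reading preserves row order and skips malformed rows with a message", {
  assoc <- random_assoc(3, seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(assoc, path)
  expect_silent(back <- read_summary_stats(path))
  expect_identical(back$variant_id, assoc$variant_id)

  bad <- assoc
  bad$se[2] <- 0
  write_summary_stats(bad, path)
  expect_message(back <- read_summary_stats(path), "skipped 1 of 3")
  expect_identical(nrow(back), 2L)
  expect_false("rs002" %in% back$variant_id)

  indel <- assoc
  indel$effect_allele[1] <- "AT"
  write_summary_stats(indel, path)
  expect_message(back <- read_summary_stats(path), "skipped 1")
  expect_identical(nrow(back), 2L)
})

test_that("missing mandatory columns and empty files are format errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- random_assoc(2)
  write.table(df[, setdiff(names(df), "beta")], path, sep = "\t",
              row.names = FALSE, quote = FALSE)
  expect_error(read_summary_stats(path), "beta",
               class = "mrphewas_format_error")
  writeLines(character(0), path)
  expect_error(read_summary_stats(path), class = "mrphewas_format_error")
})

test_that("header aliases are accepted", {
  assoc <- random_assoc(4, seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  renamed <- assoc
  names(renamed) <- c("SNP", "CHR", "BP", "A1", "A2", "freq", "b", "SE",
                      "p", "N")
  write.table(renamed, path, sep = "\t", row.names = FALSE, quote = FALSE)
  back <- read_summary_stats(path)
  expect_identical(back$variant_id, assoc$variant_id)
  expect_equal(back$beta, assoc$beta, tolerance = 1e-12)
})

test_that("instrument selection is a strict p-value filter with stable order", {
  assoc <- make_assoc(c("a", "b", "c"), beta = c(1, 1, 1), se = c(1, 1, 1),
                      pval = c(1e-9, 1e-7, 1e-8))
  sel <- select_instruments(assoc, 5e-8)
  expect_identical(sel$variant_id, c("a", "c"))

  assoc$pval <- 0.5
  expect_identical(nrow(select_instruments(assoc)), 0L)

  # equals the one-line brute-force filter on random inputs
  for (seed in 1:5) {
    r <- random_assoc(40, seed = seed)
    thr <- 10^runif(1, -8, -1)
    got <- select_instruments(r, thr)
    want <- r[r$pval < thr, ]
    want <- want[order(want$pval, want$variant_id), ]
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("harmonisation handles matched, swapped, complemented and mismatched alleles", {
  ex <- make_assoc("v1", 0.10, 0.02, effect_allele = "A", other_allele = "G")

  # swapped alleles: beta negated, EAF complemented
  out <- make_assoc("v1", 0.05, 0.02, effect_allele = "G",
                    other_allele = "A", eaf = 0.3)
  h <- harmonise_pair(ex, out)
  expect_identical(h$action, "flipped")
  expect_equal(h$outcome_beta, -0.05)
  expect_equal(h$outcome_eaf, 0.7)

  # identical orientation: untouched
  out2 <- make_assoc("v1", 0.05, 0.02, effect_allele = "A",
                     other_allele = "G", eaf = 0.3)
  h2 <- harmonise_pair(ex, out2)
  expect_identical(h2$action, "kept")
  expect_equal(h2$outcome_beta, 0.05)

  # strand complement, same order: kept after complementing
  out3 <- make_assoc("v1", 0.05, 0.02, effect_allele = "T",
                     other_allele = "C", eaf = 0.3)
  h3 <- harmonise_pair(ex, out3)
  expect_identical(h3$action, "kept")
  expect_equal(h3$outcome_beta, 0.05)

  # strand complement, swapped order: flipped
  out4 <- make_assoc("v1", 0.05, 0.02, effect_allele = "C",
                     other_allele = "T", eaf = 0.3)
  h4 <- harmonise_pair(ex, out4)
  expect_identical(h4$action, "flipped")
  expect_equal(h4$outcome_beta, -0.05)

  # incompatible allele set
  out5 <- make_assoc("v1", 0.05, 0.02, effect_allele = "A",
                     other_allele = "C")
  expect_identical(harmonise_pair(ex, out5)$action, "dropped")
  expect_identical(harmonise_pair(ex, out5)$drop_reason, "allele_mismatch")

  # mismatched ids need a proxy declaration
  out6 <- make_assoc("v2", 0.05, 0.02)
  expect_error(harmonise_pair(ex, out6), class = "mrphewas_usage_error")
})

test_that("palindromic variants are resolved by allele frequency or dropped", {
  # frequencies on opposite sides of 0.5: flip
  ex <- make_assoc("p1", 0.2, 0.05, effect_allele = "A", other_allele = "T",
                   eaf = 0.10)
  out <- make_assoc("p1", 0.1, 0.05, effect_allele = "A", other_allele = "T",
                    eaf = 0.88)
  h <- harmonise_pair(ex, out)
  expect_identical(h$action, "flipped")
  expect_equal(h$outcome_beta, -0.1)
  expect_equal(h$outcome_eaf, 0.12)

  # frequencies agreeing: resolved without change
  out2 <- make_assoc("p1", 0.1, 0.05, effect_allele = "A",
                     other_allele = "T", eaf = 0.15)
  h2 <- harmonise_pair(ex, out2)
  expect_identical(h2$action, "palindromic_resolved")
  expect_equal(h2$outcome_beta, 0.1)

  # EAF inside the ambiguity window: dropped
  ex3 <- make_assoc("p2", 0.2, 0.05, effect_allele = "C",
                    other_allele = "G", eaf = 0.50)
  out3 <- make_assoc("p2", 0.1, 0.05, effect_allele = "C",
                     other_allele = "G", eaf = 0.2)
  h3 <- harmonise_pair(ex3, out3)
  expect_identical(h3$action, "dropped")
  expect_identical(h3$drop_reason, "ambiguous_palindrome")

  # missing EAF on a palindrome: conservative drop
  out4 <- make_assoc("p1", 0.1, 0.05, effect_allele = "A",
                     other_allele = "T", eaf = NA)
  expect_identical(harmonise_pair(ex, out4)$drop_reason,
                   "ambiguous_palindrome")
})

test_that("harmonisation is idempotent and flip-involutive on random pairs", {
  set.seed(99)
  pairs <- list(c("A", "G"), c("C", "T"), c("A", "T"), c("C", "G"))
  est_cols <- c("exposure_beta", "exposure_se", "outcome_beta", "outcome_se")
  for (i in 1:60) {
    al <- pairs[[sample.int(4, 1)]]
    if (runif(1) < 0.5) al <- rev(al)
    eaf_x <- runif(1, 0.05, 0.95)
    ex <- make_assoc("v", rnorm(1, 0, 0.2), runif(1, 0.01, 0.1),
                     effect_allele = al[1], other_allele = al[2],
                     eaf = eaf_x)
    # outcome reported on a random orientation of the same variant
    flip_lab <- runif(1) < 0.5
    comp <- runif(1) < 0.5
    a1 <- if (flip_lab) al[2] else al[1]
    a2 <- if (flip_lab) al[1] else al[2]
    if (comp) {
      cmap <- c(A = "T", T = "A", C = "G", G = "C")
      a1 <- cmap[[a1]]
      a2 <- cmap[[a2]]
    }
    out <- make_assoc("v", rnorm(1, 0, 0.2), runif(1, 0.01, 0.1),
                      effect_allele = a1, other_allele = a2,
                      eaf = runif(1, 0.05, 0.95))
    h1 <- harmonise_pair(ex, out)
    if (h1$action == "dropped") next
    # idempotence: re-harmonising the aligned output is a no-op
    realigned <- make_assoc("v", h1$outcome_beta, h1$outcome_se,
                            effect_allele = h1$effect_allele,
                            other_allele = h1$other_allele,
                            eaf = h1$outcome_eaf)
    h2 <- harmonise_pair(ex, realigned)
    expect_false(h2$action %in% c("flipped", "dropped"))
    expect_equal(h2[est_cols], h1[est_cols], tolerance = 1e-15)

    # flip involution: flipping the outcome's alleles and beta sign gives
    # an estimation-identical instrument
    flipped_in <- out
    flipped_in$effect_allele <- out$other_allele
    flipped_in$other_allele <- out$effect_allele
    flipped_in$beta <- -out$beta
    flipped_in$eaf <- 1 - out$eaf
    h3 <- harmonise_pair(ex, flipped_in)
    expect_equal(h3[est_cols], h1[est_cols], tolerance = 1e-15)
  }
})

test_that("harmonise drops instruments missing from the outcome without a panel", {
  ex <- make_assoc(c("a", "b"), c(0.1, 0.2), c(0.02, 0.02))
  out <- make_assoc("a", 0.05, 0.02)
  h <- harmonise(ex, out)
  expect_identical(h$action, c("kept", "dropped"))
  expect_identical(h$drop_reason[2], "not_in_outcome")
})
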