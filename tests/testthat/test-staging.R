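fixture_table2 <- function() {
  read_staging_table(system.file("extdata", "table2_mr_staging.csv",
                                 package = "dictmri"))
}

test_that("per-stage sensitivity reproduces the published MR cohort", {
  tb <- fixture_table2()
  expect_equal(sensitivity(tb, "T1-2"), 19 / 41)
  expect_equal(sensitivity(tb, "T3"), 18 / 58)
  expect_equal(sensitivity(tb, "T4"), 15 / 47)
  ident <- staging_table(diag(c(5, 7, 9)), c("a", "b", "c"))
  for (k in 1:3) {
    expect_equal(sensitivity(ident, k), 1)
    expect_equal(specificity(ident, k), 1)
  }
})

test_that("specificity follows the one-vs-rest definition", {
  tb <- fixture_table2()
  # standard definition from the counts (not the table's printed values,
  # whose denominators are not derivable from the counts)
  expect_equal(specificity(tb, "T1-2"), 69 / 105)
  uniform <- staging_table(matrix(4, 3, 3), c("a", "b", "c"))
  for (k in 1:3) expect_equal(specificity(uniform, k), 2 / 3)
})

test_that("coincidence rate is the trace over the total", {
  tb <- fixture_table2()
  expect_equal(coincidence_rate(tb), 52 / 146)
  expect_equal(coincidence_rate(staging_table(diag(3), c("a", "b", "c"))), 1)
  expect_equal(coincidence_rate(staging_table(matrix(2, 4, 4), letters[1:4])),
               1 / 4)
})

test_that("chi-square matches closed forms and the reference routine", {
  perfect2 <- staging_table(matrix(c(10, 0, 0, 10), 2, 2), c("a", "b"))
  chi <- chi_square_test(perfect2)
  expect_equal(chi$statistic, 20)
  expect_identical(chi$df, 1)
  # outer product of margins: exact independence
  m <- outer(c(2, 3, 5), c(1, 4, 5))
  indep <- staging_table(m, c("a", "b", "c"))
  expect_equal(chi_square_test(indep)$statistic, 0, tolerance = 1e-10)
  expect_equal(chi_square_test(indep)$p_value, 1)
  # invariant under simultaneous row+column permutation
  tb <- fixture_table2()
  perm <- c(3, 1, 2)
  tb_p <- staging_table(tb$counts[perm, perm], tb$labels[perm])
  expect_equal(chi_square_test(tb_p)$statistic,
               chi_square_test(tb)$statistic, tolerance = 1e-10)
  # cross-check against the stock Pearson test
  ref <- suppressWarnings(stats::chisq.test(tb$counts, correct = FALSE))
  expect_equal(chi_square_test(tb)$statistic, unname(ref$statistic),
               tolerance = 1e-10)
  expect_equal(chi_square_test(tb)$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("kappa matches hand computation and the reference routine", {
  expect_equal(agreement_kappa(staging_table(diag(c(3, 4, 5)),
                                             c("a", "b", "c"))), 1)
  m <- outer(c(2, 3), c(4, 1))
  expect_equal(agreement_kappa(staging_table(m, c("a", "b"))), 0,
               tolerance = 1e-12)
  t22 <- staging_table(matrix(c(45, 5, 5, 45), 2, 2), c("a", "b"))
  expect_equal(agreement_kappa(t22), 0.8)
  skip_if_not_installed("e1071")
  tb <- fixture_table2()
  ref <- e1071::classAgreement(tb$counts)
  expect_equal(agreement_kappa(tb), ref$kappa, tolerance = 1e-10)
})

test_that("metric identities hold on random tables", {
  set.seed(1)
  for (trial in 1:20) {
    K <- sample(2:5, 1)
    m <- matrix(rpois(K * K, 6), K, K)
    if (sum(m) == 0) m[1, 1] <- 1
    tb <- staging_table(m, paste0("s", seq_len(K)))
    # trace/total equals column-margin-weighted mean of per-stage recall
    sens <- vapply(seq_len(K), function(k) sensitivity(tb, k), 0)
    wts <- colSums(m) / sum(m)
    ok <- !is.na(sens)
    expect_equal(coincidence_rate(tb), sum((sens * wts)[ok]),
                 tolerance = 1e-12)
    # kappa never exceeds the observed agreement
    kap <- agreement_kappa(tb)
    if (!is.na(kap)) expect_lte(kap, coincidence_rate(tb) + 1e-12)
    # relabeling invariance
    perm <- sample(K)
    tb_p <- staging_table(m[perm, perm], tb$labels[perm])
    expect_equal(coincidence_rate(tb_p), coincidence_rate(tb))
  }
})

test_that("evaluate_cohort renders the rounded report", {
  tb <- fixture_table2()
  ev <- evaluate_cohort(tb)
  expect_equal(ev$per_stage$sensitivity_pct, c(46.34, 31.03, 31.91))
  expect_equal(ev$per_stage$n_imaging, c(55L, 56L, 35L))
  expect_equal(ev$per_stage$n_pathology, c(41L, 58L, 47L))
  expect_identical(ev$n, 146L)
  expect_match(paste(ev$report, collapse = " "), "one-vs-rest")
  ident <- staging_table(diag(c(10, 10, 10)), c("a", "b", "c"))
  evi <- evaluate_cohort(ident)
  expect_equal(evi$per_stage$sensitivity_pct, rep(100, 3))
  expect_equal(evi$kappa, 1)
})

test_that("staging tables survive a CSV round trip", {
  tb <- fixture_table2()
  path <- withr::local_tempfile(fileext = ".csv")
  write_staging_table(tb, path)
  back <- read_staging_table(path)
  expect_equal(back$counts, tb$counts)
  expect_identical(back$labels, tb$labels)
})

test_that("degenerate tables yield sentinels and clean errors", {
  tb <- staging_table(matrix(c(0, 0, 3, 5), 2, 2), c("a", "b"))
  expect_true(is.na(sensitivity(tb, "a")))
  expect_error(staging_table(matrix(0, 2, 2), c("a", "b")),
               class = "dictmri_invalid_spec")
  expect_error(staging_table(matrix(1, 2, 3), c("a", "b")),
               class = "dictmri_invalid_spec")
})
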