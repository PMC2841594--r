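test_that("expected counts preserve margins", {
  expect_equal(expected_counts(matrix(10, 2, 2)), matrix(10, 2, 2))
  expect_equal(expected_counts(matrix(c(1, 0, 0, 1), 2)), matrix(0.5, 2, 2))
  m <- matrix(c(20, 30, 10, 40), 2, byrow = TRUE)
  e <- expected_counts(m)
  expect_equal(rowSums(e), rowSums(m))
  expect_equal(colSums(e), colSums(m))
  expect_equal(e[1, 1], 50 * 30 / 100)
  set.seed(5)
  for (i in 1:20) {
    m <- matrix(rpois(9, 20), 3)
    e <- expected_counts(m)
    expect_equal(rowSums(e), rowSums(m))
    expect_equal(colSums(e), colSums(m))
  }
})

test_that("applicability verdicts follow the two-tier expected-count rule", {
  # the 20%-vs-0% comparison at published scale: smallest expected ~0.033
  tab <- two_group_table(20, 54, 0, 17761)
  expect_equal(tab[1, 1], 11)
  cond <- check_conditions(tab)
  expect_equal(cond$validity, "invalid")
  expect_lt(cond$min_expected, 1)

  expect_equal(check_conditions(matrix(100, 2, 2))$validity, "valid")

  # smallest expected between 1 and 5 is runnable with a warning
  npc <- two_group_table(7, 54, 2, 17761)
  cond <- check_conditions(npc)
  expect_equal(cond$validity, "valid_with_warning")
  expect_gt(cond$min_expected, 1)
  expect_lt(cond$min_expected, 5)

  # all-zero margins are invalid outright
  expect_equal(check_conditions(matrix(c(0, 0, 3, 4), 2))$validity, "invalid")
})

test_that("verdicts are invariant under row/column permutation", {
  set.seed(17)
  for (i in 1:25) {
    m <- matrix(rpois(12, sample(c(1, 3, 10), 1)), 3, 4)
    if (sum(m) == 0) next
    v <- check_conditions(m)$validity
    expect_equal(check_conditions(m[sample(3), sample(4)])$validity, v)
    expect_equal(check_conditions(t(m))$validity, v)
  }
})

test_that("Yates 2x2 test matches hand formula, clamps, and attaches validity", {
  r <- yates_chi2_2x2(matrix(10, 2, 2))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_true(r$yates_applied)
  expect_equal(r$df, 1L)

  # published-scale co-enrichment comparison is significant below 0.005
  tab <- two_group_table(35, 54, 16, 17761)
  expect_equal(tab[, 1], c(group_a = 19, group_b = 2842))
  r <- yates_chi2_2x2(tab)
  expect_lt(r$p_value, 0.005)
  expect_equal(r$validity, "valid")

  m <- matrix(c(20, 30, 10, 40), 2, byrow = TRUE)
  o <- oracle_chisq(m, yates = TRUE)
  r <- yates_chi2_2x2(m)
  expect_equal(r$statistic, o$stat, tolerance = 1e-9)
  expect_equal(r$p_value, o$p, tolerance = 1e-9)

  # near-null table: clamped correction cannot inflate the statistic
  nearnull <- matrix(c(5, 5, 5, 6), 2)
  expect_gte(yates_chi2_2x2(nearnull)$statistic, 0)
  expect_lte(yates_chi2_2x2(nearnull)$statistic,
             contingency_chi2(nearnull)$statistic)

  expect_error(yates_chi2_2x2(matrix(1, 2, 3)), "2x2")
  # invalid tables report the verdict instead of a statistic
  r <- yates_chi2_2x2(two_group_table(20, 54, 0, 17761))
  expect_equal(r$validity, "invalid")
  expect_true(is.na(r$statistic))
})

test_that("r x c Pearson test handles identical rows and degenerate tables", {
  m <- matrix(rep(c(10, 20, 30), 2), 2, byrow = TRUE)
  r <- contingency_chi2(m)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_equal(r$df, 2L)
  expect_false(r$yates_applied)

  r <- contingency_chi2(matrix(c(0, 0, 5, 7), 2))
  expect_equal(r$validity, "invalid")
  expect_true(is.na(r$statistic))

  m <- matrix(c(12, 7, 9, 30, 21, 14, 40, 8), 2, byrow = TRUE)
  o <- oracle_chisq(m)
  r <- contingency_chi2(m)
  expect_equal(r$statistic, o$stat, tolerance = 1e-9)
  expect_equal(r$p_value, o$p, tolerance = 1e-9)
})

test_that("both tests agree with chisq.test and the direct formula on 1000 random tables", {
  set.seed(1234)
  max_diff <- 0
  for (i in 1:500) {
    m <- matrix(rpois(4, sample(c(8, 30, 150), 1)) + 1L, 2)
    ours <- yates_chi2_2x2(m)
    ref <- suppressWarnings(stats::chisq.test(m, correct = TRUE))
    o <- oracle_chisq(m, yates = TRUE)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(ours$statistic, o$stat, tolerance = 1e-9)
    expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-9)
  }
  for (i in 1:500) {
    nr <- sample(2:4, 1); nc <- sample(2:5, 1)
    m <- matrix(rpois(nr * nc, 25) + 1L, nr, nc)
    ours <- contingency_chi2(m)
    ref <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    o <- oracle_chisq(m)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(ours$statistic, o$stat, tolerance = 1e-9)
    expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-9)
    expect_equal(ours$df, as.integer(unname(ref$parameter)))
  }
})

test_that("Yates statistic never exceeds the uncorrected Pearson statistic", {
  set.seed(77)
  for (i in 1:200) {
    m <- matrix(rpois(4, 12) + 1L, 2)
    expect_lte(yates_chi2_2x2(m)$statistic, contingency_chi2(m)$statistic + 1e-12)
  }
})

test_that("p-values decrease strictly in the statistic at fixed df", {
  stats_seq <- sort(runif(20, 0, 30))
  for (df in c(1, 3, 6)) {
    p <- pchisq(stats_seq, df, lower.tail = FALSE)
    expect_true(all(diff(p) < 0))
  }
  # and via the result objects
  a <- yates_chi2_2x2(matrix(c(30, 10, 10, 30), 2))
  b <- yates_chi2_2x2(matrix(c(25, 15, 15, 25), 2))
  expect_gt(a$statistic, b$statistic)
  expect_lt(a$p_value, b$p_value)
})

test_that("printed percentages reconstruct counts by rounding", {
  expect_equal(as.integer(proportions_from_percentages(35, 54)), 19L)
  expect_equal(as.integer(proportions_from_percentages(0, 17761)), 0L)
  expect_equal(as.integer(proportions_from_percentages(41, 54)), 22L)
  expect_equal(as.integer(proportions_from_percentages(16, 17761)), 2842L)
  expect_error(proportions_from_percentages(101, 10), "percent")
  expect_error(proportions_from_percentages(50, 0))
})
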