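test_that("confusion tallies paired labels into the 2x2 layout", {
  truth <- c(rep("meets", 382), rep("does-not-meet", 383))
  pred <- c(rep("meets", 382), rep("meets", 2), rep("does-not-meet", 381))
  m <- confusion(truth, pred)
  expect_identical(c(m$A, m$B, m$C, m$D), c(382L, 2L, 0L, 381L))
  expect_identical(m$total, 765L)

  all_good <- rep(c("meets", "does-not-meet"), 5)
  m2 <- confusion(all_good, all_good)
  expect_identical(m2$B, 0L)
  expect_identical(m2$C, 0L)

  expect_error(confusion("meets", c("meets", "meets")), "equal length")
  expect_error(confusion("maybe", "meets"), "maybe")
})

test_that("confusion agrees with a hand tally on random labels", {
  set.seed(5)
  t <- sample(c(TRUE, FALSE), 200, replace = TRUE)
  p <- ifelse(runif(200) < 0.9, t, !t)
  m <- confusion(t, p)
  expect_identical(m$A, sum(t & p))
  expect_identical(m$B, sum(!t & p))
  expect_identical(m$C, sum(t & !p))
  expect_identical(m$D, sum(!t & !p))
})

test_that("the accuracy panel reproduces the printed formulas", {
  panel <- accuracy_panel(confusion_counts(382, 2, 0, 381))
  expect_equal(panel$sensitivity$point, 1)
  expect_equal(panel$specificity$point, 381 / 383)
  expect_equal(panel$accuracy$point, 763 / 765)
  # printed percentages at 2 dp
  expect_equal(round(100 * panel$sensitivity$point, 2), 100)
  expect_equal(round(100 * panel$specificity$point, 2), 99.48)
  expect_equal(round(100 * panel$accuracy$point, 2), 99.74)
})

test_that("zero denominators are undefined, not zero", {
  panel <- accuracy_panel(confusion_counts(0, 3, 0, 7))
  expect_null(panel$sensitivity)
  expect_false(is.null(panel$specificity))
})

test_that("exact intervals match the independent binomial-test oracle", {
  for (n in c(10L, 97L, 383L)) {
    for (x in unique(c(0L, 1L, n %/% 3L, n - 1L, n))) {
      got <- exact_binomial_ci(x, n)
      want <- stats::binom.test(x, n)$conf.int
      expect_equal(got$lower, want[1], tolerance = 1e-10)
      expect_equal(got$upper, want[2], tolerance = 1e-10)
      expect_true(got$lower <= got$point && got$point <= got$upper)
    }
  }
  expect_identical(exact_binomial_ci(0, 10)$lower, 0)
  expect_identical(exact_binomial_ci(10, 10)$upper, 1)
  expect_error(exact_binomial_ci(11, 10), "successes")
})

test_that("interval width shrinks with the number of trials", {
  widths <- vapply(c(50, 200, 800, 3200), function(n) {
    ci <- exact_binomial_ci(round(0.9 * n), n)
    ci$upper - ci$lower
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("accuracy decomposes into prevalence-weighted sensitivity and
           specificity", {
  set.seed(17)
  for (rep in 1:20) {
    cnt <- sample(0:200, 4, replace = TRUE)
    if (cnt[1] + cnt[3] == 0 || cnt[2] + cnt[4] == 0) next
    m <- confusion_counts(cnt[1], cnt[2], cnt[3], cnt[4])
    p <- accuracy_panel(m)
    lhs <- p$accuracy$point * m$total
    rhs <- p$sensitivity$point * (m$A + m$C) + p$specificity$point * (m$B + m$D)
    expect_equal(lhs, rhs)
  }
})

test_that("one-sample proportion sample sizes follow the formula", {
  expect_identical(sample_size_proportion(0.90, 0.05), 379L)
  expect_identical(sample_size_proportion(0.50, 0.05), 1051L)
  # doubling delta divides n by about 4
  n1 <- sample_size_proportion(0.80, 0.04)
  n2 <- sample_size_proportion(0.80, 0.08)
  expect_equal(n1 / n2, 4, tolerance = 0.02)
  expect_error(sample_size_proportion(0.95, 0.2), "infeasible")
})

test_that("event rates divide to two decimals", {
  expect_equal(event_rate(765, 197), 3.88)
  expect_equal(event_rate(382, 197), 1.94)
  expect_equal(event_rate(383, 123), 3.11)
  expect_error(event_rate(10, 0), "positive")
})
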