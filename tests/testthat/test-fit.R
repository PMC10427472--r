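test_that("increment rescaling matches hand-computed values", {
  expect_equal(frequency_increments(0:2, c(0.5, 0.5, 0.5)), c(0, 0))
  q <- frequency_increments(0:2, c(0.2, 0.3, 0.4))
  expect_equal(q, c(0.1 / sqrt(2 * 0.2 * 0.8), 0.1 / sqrt(2 * 0.3 * 0.7)),
               tolerance = 1e-12)
  expect_equal(round(q, 5), c(0.17678, 0.15430))
  expect_equal(frequency_increments(c(0, 2), c(0.2, 0.3)),
               0.1 / sqrt(2 * 0.2 * 0.8 * 2))
  expect_error(frequency_increments(0:2, c(0, 0.3, 0.4)), "degenerate")
  expect_error(frequency_increments(0, 0.5), "length >= 2")
})

test_that("increments scale as 1/sqrt(k) when time gaps are stretched by k", {
  set.seed(5)
  f <- runif(30, 0.05, 0.95)
  t0 <- cumsum(runif(30, 0.5, 2))
  for (k in c(2, 5, 10)) {
    expect_equal(frequency_increments(t0 * k, f),
                 frequency_increments(t0, f) / sqrt(k), tolerance = 1e-12)
  }
})

test_that("absorption truncation drops the uninformative tail", {
  # default convention: the absorbing value itself is excluded
  tr <- truncate_at_absorption(c(0.4, 0.7, 1.0, 1.0, 1.0), 0:4)
  expect_equal(tr$freqs, c(0.4, 0.7))
  expect_true(tr$truncated)
  # literal-prefix convention keeps the first absorbing value
  tr2 <- truncate_at_absorption(c(0.4, 0.7, 1.0, 1.0, 1.0), 0:4,
                                keep_absorbing = TRUE)
  expect_equal(tr2$freqs, c(0.4, 0.7, 1.0))
  expect_true(tr2$truncated)
  expect_equal(truncate_at_absorption(c(1.0, 1.0), 0:1,
                                      keep_absorbing = TRUE)$freqs, 1.0)

  un <- truncate_at_absorption(c(0.4, 0.5, 0.6), 0:2)
  expect_equal(un$freqs, c(0.4, 0.5, 0.6))
  expect_false(un$truncated)
})

test_that("fit_test agrees with an independent literal oracle", {
  set.seed(77)
  for (rep in 1:50) {
    len <- sample(10:60, 1)
    f <- pmin(0.99, pmax(0.01, 0.5 + cumsum(rnorm(len, 0, 0.03))))
    t <- cumsum(sample(1:3, len, replace = TRUE))
    r <- fit_test(f, times = t)
    o <- oracle_fit(f, t)
    expect_equal(r$increments, o$q, tolerance = 1e-10)
    if (r$applicable) {
      expect_equal(r$t_statistic, o$t, tolerance = 1e-10)
      expect_equal(r$p_value, o$p, tolerance = 1e-10)
    }
  }
})

test_that("fit_test handles degenerate series explicitly", {
  expect_error(fit_test(0.5), "at least 2")
  const <- fit_test(rep(0.5, 20))
  expect_equal(const$verdict, "inapplicable")
  expect_equal(const$reason, "zero_variance_increments")
  short <- fit_test(c(0.4, 0.5, 0.6))
  expect_equal(short$reason, "too_few_increments")
  absorbed <- fit_test(c(1, 1, 1, 1))
  expect_equal(absorbed$verdict, "inapplicable")
})

test_that("fit_test is exactly invariant to relabelling the two variants", {
  set.seed(31)
  for (rep in 1:20) {
    tr <- wf_simulate(1000, 100, beta = sample(c(0, 0.05), 1), start_freq = 0.5)
    a <- fit_test(tr$freqs)
    b <- fit_test(1 - tr$freqs)
    expect_identical(a$verdict, b$verdict)
    if (a$applicable) {
      expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
      expect_equal(a$shapiro_p, b$shapiro_p, tolerance = 1e-9)
    }
  }
})

test_that("under drift the mean rescaled increment is centred on zero", {
  set.seed(12)
  z <- wf_simulate_matrix(500, 1000, 100, beta = 0, start_freq = 0.5)
  means <- apply(z, 1, function(r) {
    tr <- truncate_at_absorption(r / 1000, 0:99)
    if (length(tr$freqs) < 2) return(NA_real_)
    mean(frequency_increments(tr$times, tr$freqs))
  })
  means <- means[!is.na(means)]
  expect_lt(abs(mean(means)), 3 * sd(means) / sqrt(length(means)))
})

test_that("rejection rate is calibrated under drift and grows with selection", {
  set.seed(14)
  z <- wf_simulate_matrix(1000, 1000, 200, beta = 0, start_freq = 0.5)
  res <- seldrift:::.fit_batch(z, 1000)
  rate <- mean(res$reject[res$applicable])
  expect_gte(rate, 0.035)
  expect_lte(rate, 0.07)

  rates <- sapply(c(0.001, 0.01, 0.1, 1), function(b) {
    zz <- wf_simulate_matrix(1000, 1000, 200, beta = b, start_freq = 0.5)
    rr <- seldrift:::.fit_batch(zz, 1000)
    mean(rr$reject[rr$applicable])
  })
  expect_true(all(diff(rates) > -0.03))  # non-decreasing up to MC noise
})

test_that("quantile bin count follows the ceiling-log rule", {
  expect_equal(quantile_bin_count(100), 5L)
  expect_equal(quantile_bin_count(100, c = 2), 10L)
  expect_equal(quantile_bin_count(1), 1L)  # floor at one bin
})

test_that("fit results tabulate one row per series", {
  tr <- wf_simulate(1000, 100, beta = 0.1, start_freq = 0.5, seed = 2)
  tab <- fit_results_table(list(fit_test(tr), fit_test(tr$freqs)),
                           ids = c("a", "b"))
  expect_equal(nrow(tab), 2)
  expect_equal(tab$series_id, c("a", "b"))
  expect_true(all(c("mean_Q", "t", "p", "shapiro_p", "verdict") %in% names(tab)))
})
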