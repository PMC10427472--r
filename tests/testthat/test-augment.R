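test_that("binning pools counts, conserves totals, and fixes constants", {
  tr <- wf_trajectory(0:3, c(0.2, 0.4, 0.6, 0.8), counts = c(2, 4, 6, 8),
                      trials = rep(10, 4), label = "drift", beta = 0)
  b2 <- bin_series(tr, 2)
  expect_equal(b2$freqs, c(0.3, 0.7))
  expect_equal(sum(b2$counts), sum(tr$counts))
  expect_equal(b2$times, 0:1)

  # identity binning
  bid <- bin_series(tr, 4)
  expect_equal(bid$freqs, tr$freqs)

  # constants stay constant at any bin count, counts or not
  const <- wf_trajectory(0:9, rep(0.4, 10), counts = rep(4, 10),
                         trials = rep(10, 10))
  for (nb in c(2, 3, 7, 10)) {
    expect_equal(bin_series(const, nb)$freqs, rep(0.4, nb))
  }
  nocounts <- wf_trajectory(0:9, rep(0.4, 10))
  expect_equal(bin_series(nocounts, 3)$freqs, rep(0.4, 3))

  expect_error(bin_series(tr, 5), "series length")
})

test_that("segment sizes are near-equal with larger segments first", {
  ids <- seldrift:::segment_ids(10, 3)
  expect_equal(tabulate(ids, 3), c(4, 3, 3))
  expect_equal(ids, rep(1:3, c(4, 3, 3)))  # contiguous
  expect_equal(tabulate(seldrift:::segment_ids(200, 7), 7),
               c(29, 29, 29, 29, 28, 28, 28))
})

test_that("frequency distortion is clipped, unbiased, and sigma-scaled", {
  f <- seq(0, 1, length.out = 11)
  expect_identical(distort_frequencies(f, 0), f)
  set.seed(3)
  ones <- distort_frequencies(rep(1, 5000), 0.05)
  expect_true(all(ones <= 1))
  half <- distort_frequencies(rep(0.5, 20000), 0.05)
  expect_lt(abs(sd(half) - 0.05) / 0.05, 0.05)
  expect_lt(abs(mean(half) - 0.5), 3 * 0.05 / sqrt(20000))
})

test_that("padding appends zeros on the right and rejects bad lengths", {
  expect_equal(pad_series(c(0.5, 0.6), 4), c(0.5, 0.6, 0, 0))
  x <- runif(7)
  expect_equal(pad_series(x, 7), x)
  expect_error(pad_series(numeric(0), 3), "empty")
  expect_error(pad_series(runif(5), 3), "longer")
})

test_that("generated batches are balanced, padded, and class-separated", {
  set.seed(21)
  aug <- augment_config(noise_sigma = 0.05, bin_range = c(4L, 50L),
                        pad_to = 50L)
  b <- generate_batch(500, N = 1000, T = 50, aug = aug)
  expect_equal(dim(b$x), c(500, 50))
  expect_equal(sum(b$y == 0), 250)
  expect_equal(sum(b$y == 1), 250)
  expect_true(all(b$beta[b$y == 0] == 0))
  expect_true(all(b$beta[b$y == 1] > 0))
  expect_true(all(b$x >= 0 & b$x <= 1))
  # padding: positions beyond n_obs are zero
  for (j in c(1, 100, 500)) {
    if (b$n_obs[j] < 50) expect_true(all(b$x[j, (b$n_obs[j] + 1):50] == 0))
  }
  expect_error(generate_batch(3, aug = aug, T = 50), "even")

  # raw un-distorted batch: two length-T trajectories, one per class
  raw <- generate_batch(2, N = 100, T = 50,
                        aug = augment_config(0, c(50L, 50L), 50L))
  expect_setequal(raw$y, c(0, 1))
  expect_equal(raw$n_obs, c(50L, 50L))

  # selection series drift further from their start than drift series
  set.seed(22)
  big <- generate_batch(2000, N = 1000, T = 50,
                        aug = augment_config(0, c(50L, 50L), 50L))
  net_change <- abs(big$x[, 50] - big$x[, 1])
  expect_gt(mean(net_change[big$y == 1]), mean(net_change[big$y == 0]))
})

test_that("augment_config validates its interval", {
  expect_error(augment_config(-0.1), ">= 0")
  expect_error(augment_config(0, c(1L, 10L), 10L), "b_min")
  expect_error(augment_config(0, c(4L, 20L), 10L), "pad_to")
})
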