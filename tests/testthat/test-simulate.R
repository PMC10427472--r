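test_that("selection pressure fixes boundaries, reduces to drift, is monotone", {
  expect_equal(selection_pressure(0.3, 0), 0.3)
  expect_equal(selection_pressure(c(0, 1), 1), c(0, 1))
  expect_equal(selection_pressure(0.5, 1), 2 / 3)
  expect_equal(selection_pressure(c(0, 1), 2, form = "additive"), c(0, 1))
  expect_equal(selection_pressure(0.3, 0, form = "additive"), 0.3)

  f <- seq(0.01, 0.99, by = 0.01)
  for (form in c("fitness", "additive")) {
    g1 <- selection_pressure(f, 0.5, form = form)
    expect_true(all(diff(g1) > 0))                 # increasing in f
    g2 <- selection_pressure(f, 1.5, form = form)
    expect_true(all(g2 >= g1))                      # increasing in beta
    expect_true(all(g1 >= 0 & g1 <= 1))
  }

  expect_error(selection_pressure(1.2, 0.5), "\\[0, 1\\]")
  expect_error(selection_pressure(0.5, -1), "non-negative")
})

test_that("one-step simulation moments match the binomial oracle", {
  set.seed(42)
  n <- 10000
  z <- wf_simulate_matrix(n, N = 1000, T = 2, beta = 0, start_freq = 0.5)
  f1 <- z[, 2] / 1000
  se_mean <- sqrt(0.5 * 0.5 / 1000) / sqrt(n)
  expect_lt(abs(mean(f1) - 0.5), 3 * se_mean)
  expect_lt(abs(var(f1) - 0.5 * 0.5 / 1000) / (0.5 * 0.5 / 1000), 0.1)

  zs <- wf_simulate_matrix(n, N = 1000, T = 2, beta = 1, start_freq = 0.5)
  expect_lt(abs(mean(zs[, 2] / 1000) - selection_pressure(0.5, 1)), 3 * se_mean)
})

test_that("drift is a martingale and boundaries absorb", {
  set.seed(7)
  n <- 10000
  z <- wf_simulate_matrix(n, N = 1000, T = 50, beta = 0, start_freq = 0.3)
  f50 <- z[, 50] / 1000
  # E[f(t)] = f0 under drift; SE grows with accumulated drift variance
  expect_lt(abs(mean(f50) - 0.3), 3 * sd(f50) / sqrt(n))

  tr <- wf_simulate(N = 1000, T = 200, beta = 0, start_freq = 0, seed = 1)
  expect_true(all(tr$freqs == 0))
  set.seed(8)
  z <- wf_simulate_matrix(200, N = 50, T = 100, beta = 0, start_freq = 0.5)
  for (j in seq_len(nrow(z))) {
    hit <- which(z[j, ] == 0 | z[j, ] == 50)
    if (length(hit)) {
      expect_true(all(z[j, hit[1]:100] == z[j, hit[1]]))
    }
  }
})

test_that("simulation is reproducible from its seed", {
  a <- wf_simulate(1000, 200, beta = 0.05, start_freq = 0.5, seed = 99)
  b <- wf_simulate(1000, 200, beta = 0.05, start_freq = 0.5, seed = 99)
  expect_identical(a, b)
  m1 <- wf_simulate_matrix(10, 100, 50, beta = 0.1, seed = 5)
  m2 <- wf_simulate_matrix(10, 100, 50, beta = 0.1, seed = 5)
  expect_identical(m1, m2)
})

test_that("log-uniform beta sampling has the closed-form median and decade mass", {
  expect_equal(sample_beta(5, c(0.2, 0.2)), rep(0.2, 5))
  set.seed(10)
  b <- sample_beta(20000, c(1e-3, 1))
  expect_lt(abs(median(b) - 10^(-1.5)) / 10^(-1.5), 0.1)
  dec <- table(cut(log10(b), breaks = c(-3, -2, -1, 0)))
  expect_true(all(abs(dec / 20000 - 1 / 3) < 0.02))
  expect_error(sample_beta(1, c(0, 1)), "positive")
})

test_that("trajectory constructor enforces its invariants", {
  expect_error(wf_trajectory(c(0, 0), c(0.1, 0.2)), "strictly increasing")
  expect_error(wf_trajectory(0:1, c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(wf_trajectory(0:1, c(0.1, 0.2), counts = c(1, 2)), "together")
  expect_error(wf_trajectory(0:1, c(0.5, 0.5), counts = c(3, 1), trials = c(2, 2)))
  tr <- wf_trajectory(0:2, c(0.2, 0.4, 0.6), counts = c(1, 2, 3),
                      trials = c(5, 5, 5), label = "drift", beta = 0)
  expect_s3_class(tr, "wf_trajectory")
  expect_length(tr, 3)
})
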