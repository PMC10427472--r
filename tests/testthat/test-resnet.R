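test_that("untrained network maps arbitrary input to a probability", {
  cfg <- resnet_config(input_length = 40, filters = c(8, 12, 12))
  m <- resnet_init(cfg, seed = 4)
  x <- rbind(runif(40), rnorm(40, 0, 10), rep(0, 40))
  p <- predict(m, x)
  expect_true(all(p > 0 & p < 1))
  # inference is deterministic
  expect_identical(p, predict(m, x))
  # single series as a vector
  expect_length(predict(m, runif(40)), 1)
  expect_error(predict(m, runif(39)), "input length")
})

test_that("default architecture has the hand-computed parameter count", {
  m <- resnet_init(resnet_config(), seed = 1)
  # conv W+b, batch-norm scale+shift, width-1 shortcut projections, head:
  # block1 34112 + block2 206336 + block3 263296 + head 129
  expect_identical(resnet_n_params(m), 503873L)
})

test_that("input shorter than the largest kernel is rejected", {
  expect_error(resnet_config(input_length = 5), "largest kernel")
})

test_that("label threshold is a strict greater-than at 0.5", {
  cfg <- resnet_config(input_length = 16, filters = c(4, 4, 4))
  m <- resnet_init(cfg, seed = 2)
  # force an exact 0.5 by zeroing the head: logit = 0
  m$params$head_w[] <- 0
  m$params$head_b <- 0
  expect_equal(predict(m, runif(16)), 0.5)
  expect_equal(predict(m, runif(16), type = "label"), "drift")
})

test_that("checkpoints round-trip predictions and catch config mismatches", {
  cfg <- resnet_config(input_length = 24, filters = c(6, 8, 8))
  m <- resnet_init(cfg, seed = 6)
  m$trained <- TRUE
  x <- matrix(runif(5 * 24), 5)
  path <- tempfile(fileext = ".rds")
  save_resnet(m, path)
  m2 <- load_resnet(path)
  expect_identical(predict(m2, x), predict(m, x))

  expect_error(load_resnet(path, expected_input_length = 200),
               "config mismatch")
  m$params$head_w <- matrix(0, 3, 1)  # corrupt weights vs config
  path2 <- tempfile(fileext = ".rds")
  saveRDS(m, path2)
  expect_error(load_resnet(path2), "config mismatch")
})

test_that("early stopping keeps the best epoch and stops after patience", {
  dev_losses <- c(0.5, 0.4, 0.41, 0.42, 0.43, 0.44, 0.45)
  st <- NULL
  stopped_at <- NA
  for (e in seq_along(dev_losses)) {
    st <- early_stop_update(st, dev_losses[e], e, patience = 5)
    if (st$stop) {
      stopped_at <- e
      break
    }
  }
  expect_equal(stopped_at, 7)
  expect_equal(st$best_epoch, 2)
  expect_equal(st$best_loss, 0.4)
})

test_that("training separates a trivially separable toy task", {
  # ramps with random endpoints; label says whether the series rises
  toy_gen <- function(n) {
    a <- runif(n)
    b <- runif(n)
    x <- t(vapply(seq_len(n), function(i) seq(a[i], b[i], length.out = 24),
                  numeric(24)))
    list(x = x, y = as.integer(b > a))
  }
  set.seed(55)
  m <- resnet_init(resnet_config(input_length = 24, filters = c(8, 8, 8)),
                   seed = 3)
  dev <- toy_gen(400)
  p0 <- predict(m, dev$x)
  loss0 <- -mean(dev$y * log(p0) + (1 - dev$y) * log(1 - p0))
  cfg <- train_config(series_per_epoch = 1000, batch_size = 50,
                      learning_rate = 3e-3, patience = 5, max_epochs = 4,
                      dev_set_size = 400, seed = 56)
  mt <- resnet_train(m, toy_gen, cfg)
  acc <- mean((predict(mt, dev$x) > 0.5) == (dev$y == 1))
  expect_gt(acc, 0.95)
  # training reduced the loss relative to initialisation
  expect_lt(min(mt$manifest$log$dev_loss), loss0)
  expect_true(mt$trained)
  expect_equal(nrow(mt$manifest$log), 4)
})

test_that("non-finite loss aborts with a diagnostic", {
  bad_gen <- function(n) list(x = matrix(NaN, n, 16), y = rep(0L, n))
  m <- resnet_init(resnet_config(input_length = 16, filters = c(4, 4, 4)),
                   seed = 1)
  cfg <- train_config(series_per_epoch = 50, batch_size = 50,
                      learning_rate = 1e-3, max_epochs = 1, dev_set_size = 10)
  expect_error(resnet_train(m, bad_gen, cfg), "non-finite")
})
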