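# Shared fixtures for the test suite.

# Literal, independent transcription of the increment-rescaling + t-test
# pipeline, kept deliberately naive (scalar loop, no shared code paths with
# the package internals) to serve as an oracle.
oracle_fit <- function(freqs, times, alpha = 0.05) {
  q <- numeric(0)
  for (i in 2:length(freqs)) {
    num <- freqs[i] - freqs[i - 1]
    den <- sqrt(2 * freqs[i - 1] * (1 - freqs[i - 1]) * (times[i] - times[i - 1]))
    q <- c(q, num / den)
  }
  qbar <- sum(q) / length(q)
  s <- sqrt(sum((q - qbar)^2) / (length(q) - 1))
  tstat <- qbar / (s / sqrt(length(q)))
  p <- 2 * stats::pt(-abs(tstat), df = length(q) - 1)
  list(q = q, t = tstat, p = p)
}

# Desk-scale study conditions for the classifier experiments: shorter series
# (T = 100), a narrower network and fewer simulated series per epoch than the
# reference regime, so a full training run fits in a test session. The
# replication experiments evaluate undistorted simulations, so the model for
# them trains with binning augmentation but no frequency noise.
desk <- list(
  T = 100L, N = 1000L,
  aug = augment_config(noise_sigma = 0, bin_range = c(4L, 100L),
                       pad_to = 100L),
  bins = c(4L, 10L, 25L, 50L, 100L)
)

desk_generator <- function(n) {
  generate_batch(n, N = desk$N, T = desk$T, aug = desk$aug)
}

# Train the desk-scale classifier once per test run and memoise it.
.desk_env <- new.env(parent = emptyenv())
desk_model <- function() {
  if (is.null(.desk_env$model)) {
    set.seed(100)
    model <- resnet_init(
      resnet_config(input_length = desk$aug$pad_to,
                    filters = c(16L, 32L, 32L)),
      seed = 1
    )
    cfg <- train_config(series_per_epoch = 2000L, batch_size = 100L,
                        learning_rate = 1e-3, patience = 5L,
                        max_epochs = 15L, dev_set_size = 1000L, seed = 100L)
    .desk_env$model <- resnet_train(model, desk_generator, cfg)
  }
  .desk_env$model
}
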