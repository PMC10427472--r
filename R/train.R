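#' Optimisation settings for classifier training
#'
#' Defaults mirror the reference training regime: 50,000 freshly simulated
#' series per epoch split into mini-batches of 500, Adam with learning rate
#' 6e-5, binary cross-entropy loss, and early stopping once the development
#' loss has not improved for 5 consecutive epochs.
#'
#' @param series_per_epoch Series generated per epoch (must be divisible by
#'   `batch_size`).
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam learning rate.
#' @param patience Consecutive non-improving epochs before stopping.
#' @param max_epochs Hard cap on epochs.
#' @param dev_set_size Series in the fixed development set, generated once
#'   before training.
#' @param seed Optional seed fixed at the start of training (covers the dev
#'   set, weight usage order and all simulated batches).
#' @return An object of class `train_config`.
#' @export
train_config <- function(series_per_epoch = 50000L, batch_size = 500L,
                         learning_rate = 6e-5, patience = 5L,
                         max_epochs = 100L, dev_set_size = 5000L,
                         seed = NULL) {
  if (series_per_epoch %% batch_size != 0) {
    stop("`series_per_epoch` must be divisible by `batch_size`",
         call. = FALSE)
  }
  stopifnot(learning_rate > 0, patience >= 1, max_epochs >= 1,
            dev_set_size >= 2, batch_size %% 2 == 0)
  structure(
    list(series_per_epoch = as.integer(series_per_epoch),
         batch_size = as.integer(batch_size),
         learning_rate = learning_rate, patience = as.integer(patience),
         max_epochs = as.integer(max_epochs),
         dev_set_size = as.integer(dev_set_size), seed = seed),
    class = "train_config"
  )
}

#' Early-stopping bookkeeping
#'
#' Pure state-update helper behind [resnet_train()]'s stopping rule: any
#' strictly lower development loss counts as an improvement and resets the
#' wait counter; once `patience` consecutive epochs bring no improvement,
#' `stop` becomes `TRUE`. Exposed so the rule itself is testable.
#'
#' @param state `NULL` to initialise, or a previous state.
#' @param dev_loss Development loss of the epoch just finished.
#' @param epoch Its epoch number.
#' @param patience Allowed consecutive non-improving epochs.
#' @return A list with `best_loss`, `best_epoch`, `wait`, `stop` and
#'   `improved`.
#' @export
early_stop_update <- function(state, dev_loss, epoch, patience = 5L) {
  if (is.null(state)) {
    state <- list(best_loss = Inf, best_epoch = 0L, wait = 0L, stop = FALSE)
  }
  if (dev_loss < state$best_loss) {
    state$best_loss <- dev_loss
    state$best_epoch <- epoch
    state$wait <- 0L
    state$improved <- TRUE
  } else {
    state$wait <- state$wait + 1L
    state$improved <- FALSE
  }
  state$stop <- state$wait >= patience
  state
}

#' Train the residual-network classifier on simulated batches
#'
#' Every epoch draws `series_per_epoch` fresh labelled series from
#' `generator`, takes one Adam step per mini-batch on the binary
#' cross-entropy, then scores a fixed development set (generated once before
#' the first epoch). Training stops at `max_epochs` or when the development
#' loss has not improved for `patience` consecutive epochs; the weights from
#' the best development epoch are retained.
#'
#' @param model An initialised `resnet_tsc` (see [resnet_init()]).
#' @param generator `function(n)` returning `list(x = n-by-L matrix, y =
#'   0/1 vector)`, e.g. a wrapper around [generate_batch()].
#' @param config A [train_config()].
#' @param verbose Print one line per epoch.
#' @return The trained model, with `$trained = TRUE` and `$manifest` holding
#'   the config, seed, and the per-epoch log (`epoch`, `train_loss`,
#'   `dev_loss`, `dev_accuracy`).
#' @export
resnet_train <- function(model, generator, config = train_config(),
                         verbose = FALSE) {
  stopifnot(inherits(model, "resnet_tsc"), inherits(config, "train_config"))
  if (!is.null(config$seed)) set.seed(config$seed)

  dev <- generator(config$dev_set_size)
  n_batches <- config$series_per_epoch %/% config$batch_size
  adam <- list(t = 0L, m = list(), v = list())
  es <- NULL
  best <- list(params = model$params, running = model$running)
  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    dev_loss = numeric(), dev_accuracy = numeric())

  for (epoch in seq_len(config$max_epochs)) {
    epoch_loss <- 0
    for (i in seq_len(n_batches)) {
      batch <- generator(config$batch_size)
      fwd <- .resnet_fwd(model, batch$x, training = TRUE)
      model$running <- fwd$caches$running
      loss <- .bce(fwd$prob, batch$y)
      if (!is.finite(loss)) {
        stop(sprintf("non-finite training loss at epoch %d, batch %d",
                     epoch, i), call. = FALSE)
      }
      grads <- .resnet_bwd(model, fwd, batch$y)
      upd <- .adam_step(model$params, grads, adam, config$learning_rate)
      model$params <- upd$params
      adam <- upd$state
      epoch_loss <- epoch_loss + loss
    }
    dev_prob <- .resnet_fwd(model, dev$x, training = FALSE)$prob
    dev_loss <- .bce(dev_prob, dev$y)
    dev_acc <- mean((dev_prob > 0.5) == (dev$y == 1))
    log <- rbind(log, data.frame(epoch = epoch,
                                 train_loss = epoch_loss / n_batches,
                                 dev_loss = dev_loss, dev_accuracy = dev_acc))
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  dev %.4f  acc %.3f",
                      epoch, epoch_loss / n_batches, dev_loss, dev_acc))
    }
    es <- early_stop_update(es, dev_loss, epoch, config$patience)
    if (es$improved) {
      best$params <- model$params
      best$running <- model$running
    }
    if (es$stop) break
  }

  model$params <- best$params
  model$running <- best$running
  model$trained <- TRUE
  model$manifest <- list(
    train_config = unclass(config), seed = config$seed,
    best_epoch = es$best_epoch, best_dev_loss = es$best_loss, log = log
  )
  model
}
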