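# 1-D residual network for binary time-series classification.
#
# Implemented directly on BLAS matrix multiplies. Activations live in
# matrices of shape (B*L, C): column-major with the batch index fastest, so
# the rows for time position l are the contiguous block ((l-1)*B+1):(l*B).
# A convolution is then K shifted matrix products against the (C*K, F) weight
# matrix, which keeps both passes vectorised.

#' Residual-network architecture settings
#'
#' The classifier stacks three residual blocks; block `b` holds three
#' convolution stages with `filters[b]` feature maps and kernel sizes
#' `kernels` (8, 5, 3 by default), each followed by batch normalisation and a
#' rectified linear unit. A skip connection adds the block input (projected
#' through a width-1 convolution when channel counts differ) to the block
#' output before the final rectifier. Global average pooling over time feeds
#' a single logistic output unit, so the forward pass returns a selection
#' probability in (0, 1).
#'
#' @param input_length Series length L the network ingests.
#' @param filters Feature maps per residual block.
#' @param kernels Kernel sizes of the three stages within every block.
#' @param batchnorm Include batch normalisation after each convolution.
#' @return An object of class `resnet_config`.
#' @export
resnet_config <- function(input_length = 200L, filters = c(64L, 128L, 128L),
                          kernels = c(8L, 5L, 3L), batchnorm = TRUE) {
  input_length <- as.integer(input_length)
  filters <- as.integer(filters)
  kernels <- as.integer(kernels)
  stopifnot(length(filters) >= 1, length(kernels) == 3,
            all(filters > 0), all(kernels > 0))
  if (input_length < max(kernels)) {
    stop("`input_length` must be at least the largest kernel size",
         call. = FALSE)
  }
  structure(
    list(input_length = input_length, filters = filters, kernels = kernels,
         batchnorm = isTRUE(batchnorm)),
    class = "resnet_config"
  )
}

# He-normal conv weight, stored (C*K, F) with the k-th row block for offset k
.init_conv <- function(c_in, k, f) {
  matrix(stats::rnorm(c_in * k * f, 0, sqrt(2 / (c_in * k))), c_in * k, f)
}

#' Initialise an untrained residual network
#'
#' @param config A [resnet_config()].
#' @param seed Optional integer seed for the weight initialisation.
#' @return An object of class `resnet_tsc` holding weights, batch-norm
#'   running statistics, and the architecture config.
#' @export
resnet_init <- function(config = resnet_config(), seed = NULL) {
  stopifnot(inherits(config, "resnet_config"))
  if (!is.null(seed)) set.seed(seed)
  params <- list()
  running <- list()
  c_in <- 1L
  for (b in seq_along(config$filters)) {
    f <- config$filters[b]
    for (j in 1:3) {
      k <- config$kernels[j]
      cc <- if (j == 1) c_in else f
      id <- sprintf("b%d_c%d", b, j)
      params[[paste0(id, "_W")]] <- .init_conv(cc, k, f)
      params[[paste0(id, "_b")]] <- numeric(f)
      if (config$batchnorm) {
        params[[paste0(id, "_g")]] <- rep.int(1, f)
        params[[paste0(id, "_beta")]] <- numeric(f)
        running[[paste0(id, "_mean")]] <- numeric(f)
        running[[paste0(id, "_var")]] <- rep.int(1, f)
      }
    }
    if (c_in != f) {
      id <- sprintf("b%d_sc", b)
      params[[paste0(id, "_W")]] <- .init_conv(c_in, 1L, f)
      params[[paste0(id, "_b")]] <- numeric(f)
      if (config$batchnorm) {
        params[[paste0(id, "_g")]] <- rep.int(1, f)
        params[[paste0(id, "_beta")]] <- numeric(f)
        running[[paste0(id, "_mean")]] <- numeric(f)
        running[[paste0(id, "_var")]] <- rep.int(1, f)
      }
    }
    c_in <- f
  }
  params$head_w <- matrix(stats::rnorm(c_in, 0, sqrt(1 / c_in)), c_in, 1)
  params$head_b <- 0
  structure(
    list(config = config, params = params, running = running,
         trained = FALSE, manifest = NULL),
    class = "resnet_tsc"
  )
}

#' Number of trainable parameters
#' @param model A `resnet_tsc` model.
#' @return Integer count of trainable scalars (weights, biases, batch-norm
#'   scales and shifts).
#' @export
resnet_n_params <- function(model) {
  stopifnot(inherits(model, "resnet_tsc"))
  sum(vapply(model$params, length, integer(1)))
}

#' @export
print.resnet_tsc <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<resnet_tsc> %d residual blocks, filters [%s], kernels [%s]\n",
              length(cfg$filters), paste(cfg$filters, collapse = ", "),
              paste(cfg$kernels, collapse = ", ")))
  cat(sprintf("  input length %d, %d trainable parameters, %s\n",
              cfg$input_length, resnet_n_params(x),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# ---- layer primitives -------------------------------------------------------

.conv_fwd <- function(X, W, bias, K, B, L) {
  C <- nrow(W) %/% K
  nf <- ncol(W)
  out <- matrix(bias, B * L, nf, byrow = TRUE)
  pl <- (K - 1L) %/% 2L
  for (k in seq_len(K)) {
    d <- k - 1L - pl
    ls <- max(1L, 1L - d); le <- min(L, L - d)
    if (ls > le) next
    ro <- ((ls - 1L) * B + 1L):(le * B)
    ri <- ((ls + d - 1L) * B + 1L):((le + d) * B)
    wk <- W[((k - 1L) * C + 1L):(k * C), , drop = FALSE]
    out[ro, ] <- out[ro, ] + X[ri, , drop = FALSE] %*% wk
  }
  out
}

.conv_bwd <- function(dY, X, W, K, B, L) {
  C <- nrow(W) %/% K
  dW <- matrix(0, nrow(W), ncol(W))
  dX <- matrix(0, nrow(X), ncol(X))
  pl <- (K - 1L) %/% 2L
  for (k in seq_len(K)) {
    d <- k - 1L - pl
    ls <- max(1L, 1L - d); le <- min(L, L - d)
    if (ls > le) next
    ro <- ((ls - 1L) * B + 1L):(le * B)
    ri <- ((ls + d - 1L) * B + 1L):((le + d) * B)
    rows <- ((k - 1L) * C + 1L):(k * C)
    dW[rows, ] <- crossprod(X[ri, , drop = FALSE], dY[ro, , drop = FALSE])
    dX[ri, ] <- dX[ri, ] + dY[ro, , drop = FALSE] %*%
      t(W[rows, , drop = FALSE])
  }
  list(dX = dX, dW = dW, db = colSums(dY))
}

.bn_fwd <- function(X, g, beta, rmean, rvar, training, eps = 1e-5,
                    momentum = 0.9) {
  if (training) {
    mu <- colMeans(X)
    xc <- X - matrix(mu, nrow(X), ncol(X), byrow = TRUE)
    v <- colMeans(xc * xc)
    inv <- 1 / sqrt(v + eps)
    xhat <- xc * matrix(inv, nrow(X), ncol(X), byrow = TRUE)
    list(
      Y = xhat * matrix(g, nrow(X), ncol(X), byrow = TRUE) +
        matrix(beta, nrow(X), ncol(X), byrow = TRUE),
      xhat = xhat, inv = inv,
      rmean = momentum * rmean + (1 - momentum) * mu,
      rvar = momentum * rvar + (1 - momentum) * v
    )
  } else {
    inv <- 1 / sqrt(rvar + eps)
    scale <- g * inv
    shift <- beta - rmean * scale
    list(Y = X * matrix(scale, nrow(X), ncol(X), byrow = TRUE) +
           matrix(shift, nrow(X), ncol(X), byrow = TRUE))
  }
}

.bn_bwd <- function(dY, cache, g) {
  n <- nrow(dY)
  xhat <- cache$xhat
  dg <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- dY * matrix(g, n, ncol(dY), byrow = TRUE)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * xhat)
  dX <- (dxhat - matrix(s1 / n, n, ncol(dY), byrow = TRUE) -
           xhat * matrix(s2 / n, n, ncol(dY), byrow = TRUE)) *
    matrix(cache$inv, n, ncol(dY), byrow = TRUE)
  list(dX = dX, dg = dg, dbeta = dbeta)
}

# one conv(+bn) stage; returns activation and cache for backprop
.stage_fwd <- function(model, id, X, K, B, L, training, caches) {
  p <- model$params
  Y <- .conv_fwd(X, p[[paste0(id, "_W")]], p[[paste0(id, "_b")]], K, B, L)
  cache <- list(X = X, K = K)
  if (model$config$batchnorm) {
    bn <- .bn_fwd(Y, p[[paste0(id, "_g")]], p[[paste0(id, "_beta")]],
                  model$running[[paste0(id, "_mean")]],
                  model$running[[paste0(id, "_var")]], training)
    cache$bn <- bn[c("xhat", "inv")]
    if (training) {
      caches$running[[paste0(id, "_mean")]] <- bn$rmean
      caches$running[[paste0(id, "_var")]] <- bn$rvar
    }
    Y <- bn$Y
  }
  caches$layer[[id]] <- cache
  list(Y = Y, caches = caches)
}

.stage_bwd <- function(model, id, dY, grads, B, L) {
  p <- model$params
  cache <- grads$caches$layer[[id]]
  if (model$config$batchnorm) {
    bb <- .bn_bwd(dY, cache$bn, p[[paste0(id, "_g")]])
    grads$g[[paste0(id, "_g")]] <- bb$dg
    grads$g[[paste0(id, "_beta")]] <- bb$dbeta
    dY <- bb$dX
  }
  cb <- .conv_bwd(dY, cache$X, p[[paste0(id, "_W")]], cache$K, B, L)
  grads$g[[paste0(id, "_W")]] <- cb$dW
  grads$g[[paste0(id, "_b")]] <- cb$db
  grads$dX <- cb$dX
  grads
}

# full forward pass; X is a (B, L) matrix of series rows
.resnet_fwd <- function(model, X, training = FALSE) {
  cfg <- model$config
  B <- nrow(X); L <- ncol(X)
  act <- matrix(as.vector(X), ncol = 1)  # (B*L, 1), batch index fastest
  caches <- list(layer = list(), running = model$running, B = B, L = L)
  c_in <- 1L
  for (b in seq_along(cfg$filters)) {
    f <- cfg$filters[b]
    inp <- act
    st <- .stage_fwd(model, sprintf("b%d_c1", b), act, cfg$kernels[1],
                     B, L, training, caches)
    caches <- st$caches
    a1 <- st$Y; a1[a1 < 0] <- 0
    caches$layer[[sprintf("b%d_r1", b)]] <- a1 > 0

    st <- .stage_fwd(model, sprintf("b%d_c2", b), a1, cfg$kernels[2],
                     B, L, training, caches)
    caches <- st$caches
    a2 <- st$Y; a2[a2 < 0] <- 0
    caches$layer[[sprintf("b%d_r2", b)]] <- a2 > 0

    st <- .stage_fwd(model, sprintf("b%d_c3", b), a2, cfg$kernels[3],
                     B, L, training, caches)
    caches <- st$caches
    a3 <- st$Y

    if (c_in != f) {
      st <- .stage_fwd(model, sprintf("b%d_sc", b), inp, 1L, B, L,
                       training, caches)
      caches <- st$caches
      sc <- st$Y
    } else {
      sc <- inp
    }
    act <- a3 + sc
    act[act < 0] <- 0
    caches$layer[[sprintf("b%d_out", b)]] <- act > 0
    c_in <- f
  }
  gap_ids <- rep_len(seq_len(B), B * L)
  g <- rowsum(act, gap_ids) / L                       # (B, F)
  logit <- as.vector(g %*% model$params$head_w) + model$params$head_b
  prob <- stats::plogis(logit)
  caches$g <- g
  list(prob = prob, caches = caches)
}

# backward pass from BCE loss; y in {0,1}; returns named gradient list
.resnet_bwd <- function(model, fwd, y) {
  cfg <- model$config
  caches <- fwd$caches
  B <- caches$B; L <- caches$L
  dlogit <- (fwd$prob - y) / B
  grads <- list(g = list(), caches = caches)
  grads$g$head_w <- crossprod(caches$g, dlogit)
  grads$g$head_b <- sum(dlogit)
  dg <- dlogit %*% t(model$params$head_w)             # (B, F)
  dact <- dg[rep_len(seq_len(B), B * L), , drop = FALSE] / L

  for (b in rev(seq_along(cfg$filters))) {
    c_in <- if (b == 1) 1L else cfg$filters[b - 1]
    f <- cfg$filters[b]
    dact <- dact * caches$layer[[sprintf("b%d_out", b)]]
    d_a3 <- dact
    d_sc <- dact
    if (c_in != f) {
      grads <- .stage_bwd(model, sprintf("b%d_sc", b), d_sc, grads, B, L)
      d_inp_sc <- grads$dX
    } else {
      d_inp_sc <- d_sc
    }
    grads <- .stage_bwd(model, sprintf("b%d_c3", b), d_a3, grads, B, L)
    d_a2 <- grads$dX * caches$layer[[sprintf("b%d_r2", b)]]
    grads <- .stage_bwd(model, sprintf("b%d_c2", b), d_a2, grads, B, L)
    d_a1 <- grads$dX * caches$layer[[sprintf("b%d_r1", b)]]
    grads <- .stage_bwd(model, sprintf("b%d_c1", b), d_a1, grads, B, L)
    dact <- grads$dX + d_inp_sc
  }
  grads$g
}

# Adam update; state carries first/second moment estimates and step count
.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    gr <- grads[[nm]]
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- gr * 0
      state$v[[nm]] <- gr * 0
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr * gr
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

.bce <- function(prob, y, eps = 1e-12) {
  p <- pmin(1 - eps, pmax(eps, prob))
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Classify series with a residual network
#'
#' @param object A `resnet_tsc` model.
#' @param x A numeric matrix with one series per row (or a single series as a
#'   vector); row length must equal the model's `input_length`.
#' @param type `"prob"` for selection probabilities, `"label"` for
#'   `"drift"`/`"selection"` labels at the 0.5 threshold (a probability of
#'   exactly 0.5 is labelled drift: the threshold is a strict `>`).
#' @param ... Unused.
#' @return Numeric probabilities or a character vector of labels.
#' @export
predict.resnet_tsc <- function(object, x, type = c("prob", "label"), ...) {
  type <- match.arg(type)
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != object$config$input_length) {
    stop(sprintf("input length %d does not match model input_length %d",
                 ncol(x), object$config$input_length), call. = FALSE)
  }
  prob <- .resnet_fwd(object, x, training = FALSE)$prob
  if (type == "prob") prob else ifelse(prob > 0.5, "selection", "drift")
}

#' Save / load a trained classifier
#'
#' The checkpoint stores the weights, batch-norm running statistics, the
#' architecture config and the training manifest (seeds, training settings,
#' per-epoch log), so a reloaded model reproduces predictions exactly.
#'
#' @param model A `resnet_tsc` model.
#' @param path File path for the checkpoint.
#' @return `save_resnet` returns `path` invisibly; `load_resnet` returns the
#'   model.
#' @export
save_resnet <- function(model, path) {
  stopifnot(inherits(model, "resnet_tsc"))
  saveRDS(model, path)
  invisible(path)
}

#' @param path File path of an existing checkpoint.
#' @param expected_input_length Optional check: error if the stored model's
#'   input length differs (catches mixing checkpoints across pipelines).
#' @rdname save_resnet
#' @export
load_resnet <- function(path, expected_input_length = NULL) {
  model <- readRDS(path)
  if (!inherits(model, "resnet_tsc")) {
    stop("checkpoint does not contain a resnet_tsc model", call. = FALSE)
  }
  # config/weight consistency: head width must match the last block's filters
  f_last <- model$config$filters[length(model$config$filters)]
  if (nrow(model$params$head_w) != f_last) {
    stop("config mismatch: stored weights do not fit the stored config",
         call. = FALSE)
  }
  if (!is.null(expected_input_length) &&
      model$config$input_length != expected_input_length) {
    stop(sprintf(
      "config mismatch: checkpoint input_length is %d, expected %d",
      model$config$input_length, expected_input_length), call. = FALSE)
  }
  model
}
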