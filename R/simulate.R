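#' Construct a frequency trajectory object
#'
#' A `wf_trajectory` bundles one frequency time series with its provenance:
#' observation times, variant counts and totals where available, and the
#' generating label and selection coefficient for simulated series.
#'
#' @param times Strictly increasing numeric vector of time points.
#' @param freqs Numeric vector of relative frequencies in \[0, 1\],
#'   same length as `times`.
#' @param counts Optional integer vector of variant-A counts per time point.
#' @param trials Optional integer vector of total counts per time point.
#' @param label `"drift"`, `"selection"`, or `NA` for observed data.
#' @param beta Generating selection coefficient, or `NA` for observed data.
#' @return An object of class `wf_trajectory`.
#' @export
wf_trajectory <- function(times, freqs, counts = NULL, trials = NULL,
                          label = NA_character_, beta = NA_real_) {
  times <- as.numeric(times)
  freqs <- as.numeric(freqs)
  if (length(times) != length(freqs)) {
    stop("`times` and `freqs` must have the same length", call. = FALSE)
  }
  if (length(times) && any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  if (anyNA(freqs) || any(freqs < 0 | freqs > 1)) {
    stop("`freqs` must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(counts) != !is.null(trials)) {
    stop("supply `counts` and `trials` together or not at all", call. = FALSE)
  }
  if (!is.null(counts)) {
    if (length(counts) != length(freqs) || length(trials) != length(freqs)) {
      stop("`counts`/`trials` must match the series length", call. = FALSE)
    }
    if (any(counts < 0) || any(trials <= 0) || any(counts > trials)) {
      stop("need 0 <= counts <= trials, trials > 0", call. = FALSE)
    }
  }
  if (!is.na(label) && !label %in% c("drift", "selection")) {
    stop('`label` must be "drift" or "selection"', call. = FALSE)
  }
  structure(
    list(times = times, freqs = freqs, counts = counts, trials = trials,
         label = label, beta = beta),
    class = "wf_trajectory"
  )
}

#' @export
print.wf_trajectory <- function(x, ...) {
  n <- length(x$times)
  lab <- if (is.na(x$label)) "observed" else x$label
  cat(sprintf("<wf_trajectory> %d time points, %s", n, lab))
  if (!is.na(x$beta)) cat(sprintf(" (beta = %g)", x$beta))
  cat("\n")
  if (n) {
    cat(sprintf("  t in [%g, %g], f in [%.3f, %.3f]\n",
                x$times[1], x$times[n], min(x$freqs), max(x$freqs)))
  }
  invisible(x)
}

#' @export
length.wf_trajectory <- function(x) length(x$times)

#' Simulate one Wright-Fisher frequency trajectory
#'
#' Forward simulation of a haploid Wright-Fisher population of constant size
#' `N` over `T` discrete, non-overlapping generations. The variant-A count in
#' generation \eqn{t+1} is drawn as
#' \eqn{z(t+1) \sim \mathrm{Binomial}(N,\ g(f(t)))}, where \eqn{g} is the
#' selection-pressure map of [selection_pressure()]; `beta = 0` gives neutral
#' drift. The boundaries are absorbing.
#'
#' @param N Population size (trials per generation), a positive integer.
#' @param T Number of generations, at least 2.
#' @param beta Selection coefficient, non-negative; 0 means drift.
#' @param start_freq Initial frequency in \[0, 1\], or `"uniform"` to draw it
#'   from `runif(1, start_range[1], start_range[2])`.
#' @param start_range Bounds for the uniform starting frequency; the default
#'   (0.05, 0.95) avoids immediate absorption.
#' @param form Selection-pressure functional form, see [selection_pressure()].
#' @param seed Optional integer seed for reproducibility.
#' @return A [wf_trajectory()] with `times = 0:(T-1)`, per-generation counts,
#'   `trials` all equal to `N`, and `label = "drift"` iff `beta == 0`.
#' @examples
#' tr <- wf_simulate(N = 1000, T = 200, beta = 0, start_freq = 0.5, seed = 1)
#' tr
#' @export
wf_simulate <- function(N, T, beta = 0, start_freq = 0.5,
                        start_range = c(0.05, 0.95),
                        form = c("fitness", "additive"), seed = NULL) {
  form <- match.arg(form)
  stopifnot(N >= 1, T >= 2, beta >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (identical(start_freq, "uniform")) {
    start_freq <- stats::runif(1, start_range[1], start_range[2])
  }
  stopifnot(start_freq >= 0, start_freq <= 1)

  counts <- integer(T)
  counts[1] <- as.integer(round(start_freq * N))
  for (i in 2:T) {
    p <- selection_pressure(counts[i - 1] / N, beta, form = form)
    counts[i] <- stats::rbinom(1L, N, p)
  }
  wf_trajectory(
    times = 0:(T - 1), freqs = counts / N,
    counts = counts, trials = rep.int(as.integer(N), T),
    label = if (beta == 0) "drift" else "selection", beta = beta
  )
}

#' Simulate many Wright-Fisher trajectories at once
#'
#' Vectorised replicate simulator used by the evaluation harness: all `n`
#' series share `N`, `T`, `beta` and the starting frequency, and are advanced
#' generation by generation with a single binomial draw per generation.
#'
#' @inheritParams wf_simulate
#' @param n Number of replicate trajectories.
#' @return An `n` by `T` integer matrix of variant-A counts; divide by `N`
#'   for frequencies. Row `i` is one trajectory.
#' @export
wf_simulate_matrix <- function(n, N, T, beta = 0, start_freq = 0.5,
                               form = c("fitness", "additive"), seed = NULL) {
  form <- match.arg(form)
  stopifnot(n >= 1, N >= 1, T >= 2, beta >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (identical(start_freq, "uniform")) {
    start0 <- stats::runif(n, 0.05, 0.95)
  } else {
    start0 <- rep_len(start_freq, n)
  }
  z <- matrix(0L, nrow = n, ncol = T)
  z[, 1] <- as.integer(round(start0 * N))
  for (i in 2:T) {
    p <- selection_pressure(z[, i - 1] / N, beta, form = form)
    z[, i] <- stats::rbinom(n, N, p)
  }
  z
}

#' Draw selection coefficients from a log-uniform distribution
#'
#' Training batches use many weakly selected series; drawing \eqn{\beta} so
#' that \eqn{\log\beta} is uniform on \eqn{[\log\beta_{min}, \log\beta_{max}]}
#' concentrates mass near the drift boundary where classification is hardest.
#'
#' @param n Number of draws.
#' @param beta_range Length-2 positive numeric, `c(beta_min, beta_max)` with
#'   `beta_min <= beta_max`.
#' @return Numeric vector of `n` coefficients.
#' @examples
#' set.seed(1)
#' median(sample_beta(1e4, c(1e-3, 1)))  # close to 10^(-1.5)
#' @export
sample_beta <- function(n, beta_range = c(1e-3, 1)) {
  if (length(beta_range) != 2L || any(beta_range <= 0)) {
    stop("`beta_range` must be two positive numbers", call. = FALSE)
  }
  if (beta_range[1] > beta_range[2]) {
    stop("`beta_range` must be increasing", call. = FALSE)
  }
  exp(stats::runif(n, log(beta_range[1]), log(beta_range[2])))
}
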