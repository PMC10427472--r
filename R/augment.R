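#' Distortion settings for simulated training series
#'
#' Bundles the parameters of the corpus-style distortion pipeline applied to
#' raw Wright-Fisher trajectories before they reach the classifier: Gaussian
#' frequency noise, pooling into a random number of temporal segments, and
#' right zero-padding to a fixed length.
#'
#' @param noise_sigma Standard deviation of the zero-mean Gaussian noise added
#'   to each frequency (dimensionless, >= 0). Noisy values are clipped to
#'   \[0, 1\].
#' @param bin_range Inclusive integer interval `c(b_min, b_max)` from which the
#'   number of temporal segments is drawn uniformly, with
#'   `2 <= b_min <= b_max`.
#' @param pad_to Fixed output length fed to the classifier.
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(noise_sigma = 0.05, bin_range = c(4L, 200L),
                           pad_to = 200L) {
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0", call. = FALSE)
  bin_range <- as.integer(bin_range)
  if (length(bin_range) != 2L || bin_range[1] < 2L ||
      bin_range[1] > bin_range[2]) {
    stop("`bin_range` must be an increasing integer pair with b_min >= 2",
         call. = FALSE)
  }
  if (pad_to < bin_range[2]) {
    stop("`pad_to` must be at least b_max", call. = FALSE)
  }
  structure(
    list(noise_sigma = noise_sigma, bin_range = bin_range,
         pad_to = as.integer(pad_to)),
    class = "augment_config"
  )
}

# contiguous near-equal segment ids for n points in b segments, larger first
segment_ids <- function(n, b) {
  sizes <- rep.int(n %/% b, b)
  extra <- n %% b
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  rep.int(seq_len(b), sizes)
}

#' Pool a trajectory into temporal segments
#'
#' Partitions the time axis into `n_bins` contiguous segments of near-equal
#' size (sizes differ by at most one, larger segments first). Where counts are
#' available the segment frequency is the pooled ratio
#' \eqn{\sum z / \sum \mathrm{trials}}; otherwise it is the mean of member
#' frequencies. Segment times are the segment indices `0:(n_bins-1)`.
#'
#' @param traj A [wf_trajectory()].
#' @param n_bins Number of segments, between 2 and `length(traj)`.
#' @return A binned [wf_trajectory()] with `n_bins` time points.
#' @export
bin_series <- function(traj, n_bins) {
  stopifnot(inherits(traj, "wf_trajectory"))
  n <- length(traj$freqs)
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L || n_bins > n) {
    stop("`n_bins` must be between 2 and the series length", call. = FALSE)
  }
  ids <- segment_ids(n, n_bins)
  if (!is.null(traj$counts)) {
    z <- as.vector(rowsum(traj$counts, ids))
    tot <- as.vector(rowsum(traj$trials, ids))
    wf_trajectory(times = 0:(n_bins - 1), freqs = z / tot,
                  counts = z, trials = tot,
                  label = traj$label, beta = traj$beta)
  } else {
    f <- as.vector(rowsum(traj$freqs, ids)) / tabulate(ids, n_bins)
    wf_trajectory(times = 0:(n_bins - 1), freqs = f,
                  label = traj$label, beta = traj$beta)
  }
}

#' Add truncated Gaussian noise to frequencies
#'
#' Adds an independent \eqn{N(0, \sigma^2)} error to every frequency and clips
#' the result to \[0, 1\], emulating measurement noise in sparse corpus counts.
#'
#' @param freqs Numeric vector of frequencies in \[0, 1\].
#' @param noise_sigma Noise standard deviation, >= 0.
#' @return Distorted frequencies, same length.
#' @export
distort_frequencies <- function(freqs, noise_sigma) {
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0", call. = FALSE)
  if (noise_sigma == 0) return(freqs)
  pmin(1, pmax(0, freqs + stats::rnorm(length(freqs), 0, noise_sigma)))
}

#' Right-pad a series with zeros to a fixed length
#'
#' Classifier inputs must share one length; shorter (e.g. binned) series are
#' extended with trailing zeros. Padding is on the right so that the observed
#' values keep their positions relative to the series start.
#'
#' @param freqs Non-empty numeric vector, length at most `pad_to`.
#' @param pad_to Target length.
#' @return Numeric vector of length `pad_to`.
#' @export
pad_series <- function(freqs, pad_to) {
  n <- length(freqs)
  if (n == 0L) stop("cannot pad an empty series", call. = FALSE)
  if (n > pad_to) {
    stop("series longer than `pad_to`; refusing to truncate", call. = FALSE)
  }
  c(freqs, numeric(pad_to - n))
}

# vectorised selection pressure with per-series beta (internal fast path)
.pressure_vec <- function(f, beta, form) {
  if (form == "fitness") f * (1 + beta) / (1 + f * beta)
  else pmin(1, pmax(0, f + beta * f * (1 - f)))
}

#' Generate a balanced, augmented training batch
#'
#' Produces `n` labelled classifier inputs: exactly `n/2` drift series
#' (`beta = 0`) and `n/2` selection series with `beta` drawn by
#' [sample_beta()]. Each series is simulated forward (starting frequency
#' uniform on `start_range`), pooled into a uniformly drawn number of temporal
#' segments, perturbed with Gaussian frequency noise, and right-padded to
#' `aug$pad_to`.
#'
#' @param n Even batch size.
#' @param N Population size.
#' @param T Generations simulated per series.
#' @param aug An [augment_config()].
#' @param beta_range Passed to [sample_beta()] for the selection half.
#' @param start_range Uniform bounds for starting frequencies.
#' @param form Selection-pressure form, see [selection_pressure()].
#' @return A list with elements `x` (`n` by `pad_to` numeric matrix), `y`
#'   (0 = drift, 1 = selection), `beta`, `n_bins` and `n_obs` (unpadded
#'   lengths). Rows are shuffled so labels are not blocked.
#' @export
generate_batch <- function(n, N = 1000, T = 200, aug = augment_config(),
                           beta_range = c(1e-3, 1),
                           start_range = c(0.05, 0.95),
                           form = c("fitness", "additive")) {
  form <- match.arg(form)
  if (n %% 2L) stop("`n` must be even for balanced classes", call. = FALSE)
  if (aug$bin_range[2] > T) {
    stop("`aug$bin_range` exceeds the series length T", call. = FALSE)
  }
  half <- n %/% 2L
  beta <- c(numeric(half), sample_beta(half, beta_range))
  y <- c(integer(half), rep.int(1L, half))

  # advance all series together, one binomial draw per generation
  z <- matrix(0L, nrow = n, ncol = T)
  z[, 1] <- as.integer(round(stats::runif(n, start_range[1], start_range[2]) * N))
  for (i in 2:T) {
    p <- .pressure_vec(z[, i - 1] / N, beta, form)
    z[, i] <- stats::rbinom(n, N, p)
  }

  n_bins <- sample.int(aug$bin_range[2] - aug$bin_range[1] + 1L, n,
                       replace = TRUE) + aug$bin_range[1] - 1L
  x <- matrix(0, nrow = n, ncol = aug$pad_to)
  for (j in seq_len(n)) {
    b <- n_bins[j]
    f <- as.vector(rowsum(z[j, ], segment_ids(T, b))) /
      (N * tabulate(segment_ids(T, b), b))
    x[j, seq_len(b)] <- distort_frequencies(f, aug$noise_sigma)
  }
  ord <- sample.int(n)
  list(x = x[ord, , drop = FALSE], y = y[ord], beta = beta[ord],
       n_bins = n_bins[ord], n_obs = n_bins[ord])
}
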