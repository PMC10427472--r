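#' Rescaled frequency increments
#'
#' Rescales successive frequency changes so that, under neutral Wright-Fisher
#' drift, they are approximately normal with mean zero and a common variance:
#' \deqn{Q_i = \frac{f(t_i) - f(t_{i-1})}
#'   {\sqrt{2\, f(t_{i-1})\,(1 - f(t_{i-1}))\,(t_i - t_{i-1})}}.}
#' Directional selection shifts the mean of \eqn{Q} away from zero, which is
#' what the Frequency Increment Test examines.
#'
#' An increment *into* an absorbing value (0 or 1) is well defined and kept;
#' an increment *from* an absorbing value has a zero denominator and is an
#' error here — truncate with [truncate_at_absorption()] first.
#'
#' @param times Strictly increasing numeric vector, length >= 2.
#' @param freqs Frequencies in \[0, 1\], same length as `times`.
#' @return Numeric vector of `length(freqs) - 1` rescaled increments.
#' @examples
#' frequency_increments(0:2, c(0.2, 0.3, 0.4))
#' @export
frequency_increments <- function(times, freqs) {
  n <- length(freqs)
  if (n < 2L || length(times) != n) {
    stop("need matching `times`/`freqs` of length >= 2", call. = FALSE)
  }
  f0 <- freqs[-n]
  if (any(f0 <= 0 | f0 >= 1)) {
    stop("degenerate increment: a leading frequency is 0 or 1; ",
         "truncate at absorption first", call. = FALSE)
  }
  (freqs[-1] - f0) / sqrt(2 * f0 * (1 - f0) * diff(times))
}

#' Truncate a series at its first absorption event
#'
#' Once a frequency reaches 0 or 1 the Wright-Fisher process cannot leave it,
#' so later values carry no information and would produce degenerate
#' increments. Returns the prefix before the first absorbing value (the whole
#' series when none occurs).
#'
#' By default the absorbing value itself is dropped as well: the last step
#' into the boundary is taken where the binomial increment distribution is at
#' its most skewed, and retaining it visibly distorts the normality gate of
#' [fit_test()] on strongly selected series. Set `keep_absorbing = TRUE` to
#' retain the first absorbing value (and so the final increment into it).
#'
#' @param freqs Frequencies in \[0, 1\].
#' @param times Matching time points.
#' @param keep_absorbing Keep the first absorbing value in the prefix.
#' @return A list with the truncated `freqs`, `times`, and a logical
#'   `truncated` flag.
#' @export
truncate_at_absorption <- function(freqs, times, keep_absorbing = FALSE) {
  hit <- which(freqs == 0 | freqs == 1)
  last <- if (keep_absorbing) length(freqs) else length(freqs) + 1L
  if (length(hit) == 0L || hit[1] >= last) {
    list(freqs = freqs, times = times, truncated = FALSE)
  } else {
    keep <- seq_len(hit[1] - !keep_absorbing)
    list(freqs = freqs[keep], times = times[keep], truncated = TRUE)
  }
}

#' The Frequency Increment Test
#'
#' Tests a frequency time series for directional selection against a null of
#' neutral drift. The pipeline is: truncate at the first absorption event,
#' rescale to frequency increments ([frequency_increments()]), gate on
#' normality of the increments with a Shapiro-Wilk test, then run a two-sided
#' one-sample t-test of the mean increment against zero. The null (drift) is
#' rejected when the t-test p-value falls below `alpha`.
#'
#' The test is *inapplicable* — no verdict is returned — when the increments
#' fail the normality gate (`shapiro_p < shapiro_threshold`), when fewer than
#' `min_increments` increments remain after truncation, or when the
#' increments have zero variance (the t statistic is undefined).
#'
#' @param series A [wf_trajectory()], or a numeric vector of frequencies.
#' @param times Time points when `series` is a bare numeric vector; defaults
#'   to `0:(length(series)-1)`.
#' @param alpha Rejection threshold for the t-test p-value.
#' @param shapiro_threshold Minimum Shapiro-Wilk p-value for the normality
#'   assumption to be considered met.
#' @param min_increments Minimum number of increments needed for a verdict.
#' @param keep_absorbing Passed to [truncate_at_absorption()]; the default
#'   drops the boundary value itself, see there.
#' @return An object of class `fit_result`: a list with `increments`,
#'   `mean_increment`, `t_statistic`, `p_value`, `shapiro_p`, `n_increments`,
#'   `applicable`, `truncated`, `reason` (why inapplicable, or `NA`) and
#'   `verdict` (`"drift"`, `"selection"`, or `"inapplicable"`).
#' @examples
#' tr <- wf_simulate(1000, 200, beta = 0.1, start_freq = 0.5, seed = 42)
#' fit_test(tr)
#' @export
fit_test <- function(series, times = NULL, alpha = 0.05,
                     shapiro_threshold = 0.1, min_increments = 3L,
                     keep_absorbing = FALSE) {
  if (inherits(series, "wf_trajectory")) {
    freqs <- series$freqs
    times <- series$times
  } else {
    freqs <- as.numeric(series)
    if (is.null(times)) times <- seq_along(freqs) - 1
  }
  if (length(freqs) < 2L) {
    stop("series must have at least 2 time points", call. = FALSE)
  }

  tr <- truncate_at_absorption(freqs, times, keep_absorbing = keep_absorbing)
  res <- list(
    increments = numeric(0), mean_increment = NA_real_,
    t_statistic = NA_real_, p_value = NA_real_, shapiro_p = NA_real_,
    n_increments = 0L, applicable = FALSE, truncated = tr$truncated,
    reason = NA_character_, verdict = "inapplicable",
    alpha = alpha, shapiro_threshold = shapiro_threshold
  )
  class(res) <- "fit_result"

  if (length(tr$freqs) < 2L) {
    res$reason <- "too_few_points"
    return(res)
  }
  q <- frequency_increments(tr$times, tr$freqs)
  res$increments <- q
  res$n_increments <- length(q)
  res$mean_increment <- mean(q)

  if (length(q) < max(3L, min_increments)) {
    res$reason <- "too_few_increments"
    return(res)
  }
  if (stats::sd(q) == 0) {
    res$reason <- "zero_variance_increments"
    return(res)
  }
  res$shapiro_p <- stats::shapiro.test(q)$p.value
  if (res$shapiro_p < shapiro_threshold) {
    res$reason <- "non_normal_increments"
    return(res)
  }
  tt <- stats::t.test(q, mu = 0)
  res$t_statistic <- unname(tt$statistic)
  res$p_value <- tt$p.value
  res$applicable <- TRUE
  res$verdict <- if (res$p_value < alpha) "selection" else "drift"
  res
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> Frequency Increment Test\n")
  cat(sprintf("  increments: %d%s\n", x$n_increments,
              if (x$truncated) " (truncated at absorption)" else ""))
  if (!is.na(x$shapiro_p)) {
    cat(sprintf("  mean(Q) = %.4f, t = %.3f, p = %.4g, shapiro p = %.4g\n",
                x$mean_increment, x$t_statistic, x$p_value, x$shapiro_p))
  }
  cat(sprintf("  verdict: %s%s\n", x$verdict,
              if (!is.na(x$reason)) paste0(" (", x$reason, ")") else ""))
  invisible(x)
}

#' Turn FIT results into a data frame
#'
#' @param results A `fit_result` or a list of them.
#' @param ids Optional series identifiers.
#' @return One row per result with the test's summary columns.
#' @export
fit_results_table <- function(results, ids = NULL) {
  if (inherits(results, "fit_result")) results <- list(results)
  if (is.null(ids)) ids <- seq_along(results)
  do.call(rbind, Map(function(r, id) {
    data.frame(
      series_id = id, n_increments = r$n_increments,
      mean_Q = r$mean_increment, t = r$t_statistic, p = r$p_value,
      shapiro_p = r$shapiro_p, applicable = r$applicable,
      truncated = r$truncated, verdict = r$verdict,
      stringsAsFactors = FALSE
    )
  }, results, ids))
}

#' Quantile bin count from token volume
#'
#' Number of variable-width (quantile) bins for a series observed through `v`
#' tokens: \eqn{\lceil c \ln v \rceil}. Sparse series get few bins, abundant
#' ones more, keeping per-bin token counts comparable.
#'
#' @param v Total token count, a positive integer.
#' @param c Bin-count constant, > 0.
#' @return Integer bin count, at least 1.
#' @examples
#' quantile_bin_count(100)        # ceiling(ln 100) = 5
#' quantile_bin_count(100, c = 2) # 10
#' @export
quantile_bin_count <- function(v, c = 1) {
  stopifnot(v >= 1, c > 0)
  max(1L, as.integer(ceiling(c * log(v))))
}
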