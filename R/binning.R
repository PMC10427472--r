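#' Pool yearly variant counts into fixed-width calendar windows
#'
#' Groups per-year counts of a variant into consecutive calendar windows of
#' `width_years`, anchored at the earliest observed year. Counts are summed
#' within each window; windows with no tokens are dropped (not interpolated),
#' so the time stamps of the surviving windows carry the real gaps into the
#' increment rescaling. The window time stamp is its calendar midpoint.
#'
#' @param years Integer years, ascending (duplicates allowed; summed).
#' @param countsA Variant-A counts per row, `0 <= countsA <= totals`.
#' @param totals Total token counts per row.
#' @param width_years Window width in years, >= 1.
#' @return A [wf_trajectory()] with pooled counts and window-midpoint times.
#' @export
fixed_width_bins <- function(years, countsA, totals, width_years) {
  stopifnot(length(years) == length(countsA), length(years) == length(totals),
            width_years >= 1)
  if (any(countsA < 0) || any(totals < 0) || any(countsA > totals)) {
    stop("need 0 <= countsA <= totals", call. = FALSE)
  }
  win <- (years - min(years)) %/% width_years
  z <- rowsum(countsA, win)
  tot <- rowsum(totals, win)
  keep <- tot[, 1] > 0
  if (!any(keep)) stop("no data after binning", call. = FALSE)
  widx <- as.numeric(rownames(z))[keep]
  mid <- min(years) + widx * width_years + (width_years - 1) / 2
  wf_trajectory(times = mid, freqs = z[keep, 1] / tot[keep, 1],
                counts = z[keep, 1], trials = tot[keep, 1])
}

#' Pool per-token observations into variable-width quantile bins
#'
#' Splits a time-sorted sequence of token observations into
#' \eqn{\lceil c \ln v \rceil} contiguous groups of near-equal token count
#' (`v` = total tokens), so every bin rests on roughly the same evidence.
#' Tokens sharing a year that straddles a bin boundary are split by their
#' stable input order. Each bin's frequency is the share of variant-A tokens
#' and its time stamp is the mean token year.
#'
#' @param years Year of each token, sorted non-decreasing.
#' @param variant Logical (or 0/1) per token: `TRUE` for variant A.
#' @param c Bin-count constant, see [quantile_bin_count()].
#' @return A [wf_trajectory()] with one point per quantile bin. Bins whose
#'   mean years coincide are merged to keep times strictly increasing.
#' @export
variable_width_bins <- function(years, variant, c = 1) {
  v <- length(years)
  if (v < 2L) stop("need at least 2 tokens", call. = FALSE)
  stopifnot(length(variant) == v, c > 0)
  if (is.unsorted(years)) stop("tokens must be time-sorted", call. = FALSE)
  variant <- as.integer(as.logical(variant))

  b <- quantile_bin_count(v, c)
  ids <- segment_ids(v, b)
  z <- as.vector(rowsum(variant, ids))
  tot <- tabulate(ids, b)
  mid <- as.vector(rowsum(as.numeric(years), ids)) / tot

  # merge bins with identical mean years (possible when one year dominates)
  grp <- cumsum(c(TRUE, diff(mid) > 0))
  z <- as.vector(rowsum(z, grp))
  tot <- as.vector(rowsum(tot, grp))
  mid <- as.vector(rowsum(mid * tabulate(ids, b), grp)) / tot

  wf_trajectory(times = mid, freqs = z / tot, counts = z, trials = tot)
}
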