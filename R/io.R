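#' Read a variant count table from delimited text
#'
#' Expects a header with columns `series_id`, `time`, `count_variant`,
#' `count_total` (comma- or tab-separated, auto-detected from the header
#' line). Rows violating the invariants (`0 <= count_variant <= count_total`,
#' integer counts) are reported with their line numbers. Duplicate
#' `(series_id, time)` rows are summed, with a message.
#'
#' @param path Path to the delimited file.
#' @return A data frame with the four columns, times sorted within series.
#' @export
read_counts <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("series_id", "time", "count_variant", "count_total")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  bad_int <- which(df$count_variant %% 1 != 0 | df$count_total %% 1 != 0)
  if (length(bad_int)) {
    stop("non-integer counts on line(s): ",
         paste(bad_int + 1L, collapse = ", "), call. = FALSE)
  }
  bad <- which(df$count_variant < 0 | df$count_total <= 0 |
                 df$count_variant > df$count_total)
  if (length(bad)) {
    stop("count_variant must lie in [0, count_total] (count_total > 0); ",
         "violated on line(s): ", paste(bad + 1L, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(df$series_id, df$time, sep = "\r")
  if (anyDuplicated(key)) {
    message("summing duplicate (series_id, time) rows")
    df <- aggregate(cbind(count_variant, count_total) ~ series_id + time,
                    data = df, FUN = sum)
  }
  df[order(df$series_id, df$time), need]
}

#' Write / read a simulated classifier dataset
#'
#' One row per padded series: `id`, `label`, `beta`, `n_bins`, then the `L`
#' frequency columns. Frequencies are written at full precision so a
#' round-trip reproduces them exactly.
#'
#' @param batch A batch from [generate_batch()].
#' @param path Output CSV path.
#' @param manifest Optional list (parameters, seed) written as a JSON sidecar
#'   at `paste0(path, ".json")`.
#' @return `write_series_dataset` returns `path` invisibly;
#'   `read_series_dataset` returns a batch-shaped list (`x`, `y`, `beta`,
#'   `n_bins`).
#' @export
write_series_dataset <- function(batch, path, manifest = NULL) {
  L <- ncol(batch$x)
  df <- data.frame(id = seq_len(nrow(batch$x)),
                   label = ifelse(batch$y == 1, "selection", "drift"),
                   beta = batch$beta, n_bins = batch$n_bins)
  xs <- as.data.frame(batch$x)
  names(xs) <- paste0("f", seq_len(L))
  utils::write.csv(format(cbind(df, xs), digits = 17, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  if (!is.null(manifest)) {
    jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_series_dataset
#' @export
read_series_dataset <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  fcols <- grep("^f[0-9]+$", names(df))
  list(x = as.matrix(df[, fcols]),
       y = as.integer(df$label == "selection"),
       beta = df$beta, n_bins = df$n_bins)
}

#' Generate a synthetic corpus-style variant count table
#'
#' Emulates the structure of historical corpus series (two competing
#' variants, sparse counts, non-uniform temporal coverage) with known ground
#' truth: underlying frequencies follow Wright-Fisher trajectories (half
#' drift, half selection with `beta` drawn by [sample_beta()]), one
#' generation per calendar year, observed through per-year token totals drawn
#' from a heavy-tailed (geometric) count distribution in which some years
#' carry no tokens at all.
#'
#' @param n_series Number of series (even, for balanced labels).
#' @param year_range Inclusive calendar span, e.g. `c(1810, 2009)`.
#' @param sparsity Probability that a year has no tokens, in \[0, 1).
#' @param mean_tokens Mean token count of a non-empty year.
#' @param N Population size of the latent Wright-Fisher process.
#' @param beta_range Range for the selection-series coefficients.
#' @return A list with `counts` (a long-format data frame as in
#'   [read_counts()]) and `truth` (per-series `series_id`, `label`, `beta`).
#' @export
make_corpus_fixture <- function(n_series = 36, year_range = c(1810, 2009),
                                sparsity = 0.3, mean_tokens = 20,
                                N = 1000, beta_range = c(0.01, 1)) {
  if (n_series %% 2L) stop("`n_series` must be even", call. = FALSE)
  stopifnot(sparsity >= 0, sparsity < 1, mean_tokens > 0)
  years <- year_range[1]:year_range[2]
  T <- length(years)
  half <- n_series %/% 2L
  beta <- c(numeric(half), sample_beta(half, beta_range))
  rows <- list()
  for (s in seq_len(n_series)) {
    z <- wf_simulate_matrix(1, N, T, beta = beta[s], start_freq = "uniform")
    f <- z[1, ] / N
    totals <- ifelse(stats::runif(T) < sparsity, 0L,
                     stats::rgeom(T, 1 / mean_tokens) + 1L)
    keep <- totals > 0L
    rows[[s]] <- data.frame(
      series_id = sprintf("series%02d", s),
      time = years[keep],
      count_variant = stats::rbinom(sum(keep), totals[keep], f[keep]),
      count_total = totals[keep],
      stringsAsFactors = FALSE
    )
  }
  list(
    counts = do.call(rbind, rows),
    truth = data.frame(series_id = sprintf("series%02d", seq_len(n_series)),
                       label = ifelse(beta > 0, "selection", "drift"),
                       beta = beta, stringsAsFactors = FALSE)
  )
}
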