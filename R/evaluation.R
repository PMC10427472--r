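# Simulation studies comparing the two detectors: per-coefficient accuracy,
# selection-by-binning error grids, and false-positive-vs-bins curves.

# Run the FIT pipeline over rows of a count matrix (one trajectory per row).
# Returns a data.frame with one row per series: applicable, reject, verdict.
.fit_batch <- function(z, N, n_bins = NULL, alpha = 0.05,
                       shapiro_threshold = 0.1, min_increments = 3L) {
  T <- ncol(z)
  n <- nrow(z)
  if (!is.null(n_bins)) {
    ids <- segment_ids(T, n_bins)
    sizes <- tabulate(ids, n_bins)
  }
  out <- data.frame(applicable = logical(n), reject = NA,
                    truncated = logical(n), verdict = character(n),
                    stringsAsFactors = FALSE)
  for (j in seq_len(n)) {
    if (is.null(n_bins)) {
      freqs <- z[j, ] / N
      times <- 0:(T - 1)
    } else {
      freqs <- as.vector(rowsum(z[j, ], ids)) / (N * sizes)
      times <- 0:(n_bins - 1)
    }
    r <- fit_test(freqs, times = times, alpha = alpha,
                  shapiro_threshold = shapiro_threshold,
                  min_increments = min_increments)
    out$applicable[j] <- r$applicable
    out$reject[j] <- if (r$applicable) r$p_value < alpha else NA
    out$truncated[j] <- r$truncated
    out$verdict[j] <- r$verdict
  }
  out
}

# classifier inputs from a count matrix: bin (optional), pad to model length
.tsc_inputs <- function(z, N, n_bins, input_length) {
  T <- ncol(z)
  if (is.null(n_bins)) {
    f <- z / N
  } else {
    ids <- segment_ids(T, n_bins)
    sizes <- tabulate(ids, n_bins)
    f <- t(rowsum(t(z), ids)) / matrix(N * sizes, nrow(z), n_bins,
                                       byrow = TRUE)
  }
  if (ncol(f) > input_length) {
    stop("series longer than the classifier input length; bin first",
         call. = FALSE)
  }
  cbind(f, matrix(0, nrow(f), input_length - ncol(f)))
}

#' Detector accuracy on replicate simulations at one selection coefficient
#'
#' Simulates `n` Wright-Fisher trajectories at a fixed `beta`, optionally
#' pools each into `n_bins` temporal segments, and scores a detector against
#' the ground truth (drift iff `beta == 0`). The FIT branch truncates at
#' absorption and computes accuracy over applicable series only, reporting
#' the inapplicable fraction alongside; the classifier branch scores every
#' series.
#'
#' @param detector `"fit"` or `"tsc"`.
#' @param beta Selection coefficient of the simulated series.
#' @param n Number of replicate simulations.
#' @param T Generations per series.
#' @param N Population size.
#' @param f0 Starting frequency.
#' @param n_bins Optional number of temporal segments (`NULL` = no binning).
#' @param model Trained `resnet_tsc`, required when `detector = "tsc"`.
#' @param alpha,shapiro_threshold,min_increments FIT settings, see
#'   [fit_test()].
#' @return A list with `accuracy`, `inapplicable_fraction` (NA for the
#'   classifier), `n`, and `n_applicable`.
#' @export
accuracy_experiment <- function(detector = c("fit", "tsc"), beta, n = 1000,
                                T = 200, N = 1000, f0 = 0.5, n_bins = NULL,
                                model = NULL, alpha = 0.05,
                                shapiro_threshold = 0.1,
                                min_increments = 3L) {
  detector <- match.arg(detector)
  z <- wf_simulate_matrix(n, N, T, beta = beta, start_freq = f0)
  truth_sel <- beta > 0
  if (detector == "fit") {
    res <- .fit_batch(z, N, n_bins = n_bins, alpha = alpha,
                      shapiro_threshold = shapiro_threshold,
                      min_increments = min_increments)
    app <- res$applicable
    correct <- if (truth_sel) res$reject[app] else !res$reject[app]
    list(accuracy = mean(correct), inapplicable_fraction = mean(!app),
         n = n, n_applicable = sum(app))
  } else {
    if (is.null(model) || !isTRUE(model$trained)) {
      stop("a trained classifier model is required for detector = \"tsc\"",
           call. = FALSE)
    }
    x <- .tsc_inputs(z, N, n_bins, model$config$input_length)
    pred_sel <- predict(model, x) > 0.5
    list(accuracy = mean(pred_sel == truth_sel),
         inapplicable_fraction = NA_real_, n = n, n_applicable = n)
  }
}

#' Error-rate grid over selection coefficients and bin counts
#'
#' For every combination of `beta` and bin count, simulates `n` trajectories
#' and records each detector's mean error rate; for the FIT, the masked
#' fraction (normality violations plus series left with too few increments
#' after absorption truncation) is recorded as well, and the error rate is
#' computed over unmasked series only.
#'
#' @param detectors Subset of `c("fit", "tsc")`.
#' @param beta_list Selection coefficients (0 = drift rows).
#' @param bins_list Bin counts; use `NA` for "no binning".
#' @param n Replicates per cell.
#' @inheritParams accuracy_experiment
#' @return A `grid_result`: list of `error_rate` matrices (beta by bins, one
#'   per detector), `masked_fraction` (FIT), and the axes. `as.data.frame()`
#'   gives the tidy long form.
#' @export
power_grid <- function(detectors = c("fit", "tsc"), beta_list, bins_list,
                       n = 1000, T = 200, N = 1000, f0 = 0.5, model = NULL) {
  detectors <- match.arg(detectors, several.ok = TRUE)
  err <- lapply(detectors, function(d)
    matrix(NA_real_, length(beta_list), length(bins_list),
           dimnames = list(beta_list, bins_list)))
  names(err) <- detectors
  masked <- matrix(NA_real_, length(beta_list), length(bins_list),
                   dimnames = list(beta_list, bins_list))
  for (i in seq_along(beta_list)) {
    for (k in seq_along(bins_list)) {
      nb <- if (is.na(bins_list[k])) NULL else bins_list[k]
      for (d in detectors) {
        r <- accuracy_experiment(d, beta = beta_list[i], n = n, T = T,
                                 N = N, f0 = f0, n_bins = nb, model = model)
        err[[d]][i, k] <- 1 - r$accuracy
        if (d == "fit") masked[i, k] <- r$inapplicable_fraction
      }
    }
  }
  structure(
    list(error_rate = err, masked_fraction = masked,
         beta_values = beta_list, bin_values = bins_list, n_replicates = n),
    class = "grid_result"
  )
}

#' @export
as.data.frame.grid_result <- function(x, ...) {
  rows <- list()
  for (d in names(x$error_rate)) {
    for (i in seq_along(x$beta_values)) {
      for (k in seq_along(x$bin_values)) {
        rows[[length(rows) + 1L]] <- data.frame(
          detector = d, beta = x$beta_values[i], n_bins = x$bin_values[k],
          error_rate = x$error_rate[[d]][i, k],
          masked_fraction = if (d == "fit") x$masked_fraction[i, k]
                            else NA_real_,
          n = x$n_replicates, stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}

#' False-positive rate versus bin count under drift
#'
#' With `beta = 0`, simulates `n` drift trajectories per bin count and records
#' each detector's false-positive rate (the FIT excludes series failing the
#' normality gate), together with a percentile bootstrap 95% confidence
#' interval over series resampling, and the across-bins mean rate per
#' detector.
#'
#' @param detectors Subset of `c("fit", "tsc")`.
#' @param bins_list Bin counts to scan.
#' @param n Replicates per bin count.
#' @param bootstrap_reps Bootstrap resamples per cell.
#' @inheritParams accuracy_experiment
#' @return A list with `curve` (tidy data.frame: detector, n_bins, fp_rate,
#'   ci_low, ci_high, n_used) and `mean_fp` (named vector, across-bins mean
#'   per detector).
#' @export
false_positive_curve <- function(detectors = c("fit", "tsc"), bins_list,
                                 n = 1000, bootstrap_reps = 1000, T = 200,
                                 N = 1000, f0 = 0.5, model = NULL) {
  detectors <- match.arg(detectors, several.ok = TRUE)
  rows <- list()
  for (nb in bins_list) {
    z <- wf_simulate_matrix(n, N, T, beta = 0, start_freq = f0)
    for (d in detectors) {
      if (d == "fit") {
        res <- .fit_batch(z, N, n_bins = nb)
        fp_ind <- res$reject[res$applicable]
      } else {
        if (is.null(model) || !isTRUE(model$trained)) {
          stop("a trained classifier model is required for detector = \"tsc\"",
               call. = FALSE)
        }
        x <- .tsc_inputs(z, N, nb, model$config$input_length)
        fp_ind <- predict(model, x) > 0.5
      }
      m <- length(fp_ind)
      boot <- replicate(bootstrap_reps,
                        mean(fp_ind[sample.int(m, m, replace = TRUE)]))
      ci <- stats::quantile(boot, c(0.025, 0.975), names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        detector = d, n_bins = nb, fp_rate = mean(fp_ind),
        ci_low = ci[1], ci_high = ci[2], n_used = m,
        stringsAsFactors = FALSE
      )
    }
  }
  curve <- do.call(rbind, rows)
  mean_fp <- tapply(curve$fp_rate, curve$detector, mean)
  list(curve = curve, mean_fp = mean_fp)
}

#' Cross-binning consistency of per-series verdicts
#'
#' Summarises, for each series, how its verdict varies across binning
#' strategies. FIT rows are tiered by p-value (`< 0.05` firm selection,
#' `< 0.2` weak selection, otherwise drift; `NA` = inapplicable); classifier
#' rows use the 0.5 probability threshold. A series is *consistent* when all
#' strategies with a usable verdict agree on selection (p < 0.05 /
#' probability > 0.5) versus drift.
#'
#' @param results Data frame with columns `series_id`, `strategy`, and either
#'   `p_value` (FIT; `NA` when inapplicable) or `probability` (classifier).
#' @return One row per series with the fraction of strategies per verdict
#'   class (`frac_drift`, `frac_selection_p05`, `frac_selection_p20`,
#'   `frac_inapplicable`), `n_strategies` and `consistent`.
#' @export
consistency_summary <- function(results) {
  stopifnot(is.data.frame(results),
            all(c("series_id", "strategy") %in% names(results)))
  if ("p_value" %in% names(results)) {
    tier <- ifelse(is.na(results$p_value), "inapplicable",
            ifelse(results$p_value < 0.05, "selection_p05",
            ifelse(results$p_value < 0.2, "selection_p20", "drift")))
  } else if ("probability" %in% names(results)) {
    tier <- ifelse(results$probability > 0.5, "selection_p05", "drift")
  } else {
    stop("`results` needs a `p_value` or `probability` column", call. = FALSE)
  }
  ids <- unique(results$series_id)
  out <- lapply(ids, function(id) {
    tt <- tier[results$series_id == id]
    usable <- tt[tt != "inapplicable"]
    sel <- usable == "selection_p05"
    data.frame(
      series_id = id,
      frac_drift = mean(tt == "drift"),
      frac_selection_p05 = mean(tt == "selection_p05"),
      frac_selection_p20 = mean(tt == "selection_p20"),
      frac_inapplicable = mean(tt == "inapplicable"),
      n_strategies = length(tt),
      consistent = length(usable) > 0 && (all(sel) || all(!sel)),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
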