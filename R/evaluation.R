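#' Mean absolute error
#'
#' `(1/M) * sum_i |yhat_i - y_i|`, the sole accuracy metric of the
#' benchmark protocol.
#'
#' @param y observed values.
#' @param y_hat predictions.
#' @export
mae <- function(y, y_hat) {
  stopifnot(length(y) == length(y_hat))
  if (!length(y)) stop("mae of empty input is undefined")
  mean(abs(y_hat - y))
}

#' Paired t-test across trials with significance stars
#'
#' Two-sided paired t-test on per-trial differences between a method's
#' MAEs and the baseline's, paired by trial seed. Stars follow the
#' reporting convention: `"**"` for p < 0.01, `"*"` for p < 0.05, empty
#' otherwise. If every difference is exactly zero, the statistic is
#' undefined and `p = 1` with no stars is reported.
#'
#' @param baseline_maes per-trial baseline MAEs.
#' @param method_maes per-trial method MAEs (same trial order).
#' @return list `(t, p, stars)`.
#' @export
paired_test <- function(baseline_maes, method_maes) {
  stopifnot(length(baseline_maes) == length(method_maes),
            length(baseline_maes) >= 2L)
  diffs <- method_maes - baseline_maes
  if (all(diffs == 0) || sd(diffs) == 0) {
    return(list(t = NA_real_, p = 1, stars = ""))
  }
  tt <- t.test(method_maes, baseline_maes, paired = TRUE)
  p <- tt$p.value
  stars <- if (p < 0.01) "**" else if (p < 0.05) "*" else ""
  list(t = unname(tt$statistic), p = p, stars = stars)
}

#' MAE binned by a selection indicator
#'
#' Splits the indicator range into `n_bins` equal-width bins and reports
#' the MAE and molecule count per bin. Empty bins get `NA` (missing),
#' not zero. Count-weighted recombination of the bins reproduces the
#' global MAE exactly.
#'
#' @param y,y_hat observations and predictions.
#' @param indicator selection-indicator value per molecule.
#' @param n_bins number of equal-width bins (>= 1).
#' @return data.frame with `bin_low`, `bin_high`, `mid`, `n`, `mae`.
#' @export
binned_mae <- function(y, y_hat, indicator, n_bins = 10L) {
  stopifnot(length(y) == length(y_hat), length(y) == length(indicator),
            n_bins >= 1L)
  r <- range(indicator)
  breaks <- seq(r[1], r[2], length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(indicator, breaks, rightmost.closed = TRUE),
                   1L), n_bins)
  abs_err <- abs(y_hat - y)
  out <- data.frame(bin_low = breaks[-(n_bins + 1L)], bin_high = breaks[-1L])
  out$mid <- (out$bin_low + out$bin_high) / 2
  out$n <- as.integer(tabulate(bin, nbins = n_bins))
  sums <- vapply(seq_len(n_bins),
                 function(b) sum(abs_err[bin == b]), numeric(1))
  out$mae <- ifelse(out$n > 0L, sums / pmax(out$n, 1L), NA_real_)
  out
}

#' Average train/test indicator densities over trials
#'
#' Normalized histograms of the train and test indicator values on a
#' common equal-width grid, averaged across trials. This is the
#' density-shift diagnostic of the sampling scenarios.
#'
#' @param train_indicators list (one numeric vector per trial) or a
#'   single numeric vector.
#' @param test_indicators same shape as `train_indicators`.
#' @param n_bins number of grid bins.
#' @return data.frame with `bin_low`, `bin_high`, `mid`, `train_density`,
#'   `test_density` (each column sums to 1 over bins).
#' @export
density_summary <- function(train_indicators, test_indicators,
                            n_bins = 10L) {
  if (!is.list(train_indicators)) train_indicators <- list(train_indicators)
  if (!is.list(test_indicators)) test_indicators <- list(test_indicators)
  all_vals <- c(unlist(train_indicators), unlist(test_indicators))
  r <- range(all_vals)
  if (r[2] == r[1]) r[2] <- r[1] + 1
  breaks <- seq(r[1], r[2], length.out = n_bins + 1L)
  hist_of <- function(x) {
    bin <- pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1L),
                n_bins)
    tabulate(bin, nbins = n_bins) / length(x)
  }
  tr <- rowMeans(vapply(train_indicators, hist_of, numeric(n_bins)))
  te <- rowMeans(vapply(test_indicators, hist_of, numeric(n_bins)))
  data.frame(bin_low = breaks[-(n_bins + 1L)], bin_high = breaks[-1L],
             mid = (breaks[-(n_bins + 1L)] + breaks[-1L]) / 2,
             train_density = tr, test_density = te)
}
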