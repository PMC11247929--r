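#' Classify frames into behavioral states
#'
#' Stationary when speed <= threshold, running when speed > threshold
#' (strict; the boundary value is stationary).
#'
#' @param speed speed trace, cm/s.
#' @param threshold cm/s (default 1).
#' @return Factor with levels `stationary`, `running`.
#' @export
classify_frames <- function(speed, threshold = 1) {
  if (any(!is.finite(speed))) stop("speed must be finite", call. = FALSE)
  factor(ifelse(speed > threshold, "running", "stationary"),
         levels = c("stationary", "running"))
}

#' Per-state mean activity
#'
#' Mean activity of each neuron over stationary and over running frames, and
#' their difference (running minus stationary).  A session in which one state
#' never occurs is an error (such recordings are excluded).
#'
#' @param activity neurons x frames matrix (or a single trace).
#' @param labels factor from [classify_frames()], one label per frame.
#' @return data.frame with `mean_stationary`, `mean_run`,
#'   `run_minus_stationary` (one row per neuron).
#' @export
state_means <- function(activity, labels) {
  if (!is.matrix(activity)) activity <- matrix(activity, nrow = 1)
  if (ncol(activity) != length(labels))
    stop("activity and labels are not aligned in frames", call. = FALSE)
  is_run <- labels == "running"
  if (!any(is_run) || all(is_run))
    stop("state missing: both stationary and running frames are required",
         call. = FALSE)
  ms <- rowMeans(activity[, !is_run, drop = FALSE])
  mr <- rowMeans(activity[, is_run, drop = FALSE])
  data.frame(mean_stationary = ms, mean_run = mr,
             run_minus_stationary = mr - ms)
}

# observed Pearson correlogram over integer lags; positive lag means the
# activity follows (lags behind) the speed trace
xcorr_correlogram <- function(x, y, max_lag) {
  n <- length(x)
  lags <- seq(-max_lag, max_lag)
  r <- vapply(lags, function(k) {
    if (k >= 0) cor(x[(k + 1):n], y[1:(n - k)])
    else cor(x[1:(n + k)], y[(1 - k):n])
  }, numeric(1))
  data.frame(lag = lags, r = r)
}

#' Cross-correlation of activity with locomotion, with a permutation null
#'
#' Pearson correlogram between a 5 Hz activity trace and the 5 Hz locomotion
#' speed over lags up to `max_lag_s`, and a shuffle test of the zero-lag
#' coefficient: the speed series is randomly permuted `n_shuffles` times and
#' `p = (1 + #{|r_shuffle| >= |r_zero|}) / (1 + n_shuffles)`.  The peak
#' correlation and its lag are reported only when the zero-lag correlation is
#' significant.  The default shuffle is a circular shift of the speed series,
#' which preserves the autocorrelation the 5 Hz smoothing chain imposes on
#' both series and keeps the test calibrated; a full value permutation
#' (`null = "permute"`) destroys autocorrelation and is anti-conservative on
#' smoothed traces (see the methods vignette).
#'
#' @param activity_5hz,speed_5hz equal-length traces at `rate` Hz.
#' @param rate sampling rate, Hz (default 5).
#' @param max_lag_s maximum lag, seconds (default 10).
#' @param n_shuffles permutations (default 1000).
#' @param alpha significance level (default 0.05).
#' @param seed RNG seed.
#' @param null `"circular"` (default) or `"permute"`.
#' @return List of class `xcorr_result`: `r_zero`, `correlogram`
#'   (data.frame `lag_s`, `r`), `p`, `significant`, `peak_r`, `peak_lag_s`
#'   (NA unless significant).
#' @export
xcorr_speed <- function(activity_5hz, speed_5hz, rate = 5, max_lag_s = 10,
                        n_shuffles = 1000, alpha = 0.05, seed = 1,
                        null = c("circular", "permute")) {
  null <- match.arg(null)
  x <- as.numeric(activity_5hz); y <- as.numeric(speed_5hz)
  if (length(x) != length(y))
    stop("invalid argument: traces differ in length", call. = FALSE)
  if (sample_sd(x) == 0 || sample_sd(y) == 0)
    stop("degenerate trace: zero variance", call. = FALSE)
  n <- length(x)
  max_lag <- round(max_lag_s * rate)
  cg <- xcorr_correlogram(x, y, max_lag)
  r_zero <- cg$r[cg$lag == 0]
  r_sh <- with_seed(seed, {
    if (null == "permute") {
      perm <- replicate(n_shuffles, sample.int(n))
    } else {
      shifts <- sample.int(n - 1, n_shuffles, replace = TRUE)
      perm <- vapply(shifts, function(s) c((s + 1):n, 1:s), integer(n))
    }
    as.numeric(cor(x, matrix(y[perm], n, n_shuffles)))
  })
  p <- (1 + sum(abs(r_sh) >= abs(r_zero))) / (1 + n_shuffles)
  significant <- p < alpha
  peak <- which.max(abs(cg$r))
  structure(list(
    r_zero = r_zero,
    correlogram = data.frame(lag_s = cg$lag / rate, r = cg$r),
    p = p, significant = significant,
    peak_r = if (significant) cg$r[peak] else NA_real_,
    peak_lag_s = if (significant) cg$lag[peak] / rate else NA_real_),
    class = "xcorr_result")
}

#' Pairwise zero-lag synchrony with a shuffle null
#'
#' Zero-lag Pearson correlation for every unordered neuron pair, with a
#' shuffle test: the second member of each pair is shuffled (the same
#' `n_shuffles` shuffles are reused across pairs) and the add-one p-value is
#' computed per pair.  As in [xcorr_speed()], the default shuffle is a
#' circular shift.
#'
#' @param activity_5hz neurons x samples matrix at 5 Hz (included ROIs only).
#' @param n_shuffles permutations (default 1000).
#' @param alpha significance level.
#' @param seed RNG seed.
#' @param null `"circular"` (default) or `"permute"`.
#' @return List: `pairs` (data.frame `i`, `j`, `r_zero`, `p`, `significant`),
#'   `frac_significant`, `mean_r`.
#' @export
pairwise_synchrony <- function(activity_5hz, n_shuffles = 1000, alpha = 0.05,
                               seed = 1, null = c("circular", "permute")) {
  null <- match.arg(null)
  if (!is.matrix(activity_5hz) || nrow(activity_5hz) < 2)
    stop("insufficient data: at least 2 neurons required", call. = FALSE)
  nn <- nrow(activity_5hz); n <- ncol(activity_5hz)
  y <- t(activity_5hz)                       # samples x neurons
  robs <- cor(y)
  ut <- upper.tri(robs)
  counts <- matrix(0L, nn, nn)
  with_seed(seed, {
    for (b in seq_len(n_shuffles)) {
      pm <- if (null == "permute") sample.int(n) else {
        s <- sample.int(n - 1, 1)
        c((s + 1):n, 1:s)
      }
      rb <- cor(y, y[pm, , drop = FALSE])    # rb[i, j] = cor(x_i, perm(x_j))
      counts[ut] <- counts[ut] + (abs(rb[ut]) >= abs(robs[ut]))
    }
  })
  idx <- which(ut, arr.ind = TRUE)
  p <- (1 + counts[ut]) / (1 + n_shuffles)
  pairs <- data.frame(i = idx[, 1], j = idx[, 2], r_zero = robs[ut],
                      p = p, significant = p < alpha)
  list(pairs = pairs,
       frac_significant = mean(pairs$significant),
       mean_r = mean(pairs$r_zero))
}
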