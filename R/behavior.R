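#' Condition a raw locomotion signal
#'
#' Convolution with a normalized smoothing kernel, mean-binning to the target
#' rate, and scaling by a calibration factor into cm/s — the conditioning
#' applied to the rotary-encoder voltage before any analysis.
#'
#' @param raw numeric samples at `src_rate`.
#' @param src_rate acquisition rate, Hz.
#' @param target_rate output rate, Hz (default 30).
#' @param kernel smoothing kernel (normalized internally; default 5-point box).
#' @param calibration multiplicative factor converting signal units to cm/s.
#' @return Speed trace at `target_rate` (attribute `rate`).
#' @export
condition_speed <- function(raw, src_rate, target_rate = 30,
                            kernel = rep(1, 5), calibration = 1) {
  if (length(raw) == 0) stop("invalid argument: empty signal", call. = FALSE)
  check_scalar(src_rate, "src_rate", positive = TRUE)
  check_scalar(target_rate, "target_rate", positive = TRUE)
  kernel <- kernel / sum(kernel)
  k <- length(kernel)
  pad <- k %/% 2
  x <- c(rep(raw[1], pad), raw, rep(raw[length(raw)], pad))
  sm <- stats::filter(x, kernel, sides = 2)
  sm <- as.numeric(sm[(pad + 1):(pad + length(raw))])
  # mean-binning: sample i (0-based time i/src_rate) falls in bin
  # floor(t * target_rate)
  t <- (seq_along(sm) - 1) / src_rate
  bin <- floor(t * target_rate)
  out <- as.numeric(tapply(sm, bin, mean))
  out <- out * calibration
  attr(out, "rate") <- target_rate
  out
}

#' Detect eyelid blinks from a z-scored blink trace
#'
#' The trace is smoothed with a Hanning window, differentiated, and velocity
#' threshold crossings define blink onsets (velocity below `-vel_threshold`)
#' and offsets (velocity above `+vel_threshold`).  Each interval is widened
#' by `buffer_s` on both sides, and intervals separated by less than
#' `merge_gap_s` are merged.  An onset without a matching offset closes at
#' the trace end with a warning.
#'
#' @param blink_z z-scored blink/eyelid trace.
#' @param rate sampling rate, Hz.
#' @param smooth_window_s Hanning window length, seconds (default 0.26).
#' @param vel_threshold velocity threshold, z/s (default 4).
#' @param buffer_s buffer added before onset and after offset (default 0.1).
#' @param merge_gap_s merge intervals closer than this (default 0.3).
#' @return data.frame of sorted, disjoint `onset_s`, `offset_s`.
#' @export
detect_blinks <- function(blink_z, rate, smooth_window_s = 0.26,
                          vel_threshold = 4, buffer_s = 0.1,
                          merge_gap_s = 0.3) {
  check_scalar(rate, "rate", positive = TRUE)
  check_scalar(vel_threshold, "vel_threshold", positive = TRUE)
  if (buffer_s < 0 || merge_gap_s < 0)
    stop("buffer and merge gap must be >= 0", call. = FALSE)
  n <- length(blink_z)
  m <- max(3L, round(smooth_window_s * rate))
  h <- 0.5 - 0.5 * cos(2 * pi * seq(0, m - 1) / (m - 1))
  h <- h / sum(h)
  pad <- m %/% 2
  x <- c(rep(blink_z[1], pad), blink_z, rep(blink_z[n], pad))
  sm <- as.numeric(stats::filter(x, h, sides = 2))[(pad + 1):(pad + n)]
  vel <- diff(sm) * rate                       # z per second, at half-steps
  below <- vel < -vel_threshold
  above <- vel > vel_threshold
  onset_idx <- which(below & !c(FALSE, below[-length(below)]))
  off_runs_end <- which(above & !c(above[-1], FALSE))
  intervals <- list()
  used_off <- 0L
  for (on in onset_idx) {
    if (length(intervals) && on / rate <= intervals[[length(intervals)]][2])
      next  # still inside the previous blink
    off <- off_runs_end[off_runs_end > on]
    if (length(off) == 0) {
      warning("unpaired blink onset near trace end; interval closed at trace end")
      off_t <- n / rate
    } else {
      off_t <- off[1] / rate
    }
    intervals[[length(intervals) + 1L]] <- c((on - 1) / rate, off_t)
  }
  if (length(intervals) == 0)
    return(data.frame(onset_s = numeric(0), offset_s = numeric(0)))
  iv <- do.call(rbind, intervals)
  iv[, 1] <- pmax(0, iv[, 1] - buffer_s)
  iv[, 2] <- pmin(n / rate, iv[, 2] + buffer_s)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  merged <- list(iv[1, ])
  for (i in seq_len(nrow(iv))[-1]) {
    last <- merged[[length(merged)]]
    if (iv[i, 1] - last[2] < merge_gap_s) {
      merged[[length(merged)]] <- c(last[1], max(last[2], iv[i, 2]))
    } else {
      merged[[length(merged) + 1L]] <- iv[i, ]
    }
  }
  out <- do.call(rbind, merged)
  data.frame(onset_s = out[, 1], offset_s = out[, 2])
}

#' Fill blink gaps in a pupil trace by cubic spline interpolation
#'
#' Samples inside blink intervals are replaced by a cubic spline fitted
#' through the remaining samples; everything outside the intervals is
#' returned unchanged (exact equality).  Gaps at the trace edges are filled
#' by spline extrapolation and flagged in the `extrapolated` attribute.
#'
#' @param pupil_z pupil trace.
#' @param blinks data.frame of `onset_s`, `offset_s` (e.g. from
#'   [detect_blinks()]).
#' @param rate sampling rate, Hz.
#' @return Gap-filled trace with attribute `extrapolated` (TRUE when an edge
#'   gap required extrapolation).
#' @export
interpolate_pupil <- function(pupil_z, blinks, rate) {
  check_scalar(rate, "rate", positive = TRUE)
  n <- length(pupil_z)
  if (nrow(blinks) == 0) {
    attr(pupil_z, "extrapolated") <- FALSE
    return(pupil_z)
  }
  t <- (seq_len(n) - 1) / rate
  mask <- rep(FALSE, n)
  for (i in seq_len(nrow(blinks)))
    mask <- mask | (t >= blinks$onset_s[i] & t <= blinks$offset_s[i])
  if (all(mask))
    stop("not interpolatable: blink intervals cover the whole trace",
         call. = FALSE)
  keep_t <- t[!mask]
  fill <- spline(keep_t, pupil_z[!mask], xout = t[mask], method = "fmm")$y
  out <- pupil_z
  out[mask] <- fill
  attr(out, "extrapolated") <- any(t[mask] < min(keep_t) | t[mask] > max(keep_t))
  out
}
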