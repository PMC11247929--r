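#' Neuropil correction
#'
#' `F = F_somatic - r * F_neuropil`, the standard linear unmixing of
#' out-of-focus neuropil signal from a somatic ROI.  `r` defaults to the
#' indicator-specific factor (see [neuropil_factor()]).
#'
#' @param f_soma,f_neuropil equal-length numeric vectors (or matrices of the
#'   same shape, neurons x frames).
#' @param r neuropil factor in `[0, 1)`.
#' @return Corrected trace(s), same shape as the input.
#' @export
neuropil_correct <- function(f_soma, f_neuropil, r = 0.7) {
  if (length(f_soma) != length(f_neuropil))
    stop("invalid argument: `f_soma` and `f_neuropil` differ in length",
         call. = FALSE)
  check_scalar(r, "r", nonneg = TRUE)
  if (r >= 1) stop("`r` must be in [0, 1)", call. = FALSE)
  f_soma - r * f_neuropil
}

#' Neuropil factor by indicator
#'
#' 0.7 for GCaMP6f and GCaMP7s, 0.8 for jGCaMP8m; any other label errors so
#' the caller must supply `r` explicitly.
#'
#' @param indicator indicator label.
#' @return The neuropil factor.
#' @export
neuropil_factor <- function(indicator) {
  switch(indicator,
         GCaMP6f = 0.7, GCaMP7s = 0.7, jGCaMP8m = 0.8,
         stop(sprintf("no default neuropil factor for indicator '%s'", indicator),
              call. = FALSE))
}

#' Rolling-percentile baseline F0
#'
#' The baseline at frame `t` is the 30th percentile (by default) of the trace
#' over a centred moving window of `window_s` seconds, truncated at the trace
#' edges.  Percentiles interpolate linearly between order statistics
#' (`quantile()` type 7).
#'
#' @param f numeric trace, or a neurons x frames matrix (rows processed
#'   independently).
#' @param frame_rate sampling rate, Hz.
#' @param window_s window length, seconds (default 150).
#' @param percentile percentile in `[0, 100]` (default 30).
#' @return Baseline trace(s), same shape as `f`.
#' @export
rolling_percentile_baseline <- function(f, frame_rate, window_s = 150,
                                        percentile = 30) {
  check_scalar(frame_rate, "frame_rate", positive = TRUE)
  if (length(f) == 0)
    stop("invalid argument: empty trace", call. = FALSE)
  if (window_s * frame_rate < 2)
    stop("invalid argument: window must span at least 2 frames", call. = FALSE)
  if (percentile < 0 || percentile > 100)
    stop("`percentile` must be in [0, 100]", call. = FALSE)
  halfwidth <- as.integer(round(window_s * frame_rate / 2))
  p <- percentile / 100
  if (is.matrix(f)) {
    if (any(!is.finite(f))) stop("non-finite values in trace", call. = FALSE)
    out <- t(apply(f, 1, roll_quantile_cpp, halfwidth = halfwidth, p = p))
    dimnames(out) <- dimnames(f)
    return(out)
  }
  if (any(!is.finite(f))) stop("non-finite values in trace", call. = FALSE)
  roll_quantile_cpp(as.numeric(f), halfwidth, p)
}

#' dF/F0
#'
#' `(F - F0) / F0` elementwise.  A nonpositive baseline anywhere is an error
#' (degenerate baseline), not silently clipped: synthetic fluorescence must
#' be generated with a positive offset.
#'
#' @param f,f0 traces (vectors or matrices) of identical shape.
#' @return dF/F0 trace(s).
#' @export
dff <- function(f, f0) {
  if (length(f) != length(f0))
    stop("invalid argument: `f` and `f0` differ in length", call. = FALSE)
  bad <- which(f0 <= 0)
  if (length(bad))
    stop(sprintf("degenerate baseline: F0 <= 0 at %d frame(s), first at index %d",
                 length(bad), bad[1]), call. = FALSE)
  (f - f0) / f0
}

#' Standardize a dF/F0 trace
#'
#' Subtracts the median and divides by the sample standard deviation
#' (denominator n - 1), the package-wide SD convention.  Output has median 0
#' and SD 1.
#'
#' @param x numeric trace, or a neurons x frames matrix (rows standardized
#'   independently).
#' @return Standardized trace(s).
#' @export
standardize <- function(x) {
  if (is.matrix(x)) return(t(apply(x, 1, standardize)))
  s <- sample_sd(x)
  if (!is.finite(s) || s == 0)
    stop("degenerate trace: zero variance, cannot standardize", call. = FALSE)
  (x - stats::median(x)) / s
}

#' ROI inclusion mask
#'
#' An ROI is included when its standardized dF/F0 reaches `threshold`
#' (inclusive) at least once, i.e. it shows at least one clear transient.
#'
#' @param std standardized dF/F0 matrix (neurons x frames) or vector.
#' @param threshold inclusion threshold (default 3).
#' @return Logical vector, one flag per ROI.
#' @export
roi_inclusion_mask <- function(std, threshold = 3) {
  if (!is.matrix(std)) std <- matrix(std, nrow = 1)
  apply(std, 1, function(x) max(x) >= threshold)
}

#' Resample a trace to 5 Hz
#'
#' Linear interpolation onto a 10 Hz grid, centred 5-point moving average
#' (windows truncated at the edges), then decimation by 2 to 5 Hz — the
#' smoothing chain applied before all correlation analyses.
#'
#' @param x numeric trace.
#' @param src_rate source sampling rate, Hz.
#' @return Numeric vector at 5 Hz (attribute `rate = 5`).
#' @export
resample_5hz <- function(x, src_rate) {
  check_scalar(src_rate, "src_rate", positive = TRUE)
  n <- length(x)
  duration <- (n - 1) / src_rate
  if (duration * 10 < 4)
    stop("invalid argument: trace shorter than the smoothing window",
         call. = FALSE)
  t_in <- (seq_len(n) - 1) / src_rate
  m10 <- floor(duration * 10 + 1e-9) + 1L
  t10 <- (seq_len(m10) - 1) / 10
  z <- approx(t_in, as.numeric(x), xout = t10)$y
  sm <- vapply(seq_len(m10), function(i) {
    mean(z[max(1L, i - 2L):min(m10, i + 2L)])
  }, numeric(1))
  out <- sm[seq(1L, m10, by = 2L)]
  attr(out, "rate") <- 5
  out
}

#' Preprocess a session's fluorescence into standardized dF/F0
#'
#' Runs the full trace chain on every ROI: neuropil correction,
#' rolling-percentile baseline, dF/F0, standardization, and the
#' transient-based inclusion mask.  Results are stored back into the session
#' under `$processed`.
#'
#' @param session a `ca_session` (see [new_session()]).
#' @param r neuropil factor; defaults to the session indicator's factor.
#' @param window_s,percentile baseline parameters.
#' @param inclusion_threshold standardized-dF/F0 inclusion threshold.
#' @return The session with `$processed` populated (`std_dff`, `dff`, `f0`,
#'   `included`).
#' @export
preprocess_session <- function(session, r = NULL, window_s = 150,
                               percentile = 30, inclusion_threshold = 3) {
  stopifnot(inherits(session, "ca_session"))
  fl <- session$fluorescence
  if (is.null(r)) r <- neuropil_factor(fl$indicator)
  f <- neuropil_correct(fl$f_soma, fl$f_neuropil, r)
  f0 <- rolling_percentile_baseline(f, fl$frame_rate, window_s, percentile)
  d <- dff(f, f0)
  std <- standardize(d)
  session$processed <- list(std_dff = std, dff = d, f0 = f0,
                            included = roi_inclusion_mask(std, inclusion_threshold),
                            neuropil_r = r, window_s = window_s,
                            percentile = percentile,
                            inclusion_threshold = inclusion_threshold)
  session
}
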