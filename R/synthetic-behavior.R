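#' Simulate a locomotion speed trace
#'
#' Two-state semi-Markov model: the animal alternates stationary and running
#' bouts with exponentially distributed durations; each running bout has a
#' lognormal peak speed and the assembled trace is smoothed with a short box
#' kernel so bout edges ramp rather than step.  Speeds are in cm/s on a
#' uniform grid at `frame_rate`.
#'
#' @param duration_s recording duration, seconds (> 0).
#' @param frame_rate sampling rate, Hz (default 30).
#' @param bout_params list with elements `stationary_mean_s` (mean stationary
#'   bout length, default 20 s), `run_mean_s` (mean running bout length,
#'   default 10 s), `run_speed_median` (median bout speed, default 5 cm/s),
#'   `run_speed_sdlog` (lognormal sd on the log scale, default 0.4) and
#'   `run_prob` (probability that a scheduled running bout occurs, default 1;
#'   0 gives a never-running trace).
#' @param seed RNG seed.
#' @return Numeric vector of nonnegative speeds, length
#'   `round(duration_s * frame_rate)`, with attribute `rate`.
#' @export
gen_locomotion <- function(duration_s, frame_rate = 30,
                           bout_params = list(), seed = 1) {
  check_scalar(duration_s, "duration_s", positive = TRUE)
  check_scalar(frame_rate, "frame_rate", positive = TRUE)
  p <- modifyList(list(stationary_mean_s = 20, run_mean_s = 10,
                       run_speed_median = 5, run_speed_sdlog = 0.4,
                       run_prob = 1), bout_params)
  if (p$stationary_mean_s <= 0 || p$run_mean_s <= 0)
    stop("bout mean lengths must be > 0", call. = FALSE)
  if (p$run_prob < 0 || p$run_prob > 1)
    stop("`run_prob` must be in [0, 1]", call. = FALSE)
  n <- round(duration_s * frame_rate)
  with_seed(seed, {
    speed <- numeric(n)
    t0 <- 0
    running <- FALSE
    while (t0 < duration_s) {
      if (running) {
        len <- rexp(1, 1 / p$run_mean_s)
        occurs <- runif(1) < p$run_prob
        if (occurs) {
          v <- rlnorm(1, meanlog = log(p$run_speed_median),
                      sdlog = p$run_speed_sdlog)
          i0 <- max(1L, floor(t0 * frame_rate) + 1L)
          i1 <- min(n, floor((t0 + len) * frame_rate))
          if (i1 >= i0) speed[i0:i1] <- v
        }
      } else {
        len <- rexp(1, 1 / p$stationary_mean_s)
      }
      t0 <- t0 + len
      running <- !running
    }
    # short box smoothing so bout transitions ramp over ~0.5 s
    k <- max(1L, round(frame_rate / 2))
    sm <- stats::filter(c(rep(speed[1], k), speed, rep(speed[n], k)),
                        rep(1 / (2 * k + 1), 2 * k + 1), sides = 2)
    speed <- as.numeric(sm[(k + 1):(k + n)])
    speed[speed < 0] <- 0
    attr(speed, "rate") <- frame_rate
    speed
  })
}

#' Simulate a pupil trace with eyelid blinks
#'
#' A smooth latent pupil signal (slow AR(1) fluctuation around 0) is
#' interrupted by blink dropouts: sharp negative pulses at Poisson-distributed
#' times with short random durations.  The true blink intervals are returned
#' so blink detection can be validated against ground truth.
#'
#' @param duration_s recording duration, seconds.
#' @param rate_hz sampling rate (default 19.06 Hz, typical for an eye camera).
#' @param blink_rate_per_min expected blink count per minute (>= 0).
#' @param blink_depth dropout amplitude in trace units (default 6).
#' @param seed RNG seed.
#' @return List with `pupil` (numeric trace), `rate`, and `blinks`
#'   (data.frame of true `onset_s`, `offset_s`).
#' @export
gen_pupil_with_blinks <- function(duration_s, rate_hz = 19.06,
                                  blink_rate_per_min = 3, blink_depth = 6,
                                  seed = 1) {
  check_scalar(duration_s, "duration_s", positive = TRUE)
  check_scalar(rate_hz, "rate_hz", positive = TRUE)
  check_scalar(blink_rate_per_min, "blink_rate_per_min", nonneg = TRUE)
  n <- round(duration_s * rate_hz)
  with_seed(seed, {
    # slow latent dilation: AR(1) with ~15 s time constant, stationary sd 1
    phi <- exp(-1 / (15 * rate_hz))
    innov <- rnorm(n, 0, sqrt(1 - phi^2))
    latent <- as.numeric(stats::filter(innov, phi, method = "recursive"))
    n_blinks <- rpois(1, blink_rate_per_min * duration_s / 60)
    if (n_blinks > 0) {
      onset <- sort(runif(n_blinks, 0.5, max(0.6, duration_s - 1)))
      dur <- runif(n_blinks, 0.15, 0.35)
      offset <- pmin(onset + dur, duration_s)
      # drop blinks that collide with the previous one
      keep <- c(TRUE, diff(onset) > 1)
      onset <- onset[keep]; offset <- offset[keep]
      pupil <- latent
      for (b in seq_along(onset)) {
        i0 <- floor(onset[b] * rate_hz) + 1L
        i1 <- min(n, max(i0, floor(offset[b] * rate_hz)))
        pupil[i0:i1] <- pupil[i0:i1] - blink_depth
      }
      blinks <- data.frame(onset_s = onset, offset_s = offset)
    } else {
      pupil <- latent
      blinks <- data.frame(onset_s = numeric(0), offset_s = numeric(0))
    }
    list(pupil = pupil, rate = rate_hz, blinks = blinks)
  })
}
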