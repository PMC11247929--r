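#' Simulate raw somatic and neuropil fluorescence
#'
#' Forward model for one imaging session.  Each neuron's event rate per frame
#' is `baseline_rate * (run_gain if speed > run_threshold else 1) +
#' speed_coupling * speed + visual_gain * tuning(theta) * contrast_resp(c)`
#' during grating presentation.  Events are Poisson-sampled per frame,
#' convolved with a single-exponential calcium kernel (decay `tau_decay_s`),
#' scaled to fluorescence and offset; the neuropil channel is a shared
#' low-pass common signal; the somatic channel adds `neuropil_weight` times
#' the neuropil plus white Gaussian noise.  With `deterministic = TRUE` every
#' stochastic step is replaced by its expectation (noise-free traces for
#' ground-truth recovery tests).
#'
#' @param neurons list of [gt_neuron()].
#' @param schedule a [make_schedule()] object.
#' @param speed locomotion trace at `frame_rate` covering the schedule span.
#' @param frame_rate imaging rate, Hz (default 30).
#' @param seed RNG seed.
#' @param tau_decay_s calcium kernel decay constant, s (default 1, GCaMP-like).
#' @param amp_per_event fluorescence transient amplitude per event, a.u.
#' @param f0_cell somatic baseline fluorescence offset, a.u.
#' @param np_offset,np_sd,np_tau_s neuropil offset, fluctuation SD and
#'   low-pass time constant.
#' @param run_threshold speed above which `run_gain` applies, cm/s.
#' @param deterministic replace Poisson/Gaussian draws by expectations.
#' @param return_events also return the event-count matrix (ground truth).
#' @return Object of class `raw_recording`: list with `f_soma`, `f_neuropil`
#'   (neurons x frames matrices), `frame_rate`, `indicator`, `ground_truth`,
#'   `seed` and optionally `events`.
#' @export
gen_recording <- function(neurons, schedule, speed, frame_rate = 30, seed = 1,
                          tau_decay_s = 1, amp_per_event = 20, f0_cell = 100,
                          np_offset = 30, np_sd = 3, np_tau_s = 2,
                          run_threshold = 1, deterministic = FALSE,
                          return_events = FALSE) {
  stopifnot(inherits(schedule, "stim_schedule"), length(neurons) >= 1)
  n_frames <- round(schedule$duration_s * frame_rate)
  if (length(speed) < n_frames)
    stop("invalid argument: schedule extends past the speed trace", call. = FALSE)
  speed <- speed[seq_len(n_frames)]
  n_neur <- length(neurons)

  # per-frame stimulus condition
  ori <- rep(NA_real_, n_frames); con <- rep(0, n_frames)
  tr <- schedule$trials
  if (nrow(tr)) {
    for (i in seq_len(nrow(tr))) {
      if (tr$blank[i]) next
      i0 <- floor(tr$stim_on_s[i] * frame_rate) + 1L
      i1 <- floor(tr$stim_off_s[i] * frame_rate)
      if (i1 > n_frames) stop("invalid argument: trial window outside recording",
                              call. = FALSE)
      ori[i0:i1] <- tr$orientation_deg[i]
      con[i0:i1] <- tr$contrast_pct[i]
    }
  }
  stim <- !is.na(ori)
  run <- speed > run_threshold
  decay <- exp(-1 / (frame_rate * tau_decay_s))

  with_seed(seed, {
    # shared neuropil: AR(1) low-pass common signal
    if (deterministic) {
      np <- rep(np_offset, n_frames)
    } else {
      phi <- exp(-1 / (np_tau_s * frame_rate))
      np <- np_offset + as.numeric(stats::filter(
        rnorm(n_frames, 0, np_sd * sqrt(1 - phi^2)), phi, method = "recursive"))
    }
    f_soma <- matrix(0, n_neur, n_frames)
    f_neuropil <- matrix(rep(np, each = n_neur), n_neur, n_frames)
    events <- if (return_events) matrix(0, n_neur, n_frames) else NULL
    for (j in seq_len(n_neur)) {
      nr <- neurons[[j]]
      rate <- nr$baseline_rate * ifelse(run, nr$run_gain, 1) +
        nr$speed_coupling * speed
      if (nr$visual_gain > 0 && any(stim)) {
        vis <- nr$visual_gain * gt_tuning(nr, ori[stim]) *
          gt_contrast_response(nr, con[stim])
        rate[stim] <- rate[stim] + vis
      }
      lambda <- rate / frame_rate
      ev <- if (deterministic) lambda else rpois(n_frames, lambda)
      if (return_events) events[j, ] <- ev
      sig <- as.numeric(stats::filter(ev, decay, method = "recursive"))
      f_cell <- f0_cell + amp_per_event * sig
      noise <- if (deterministic || nr$noise_sd == 0) 0 else
        rnorm(n_frames, 0, nr$noise_sd)
      f_soma[j, ] <- f_cell + nr$neuropil_weight * np + noise
    }
    structure(list(f_soma = f_soma, f_neuropil = f_neuropil,
                   frame_rate = frame_rate, indicator = "GCaMP7s",
                   ground_truth = neurons, seed = seed, events = events),
              class = "raw_recording")
  })
}

#' Simulate a complete session (behavior + schedule + fluorescence)
#'
#' One-call generator used by the analysis scripts and tests: draws a
#' locomotion trace, a pupil trace with blinks, a stimulus schedule for the
#' requested protocol, and the fluorescence matrices for the supplied (or
#' default) ground-truth population, assembled into a session container.
#'
#' @param protocol `"spontaneous"`, `"orientation"` or `"contrast"`.
#' @param neurons list of [gt_neuron()]; defaults to the protocol-matched
#'   population builder.
#' @param seed master seed; behaviour, schedule and recording use distinct
#'   child seeds derived from it.
#' @param n_repeats repeats per stimulus condition (protocol default if NULL).
#' @param duration_s spontaneous duration.
#' @param ... passed to [gen_recording()].
#' @return A `ca_session` (see [new_session()]).
#' @export
simulate_session <- function(protocol = c("spontaneous", "orientation", "contrast"),
                             neurons = NULL, seed = 1, n_repeats = NULL,
                             duration_s = 730, ...) {
  protocol <- match.arg(protocol)
  if (is.null(neurons)) {
    neurons <- switch(protocol,
      spontaneous = gt_population_spontaneous(),
      orientation = gt_population_orientation(seed = child_seed(seed, 11)),
      contrast = gt_population_contrast(seed = child_seed(seed, 11)))
  }
  schedule <- make_schedule(protocol, n_repeats = n_repeats,
                            duration_s = duration_s, seed = child_seed(seed, 1))
  speed <- gen_locomotion(schedule$duration_s, seed = child_seed(seed, 2))
  pupil <- gen_pupil_with_blinks(schedule$duration_s, seed = child_seed(seed, 3))
  rec <- gen_recording(neurons, schedule, speed, seed = child_seed(seed, 4), ...)
  new_session(rec, speed = speed, pupil = pupil, schedule = schedule,
              seed = seed)
}
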