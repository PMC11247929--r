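#' Label trials by locomotion state
#'
#' A trial is running when the mean speed over its stimulus window exceeds
#' the threshold, stationary otherwise (boundary inclusive to stationary).
#'
#' @param speed speed trace at `frame_rate`, cm/s.
#' @param schedule a [make_schedule()] object (or its `trials` data.frame).
#' @param frame_rate speed sampling rate, Hz.
#' @param threshold cm/s (default 1).
#' @return Factor (`stationary`/`running`), one label per trial.
#' @export
label_trial_state <- function(speed, schedule, frame_rate, threshold = 1) {
  trials <- if (inherits(schedule, "stim_schedule")) schedule$trials else schedule
  n <- length(speed)
  mean_speed <- vapply(seq_len(nrow(trials)), function(i) {
    s0 <- floor(trials$stim_on_s[i] * frame_rate) + 1L
    s1 <- floor(trials$stim_off_s[i] * frame_rate)
    if (s0 < 1L || s1 > n)
      stop("invalid schedule: stimulus window outside the speed trace",
           call. = FALSE)
    mean(speed[s0:s1])
  }, numeric(1))
  factor(ifelse(mean_speed > threshold, "running", "stationary"),
         levels = c("stationary", "running"))
}

#' Contrast response curve
#'
#' Mean response per contrast, pooling orientations (and optionally split by
#' per-trial locomotion state).  Blank (0%-contrast) trials are averaged
#' separately and never enter the contrast curve or the cCOM.
#'
#' @param table a [extract_trial_responses()] result (contrast protocol).
#' @param neuron neuron (row) index.
#' @param states optional factor from [label_trial_state()]; when given, the
#'   result also contains per-state curves (contrasts with no trial of a
#'   state are NA, with a warning).
#' @return List: `contrasts`, `Rc`, `blank_response`, `n_trials`, and with
#'   `states` also `Rc_stationary`, `Rc_running`.
#' @export
contrast_curve <- function(table, neuron = 1, states = NULL) {
  stopifnot(inherits(table, "trial_response_table"))
  tr <- table$trials
  resp <- table$response[neuron, ]
  grating <- !tr$blank
  contrasts <- sort(unique(tr$contrast_pct[grating]))
  mean_at <- function(sel) {
    vapply(contrasts, function(cc) {
      idx <- sel & grating & tr$contrast_pct == cc
      if (!any(idx)) NA_real_ else mean(resp[idx])
    }, numeric(1))
  }
  out <- list(contrasts = contrasts,
              Rc = mean_at(rep(TRUE, nrow(tr))),
              blank_response = if (any(tr$blank)) mean(resp[tr$blank]) else NA_real_,
              n_trials = vapply(contrasts, function(cc)
                sum(grating & tr$contrast_pct == cc), numeric(1)))
  if (!is.null(states)) {
    out$Rc_stationary <- mean_at(states == "stationary")
    out$Rc_running <- mean_at(states == "running")
    if (any(is.na(out$Rc_stationary)) || any(is.na(out$Rc_running)))
      warning("some contrasts have no trials in one state; entries are NA")
  }
  out
}

#' Log-scale contrast centre of mass (cCOM)
#'
#' `exp( sum(w * ln c) / sum(w) )` with weights `w = max(Rc, 0)` — negative
#' mean responses are floored at zero because a centre of mass requires
#' nonnegative weights.  Blank (zero) contrasts are not allowed (ln 0).
#'
#' @param rc mean responses at each contrast.
#' @param contrasts contrast levels, percent (> 0).
#' @return cCOM in percent contrast.
#' @export
ccom <- function(rc, contrasts) {
  if (length(rc) != length(contrasts) || length(rc) < 2)
    stop("need matched responses at >= 2 contrasts", call. = FALSE)
  if (any(contrasts <= 0))
    stop("contrasts must be > 0 (blank trials are excluded from cCOM)",
         call. = FALSE)
  w <- pmax(rc, 0)
  if (sum(w) <= 0)
    stop("undefined cCOM: all weights are <= 0", call. = FALSE)
  exp(sum(w * log(contrasts)) / sum(w))
}

#' Contrast preference class
#'
#' The preferred contrast is the argmax of the mean contrast curve (ties to
#' the lower contrast).  Preference at 5 or 10% is `low`, at 60 or 80%
#' `high`, otherwise `other`.
#'
#' @param rc mean responses at the six contrasts.
#' @param contrasts contrast levels, percent.
#' @return `"low"`, `"high"` or `"other"`.
#' @export
preference_class <- function(rc, contrasts) {
  if (any(is.na(rc))) stop("classification skipped: undefined Rc entries",
                           call. = FALSE)
  ord <- order(contrasts)
  pref <- contrasts[ord][which.max(rc[ord])]
  if (pref %in% c(5, 10)) "low"
  else if (pref %in% c(60, 80)) "high"
  else "other"
}

#' Per-neuron contrast-response summary
#'
#' For every neuron: the pooled and per-state contrast curves, blank
#' response, cCOM and preference class.  Neurons failing the responsiveness
#' filter are reported with NA metrics.
#'
#' @param table a [extract_trial_responses()] result.
#' @param states factor from [label_trial_state()].
#' @param k,min_trials responsiveness filter parameters.
#' @return data.frame, one row per neuron, with `responsive`, `Rc_<c>`
#'   columns, `blank_response`, `ccom` and `class`.
#' @export
contrast_metrics <- function(table, states = NULL, k = 3, min_trials = 2) {
  stopifnot(inherits(table, "trial_response_table"))
  responsive <- responsive_mask(table, k, min_trials)
  nn <- nrow(table$response)
  rows <- lapply(seq_len(nn), function(j) {
    cv <- contrast_curve(table, j, states = states)
    com <- tryCatch(ccom(cv$Rc, cv$contrasts), error = function(e) NA_real_)
    cls <- tryCatch(preference_class(cv$Rc, cv$contrasts),
                    error = function(e) NA_character_)
    out <- data.frame(neuron = j, responsive = responsive[j],
                      blank_response = cv$blank_response, ccom = com,
                      class = cls, stringsAsFactors = FALSE)
    rc <- as.data.frame(t(cv$Rc))
    names(rc) <- paste0("Rc_", cv$contrasts)
    cbind(out, rc)
  })
  do.call(rbind, rows)
}
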