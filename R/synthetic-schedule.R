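#' Build a stimulus schedule
#'
#' Trial schedules mirroring the three recording protocols.  Spontaneous
#' sessions have no trials (gray screen, default 730 s).  Orientation
#' sessions use 6 s trials (1 s gray, 2 s full-field grating at 80% contrast,
#' 3 s gray) with 12 directions 30 deg apart, each repeated `n_repeats`
#' times in randomized order, after a 10 s gray lead-in.  Contrast sessions
#' use 3 s trials (0.8 s gray, 2 s grating, 0.2 s gray) crossing six
#' contrasts (5, 10, 20, 40, 60, 80%) with 8 directions 45 deg apart,
#' `n_repeats` repeats each, plus one randomly placed blank (0% contrast)
#' trial per 20 grating trials.
#'
#' @param protocol `"spontaneous"`, `"orientation"` or `"contrast"`.
#' @param n_repeats repeats per condition (default 10 for orientation,
#'   15 for contrast).
#' @param duration_s spontaneous duration (default 730 s).
#' @param lead_in_s gray-screen lead-in before the first trial (default 10 s).
#' @param seed RNG seed used to randomize trial order.
#' @return Object of class `stim_schedule`: list with `trials` (data.frame of
#'   `trial_start_s`, `stim_on_s`, `stim_off_s`, `orientation_deg`,
#'   `contrast_pct`, `blank`), `protocol` and `duration_s`.
#' @export
make_schedule <- function(protocol = c("spontaneous", "orientation", "contrast"),
                          n_repeats = NULL, duration_s = 730, lead_in_s = 10,
                          seed = 1) {
  protocol <- match.arg(protocol)
  if (protocol == "spontaneous") {
    trials <- data.frame(trial_start_s = numeric(0), stim_on_s = numeric(0),
                         stim_off_s = numeric(0), orientation_deg = numeric(0),
                         contrast_pct = numeric(0), blank = logical(0))
    return(structure(list(trials = trials, protocol = protocol,
                          duration_s = duration_s), class = "stim_schedule"))
  }
  if (protocol == "orientation") {
    if (is.null(n_repeats)) n_repeats <- 10
    conds <- expand.grid(orientation_deg = seq(0, 330, by = 30),
                         rep = seq_len(n_repeats))
    ord <- with_seed(seed, sample.int(nrow(conds)))
    conds <- conds[ord, , drop = FALSE]
    trial_dur <- 6; on_off <- c(1, 3)
    trials <- data.frame(
      trial_start_s = lead_in_s + (seq_len(nrow(conds)) - 1) * trial_dur,
      orientation_deg = conds$orientation_deg,
      contrast_pct = 80, blank = FALSE)
  } else {
    if (is.null(n_repeats)) n_repeats <- 15
    conds <- expand.grid(orientation_deg = seq(0, 315, by = 45),
                         contrast_pct = c(5, 10, 20, 40, 60, 80),
                         rep = seq_len(n_repeats))
    n_cond <- nrow(conds)
    n_blank <- floor(n_cond / 20)
    trials <- with_seed(seed, {
      ord <- sample.int(n_cond)
      df <- data.frame(orientation_deg = conds$orientation_deg[ord],
                       contrast_pct = conds$contrast_pct[ord], blank = FALSE)
      # one blank randomly placed within every consecutive block of 20 trials
      blank_row <- data.frame(orientation_deg = NA_real_, contrast_pct = 0,
                              blank = TRUE)
      out <- vector("list", n_blank + 1L)
      pos0 <- 0L
      for (b in seq_len(n_blank)) {
        block <- df[(20L * (b - 1L) + 1L):(20L * b), , drop = FALSE]
        at <- sample.int(20L, 1L)
        out[[b]] <- rbind(block[seq_len(at - 1L), , drop = FALSE], blank_row,
                          block[seq(at, 20L), , drop = FALSE][seq_len(20L - at + 1L), , drop = FALSE])
      }
      tail_rows <- df[seq_len(n_cond) > 20L * n_blank, , drop = FALSE]
      out[[n_blank + 1L]] <- tail_rows
      do.call(rbind, out)
    })
    trial_dur <- 3; on_off <- c(0.8, 2.8)
    trials$trial_start_s <- lead_in_s + (seq_len(nrow(trials)) - 1) * trial_dur
  }
  trials$stim_on_s <- trials$trial_start_s + on_off[1]
  trials$stim_off_s <- trials$trial_start_s + on_off[2]
  trials <- trials[, c("trial_start_s", "stim_on_s", "stim_off_s",
                       "orientation_deg", "contrast_pct", "blank")]
  rownames(trials) <- NULL
  structure(list(trials = trials, protocol = protocol,
                 duration_s = max(trials$trial_start_s) + trial_dur + 2),
            class = "stim_schedule")
}
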