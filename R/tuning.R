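#' Extract per-trial visual responses
#'
#' The response of a neuron on a trial is its mean standardized dF/F0 over
#' the stimulus window minus its mean over the `baseline_s` window
#' immediately before stimulus onset.  Windows are half-open in frames:
#' `[floor(on * rate), floor(off * rate))`.  The SD of the baseline window is
#' stored per trial for the responsiveness filter.
#'
#' @param activity neurons x frames standardized dF/F0 matrix.
#' @param schedule a [make_schedule()] object (or its `trials` data.frame).
#' @param frame_rate imaging rate, Hz.
#' @param baseline_s pre-stimulus baseline length, seconds (default 0.5).
#' @return Object of class `trial_response_table`: list with `response`
#'   (neurons x trials), `baseline_sd` (neurons x trials), `trials`
#'   (metadata data.frame) and `frame_rate`.
#' @export
extract_trial_responses <- function(activity, schedule, frame_rate,
                                    baseline_s = 0.5) {
  trials <- if (inherits(schedule, "stim_schedule")) schedule$trials else schedule
  if (!is.matrix(activity)) activity <- matrix(activity, nrow = 1)
  n_frames <- ncol(activity)
  nt <- nrow(trials)
  if (nt == 0) stop("schedule has no trials", call. = FALSE)
  resp <- matrix(NA_real_, nrow(activity), nt)
  bsd <- matrix(NA_real_, nrow(activity), nt)
  for (i in seq_len(nt)) {
    s0 <- floor(trials$stim_on_s[i] * frame_rate) + 1L
    s1 <- floor(trials$stim_off_s[i] * frame_rate)
    b0 <- floor((trials$stim_on_s[i] - baseline_s) * frame_rate) + 1L
    b1 <- s0 - 1L
    if (b0 < 1L || s1 > n_frames)
      stop("invalid schedule: trial window outside the recording", call. = FALSE)
    stim <- activity[, s0:s1, drop = FALSE]
    base <- activity[, b0:b1, drop = FALSE]
    resp[, i] <- rowMeans(stim) - rowMeans(base)
    bsd[, i] <- apply(base, 1, sample_sd)
  }
  structure(list(response = resp, baseline_sd = bsd, trials = trials,
                 frame_rate = frame_rate, baseline_s = baseline_s),
            class = "trial_response_table")
}

#' Responsiveness filter
#'
#' A neuron is responsive when, in at least `min_trials` trials, its response
#' exceeds `k` times the SD of that trial's baseline window.  Trials with
#' zero baseline SD use threshold 0 (any positive response counts).
#'
#' @param table a [extract_trial_responses()] result.
#' @param k SD multiplier (default 3).
#' @param min_trials required number of super-threshold trials (default 2).
#' @return Logical vector, one flag per neuron.
#' @export
responsive_mask <- function(table, k = 3, min_trials = 2) {
  stopifnot(inherits(table, "trial_response_table"))
  hits <- table$response > k * table$baseline_sd
  rowSums(hits) >= min_trials
}

#' Min-max normalization of a response vector
#'
#' `(R - Rmin) / (Rmax - Rmin)`, applied to mean responses before gOSI and
#' DSI so that negative standardized responses cannot corrupt the vector
#' statistics.  A flat vector is a degenerate-tuning error.
#'
#' @param r numeric responses.
#' @return Normalized responses in `[0, 1]`.
#' @export
minmax_normalize <- function(r) {
  rng <- range(r)
  if (rng[2] <= rng[1])
    stop("degenerate tuning: flat response vector, gOSI/DSI undefined",
         call. = FALSE)
  (r - rng[1]) / (rng[2] - rng[1])
}

#' Global orientation selectivity index
#'
#' Modulus of the response-weighted doubled-angle vector sum divided by the
#' summed response: `|sum(R(theta) e^{2 i theta})| / sum(R(theta))` with
#' theta in radians.  0 for an untuned neuron, 1 for one responding at a
#' single orientation.
#'
#' @param r nonnegative mean responses per orientation.
#' @param theta_deg orientations in degrees, same length as `r`.
#' @return gOSI in `[0, 1]`.
#' @export
gosi <- function(r, theta_deg) {
  if (length(r) != length(theta_deg))
    stop("`r` and `theta_deg` differ in length", call. = FALSE)
  if (any(r < 0)) stop("responses must be nonnegative (normalize first)",
                       call. = FALSE)
  s <- sum(r)
  if (s <= 0) stop("degenerate tuning: responses sum to zero", call. = FALSE)
  th <- theta_deg * pi / 180
  Mod(sum(r * exp(2i * th))) / s
}

#' Direction selectivity index
#'
#' `(Rpref - Rnull) / (Rpref + Rnull)` where Rpref is the response at the
#' preferred direction (argmax) and Rnull the response at the direction
#' 180 deg opposite.
#'
#' @param r nonnegative mean responses per direction.
#' @param theta_deg directions in degrees.
#' @return DSI in `[0, 1]` for nonnegative responses.
#' @export
dsi <- function(r, theta_deg) {
  if (length(r) != length(theta_deg))
    stop("`r` and `theta_deg` differ in length", call. = FALSE)
  pref <- which.max(r)
  null_theta <- (theta_deg[pref] + 180) %% 360
  nidx <- which(abs(((theta_deg - null_theta) %% 360)) < 1e-9)
  if (length(nidx) != 1)
    stop("no direction 180 deg opposite the preferred one", call. = FALSE)
  rp <- r[pref]; rn <- r[nidx]
  if (rp + rn <= 0) stop("degenerate tuning: Rpref + Rnull = 0", call. = FALSE)
  (rp - rn) / (rp + rn)
}

#' Preferred orientation
#'
#' The orientation attaining the maximum mean response; ties break toward
#' the smallest angle.
#'
#' @param r mean responses per orientation.
#' @param theta_deg orientations in degrees (ascending).
#' @return Preferred orientation in degrees.
#' @export
preferred_orientation <- function(r, theta_deg) {
  ord <- order(theta_deg)
  theta_deg[ord][which.max(r[ord])]
}

#' Tuning signal-to-noise ratio
#'
#' For each orientation, `SNR_theta = mean(repetitions)^2 / sd(repetitions)`
#' (sample SD); the neuron's SNR is the mean over orientations.  Orientations
#' with zero SD are undefined and excluded with a warning; if all are
#' undefined this is an error.
#'
#' @param resp repetitions x orientations matrix of trial responses.
#' @return Scalar SNR.
#' @export
tuning_snr <- function(resp) {
  if (!is.matrix(resp) || nrow(resp) < 2)
    stop("at least 2 repetitions per orientation required", call. = FALSE)
  snr_th <- apply(resp, 2, function(x) {
    s <- sample_sd(x)
    if (s == 0) NA_real_ else mean(x)^2 / s
  })
  if (all(is.na(snr_th)))
    stop("SNR undefined at every orientation (zero variance)", call. = FALSE)
  if (any(is.na(snr_th)))
    warning("zero-variance orientation(s) excluded from SNR average")
  mean(snr_th, na.rm = TRUE)
}

#' Split-half signal correlation between two neurons
#'
#' Repetitions are split into disjoint halves: neuron j's tuning curve is the
#' per-orientation mean over one half, neuron k's over the other half (odd
#' counts give the extra repetition to j), and the signal correlation is the
#' Pearson correlation between the two curves.  The split removes shared
#' trial-by-trial noise from the estimate.
#'
#' @param resp_j,resp_k repetitions x orientations matrices with matching
#'   orientation columns.
#' @param seed seed for the random split.
#' @param split optional explicit repetition indices for neuron j's half
#'   (overrides `seed`).
#' @return Pearson signal correlation.
#' @export
signal_correlation <- function(resp_j, resp_k, seed = 1, split = NULL) {
  if (!identical(dim(resp_j), dim(resp_k)))
    stop("response matrices differ in shape", call. = FALSE)
  if (ncol(resp_j) < 2)
    stop("insufficient data: at least 2 orientations required", call. = FALSE)
  n <- nrow(resp_j)
  if (n < 2) stop("at least 2 repetitions per orientation required", call. = FALSE)
  if (is.null(split)) split <- with_seed(seed, sample.int(n, ceiling(n / 2)))
  mj <- colMeans(resp_j[split, , drop = FALSE])
  mk <- colMeans(resp_k[-split, , drop = FALSE])
  cor(mj, mk)
}

#' Noise correlation between two neurons
#'
#' Mean over orientations of the Pearson correlation between the two
#' neurons' repetition vectors at that orientation (repetition order must
#' match).  Orientations where either vector has zero variance are skipped
#' with a warning.
#'
#' @param resp_j,resp_k repetitions x orientations matrices.
#' @return Mean noise correlation.
#' @export
noise_correlation <- function(resp_j, resp_k) {
  if (!identical(dim(resp_j), dim(resp_k)))
    stop("response matrices differ in shape", call. = FALSE)
  rs <- vapply(seq_len(ncol(resp_j)), function(t) {
    if (sample_sd(resp_j[, t]) == 0 || sample_sd(resp_k[, t]) == 0)
      NA_real_
    else cor(resp_j[, t], resp_k[, t])
  }, numeric(1))
  if (any(is.na(rs)))
    warning("zero-variance orientation(s) skipped in noise correlation")
  mean(rs, na.rm = TRUE)
}

# repetitions x orientations matrix for one neuron from a trial table
# (non-blank trials; requires equal repeat counts per orientation)
rep_matrix <- function(table, neuron) {
  tr <- table$trials
  keep <- !tr$blank
  oris <- sort(unique(tr$orientation_deg[keep]))
  cols <- lapply(oris, function(o) {
    idx <- which(keep & tr$orientation_deg == o)
    table$response[neuron, idx]
  })
  nrep <- min(lengths(cols))
  sapply(cols, function(x) x[seq_len(nrep)])
}

#' Per-neuron orientation-tuning summary
#'
#' Computes, for every neuron in a trial-response table: the mean response
#' per orientation, responsiveness, preferred orientation, gOSI and DSI on
#' min-max-normalized mean responses, SNR, and the tuning curve circularly
#' aligned so the preferred orientation sits at the 90 deg bin
#' ("pseudo-90 deg").
#'
#' @param table a [extract_trial_responses()] result (orientation protocol).
#' @param k,min_trials responsiveness filter parameters.
#' @return List: `neurons` (data.frame with `responsive`,
#'   `pref_orientation`, `gosi`, `dsi`, `snr`), `curves` (neurons x
#'   orientations mean responses), `aligned` (pseudo-90 curves),
#'   `orientations`.
#' @export
tuning_metrics <- function(table, k = 3, min_trials = 2) {
  stopifnot(inherits(table, "trial_response_table"))
  tr <- table$trials
  keep <- !tr$blank
  oris <- sort(unique(tr$orientation_deg[keep]))
  nn <- nrow(table$response)
  curves <- sapply(oris, function(o)
    rowMeans(table$response[, keep & tr$orientation_deg == o, drop = FALSE]))
  curves <- matrix(curves, nrow = nn)
  responsive <- responsive_mask(table, k, min_trials)
  pseudo_idx <- which.min(abs(oris - 90))
  out <- data.frame(neuron = seq_len(nn), responsive = responsive,
                    pref_orientation = NA_real_, gosi = NA_real_,
                    dsi = NA_real_, snr = NA_real_)
  aligned <- matrix(NA_real_, nn, length(oris))
  for (j in seq_len(nn)) {
    cv <- curves[j, ]
    out$pref_orientation[j] <- preferred_orientation(cv, oris)
    norm <- tryCatch(minmax_normalize(cv), error = function(e) NULL)
    if (is.null(norm)) {
      warning(sprintf("neuron %d: flat tuning curve, gOSI/DSI skipped", j))
    } else {
      out$gosi[j] <- gosi(norm, oris)
      out$dsi[j] <- dsi(norm, oris)
    }
    out$snr[j] <- tryCatch(tuning_snr(rep_matrix(table, j)),
                           error = function(e) NA_real_)
    shift <- pseudo_idx - which.max(cv)
    aligned[j, ] <- cv[((seq_along(cv) - 1 - shift) %% length(cv)) + 1]
  }
  list(neurons = out, curves = curves, aligned = aligned, orientations = oris)
}
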