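#' Session container
#'
#' In-memory container for one imaging session: fluorescence matrices with
#' their frame rate and indicator, behavior traces on their own time bases,
#' the stimulus schedule, optional ground truth, and metadata (schema
#' version, seed provenance).  [write_session()]/[read_session()] persist the
#' container to a directory (arrays as RDS, metadata as JSON, trial table as
#' CSV) with a bit-exact round trip.
#'
#' @param recording a [gen_recording()] result (or a list with `f_soma`,
#'   `f_neuropil`, `frame_rate`, `indicator`).
#' @param speed locomotion trace at the imaging frame rate.
#' @param pupil optional [gen_pupil_with_blinks()] result.
#' @param schedule a [make_schedule()] object.
#' @param seed seed recorded for provenance.
#' @return Object of class `ca_session`.
#' @export
new_session <- function(recording, speed, pupil = NULL, schedule, seed = NA) {
  stopifnot(inherits(schedule, "stim_schedule"))
  structure(list(
    fluorescence = list(f_soma = recording$f_soma,
                        f_neuropil = recording$f_neuropil,
                        frame_rate = recording$frame_rate,
                        indicator = recording$indicator),
    behavior = list(speed = as.numeric(speed),
                    speed_rate = recording$frame_rate,
                    pupil = if (!is.null(pupil)) pupil$pupil,
                    pupil_rate = if (!is.null(pupil)) pupil$rate,
                    blinks = if (!is.null(pupil)) pupil$blinks),
    schedule = schedule,
    ground_truth = recording$ground_truth,
    events = recording$events,
    processed = NULL,
    meta = list(schema_version = 1L, seed = seed)),
    class = "ca_session")
}

#' @rdname new_session
#' @param session a `ca_session`.
#' @param dir target directory (created if absent).
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "ca_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(session$fluorescence, file.path(dir, "fluorescence.rds"))
  saveRDS(session$behavior, file.path(dir, "behavior.rds"))
  saveRDS(session$ground_truth, file.path(dir, "ground_truth.rds"))
  saveRDS(session$processed, file.path(dir, "processed.rds"))
  data.table::fwrite(session$schedule$trials, file.path(dir, "schedule.csv"))
  jsonlite::write_json(
    c(session$meta, list(protocol = session$schedule$protocol,
                         duration_s = session$schedule$duration_s)),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname new_session
#' @export
read_session <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path))
    stop(sprintf("'%s' is not a session directory (meta.json missing)", dir),
         call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$schema_version) || meta$schema_version != 1L)
    stop("unsupported session schema version", call. = FALSE)
  trials <- as.data.frame(data.table::fread(file.path(dir, "schedule.csv")))
  if (nrow(trials) == 0)
    trials <- data.frame(trial_start_s = numeric(0), stim_on_s = numeric(0),
                         stim_off_s = numeric(0), orientation_deg = numeric(0),
                         contrast_pct = numeric(0), blank = logical(0))
  schedule <- structure(list(trials = trials, protocol = meta$protocol,
                             duration_s = meta$duration_s),
                        class = "stim_schedule")
  structure(list(
    fluorescence = readRDS(file.path(dir, "fluorescence.rds")),
    behavior = readRDS(file.path(dir, "behavior.rds")),
    schedule = schedule,
    ground_truth = readRDS(file.path(dir, "ground_truth.rds")),
    events = NULL,
    processed = readRDS(file.path(dir, "processed.rds")),
    meta = list(schema_version = meta$schema_version, seed = meta$seed)),
    class = "ca_session")
}

#' Default analysis configuration
#'
#' Every tunable named across the analysis stages, in one place: neuropil
#' factors, baseline window, inclusion threshold, resampling, state
#' threshold, permutation settings, blink detection, responsiveness filter
#' and bootstrap settings.
#'
#' @return Named list of parameters.
#' @export
default_config <- function() {
  list(
    neuropil_r = NULL,           # NULL = indicator default (0.7 / 0.8)
    baseline_window_s = 150, baseline_percentile = 30,
    inclusion_threshold = 3,
    state_threshold_cms = 1,
    max_lag_s = 10, n_shuffles = 1000, alpha = 0.05,
    null = "circular",
    trial_baseline_s = 0.5, responsive_k = 3, responsive_min_trials = 2,
    blink_smooth_window_s = 0.26, blink_vel_threshold = 4,
    blink_buffer_s = 0.1, blink_merge_gap_s = 0.3,
    n_boot = 10000, drop_leading_samples = 0)
}

#' Run a full analysis protocol over a session
#'
#' Executes the stage chain for the session's protocol — preprocessing, then
#' spontaneous-state analysis (state means, activity-locomotion
#' cross-correlation, pairwise synchrony), orientation tuning, or contrast
#' tuning — and writes every result table (CSV) and summary (JSON) under
#' `out_dir`.  Reruns with identical config and seed reproduce all files
#' bit-identically.
#'
#' @param session a `ca_session`.
#' @param out_dir output directory.
#' @param config list from [default_config()] (partial overrides allowed).
#' @param seed seed for all stochastic stages.
#' @param overwrite overwrite existing results (default FALSE: error if
#'   `out_dir` already holds a summary).
#' @return Invisibly, the list of written file paths.
#' @export
run_protocol <- function(session, out_dir, config = list(), seed = 1,
                         overwrite = FALSE) {
  stopifnot(inherits(session, "ca_session"))
  cfg <- modifyList(default_config(), config)
  protocol <- session$schedule$protocol
  if (is.null(session$fluorescence[["f_soma"]]))
    stop("schema error: session lacks /fluorescence", call. = FALSE)
  if (is.null(session$behavior[["speed"]]) &&
      protocol %in% c("spontaneous", "contrast"))
    stop("schema error: session lacks /behavior/speed", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summary_path <- file.path(out_dir, "summary.json")
  if (file.exists(summary_path) && !overwrite)
    stop("results already exist in `out_dir`; use overwrite = TRUE",
         call. = FALSE)
  written <- character(0)
  emit_csv <- function(df, name) {
    path <- file.path(out_dir, name)
    data.table::fwrite(df, path)
    written <<- c(written, path)
  }
  session <- preprocess_session(session, r = cfg$neuropil_r,
                                window_s = cfg$baseline_window_s,
                                percentile = cfg$baseline_percentile,
                                inclusion_threshold = cfg$inclusion_threshold)
  fr <- session$fluorescence$frame_rate
  std <- session$processed$std_dff
  included <- session$processed$included
  summary <- list(protocol = protocol, seed = seed,
                  n_neurons = nrow(std), n_included = sum(included),
                  config = cfg[order(names(cfg))])

  if (protocol == "spontaneous") {
    labels <- classify_frames(session$behavior$speed, cfg$state_threshold_cms)
    sm <- state_means(std, labels)
    act5 <- t(apply(std, 1, resample_5hz, src_rate = fr))
    sp5 <- resample_5hz(session$behavior$speed, fr)
    per_neuron <- do.call(rbind, lapply(seq_len(nrow(std)), function(j) {
      xr <- xcorr_speed(act5[j, ], sp5, max_lag_s = cfg$max_lag_s,
                        n_shuffles = cfg$n_shuffles, alpha = cfg$alpha,
                        seed = child_seed(seed, 100 + j), null = cfg$null)
      data.frame(neuron = j, included = included[j],
                 mean_stationary = sm$mean_stationary[j],
                 mean_run = sm$mean_run[j],
                 run_minus_stationary = sm$run_minus_stationary[j],
                 r_zero = xr$r_zero, p = xr$p, significant = xr$significant,
                 peak_r = xr$peak_r, peak_lag_s = xr$peak_lag_s)
    }))
    emit_csv(per_neuron, "spontaneous_neurons.csv")
    if (sum(included) >= 2) {
      sync <- pairwise_synchrony(act5[included, , drop = FALSE],
                                 n_shuffles = cfg$n_shuffles,
                                 alpha = cfg$alpha,
                                 seed = child_seed(seed, 7))
      emit_csv(sync$pairs, "spontaneous_pairs.csv")
      summary$frac_significant_pairs <- sync$frac_significant
      summary$mean_pair_r <- sync$mean_r
    }
    summary$frac_speed_correlated <-
      mean(per_neuron$significant[per_neuron$included])
  } else if (protocol == "orientation") {
    trt <- extract_trial_responses(std, session$schedule, fr,
                                   baseline_s = cfg$trial_baseline_s)
    tm <- tuning_metrics(trt, k = cfg$responsive_k,
                         min_trials = cfg$responsive_min_trials)
    emit_csv(tm$neurons, "orientation_neurons.csv")
    curves <- as.data.frame(tm$curves)
    names(curves) <- paste0("ori_", tm$orientations)
    emit_csv(cbind(neuron = seq_len(nrow(curves)), curves),
             "orientation_curves.csv")
    summary$frac_responsive <- mean(tm$neurons$responsive)
    summary$median_gosi <- stats::median(tm$neurons$gosi, na.rm = TRUE)
  } else if (protocol == "contrast") {
    trt <- extract_trial_responses(std, session$schedule, fr,
                                   baseline_s = cfg$trial_baseline_s)
    states <- label_trial_state(session$behavior$speed, session$schedule, fr,
                                threshold = cfg$state_threshold_cms)
    cm <- contrast_metrics(trt, states = states, k = cfg$responsive_k,
                           min_trials = cfg$responsive_min_trials)
    emit_csv(cm, "contrast_neurons.csv")
    summary$frac_responsive <- mean(cm$responsive)
    summary$class_counts <- as.list(table(cm$class))
  } else {
    stop(sprintf("unknown protocol '%s'", protocol), call. = FALSE)
  }
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, digits = 12,
                       null = "null")
  written <- c(written, summary_path)
  invisible(written)
}
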