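#' Ground-truth neuron parameters for the synthetic session generator
#'
#' Defines one simulated neuron of the forward model used by
#' [gen_recording()]: a Poisson event process whose rate is
#' `baseline_rate * run_gain(state) + speed_coupling * speed + visual term`,
#' convolved with a single-exponential calcium kernel and mixed with neuropil
#' signal and Gaussian measurement noise.
#'
#' @param id integer label.
#' @param baseline_rate spontaneous event rate, events/s (>= 0).
#' @param run_gain multiplicative rate gain while the animal runs
#'   (1 = no state modulation).
#' @param speed_coupling additive rate per unit speed, events/s per cm/s.
#' @param pref_orientation preferred grating direction, degrees in `[0, 360)`.
#' @param tuning_concentration von Mises concentration kappa on the doubled
#'   angle (period 180 deg); 0 = untuned.
#' @param contrast_c50 Naka-Rushton semi-saturation contrast, percent.
#' @param contrast_exponent Naka-Rushton exponent (> 0).
#' @param contrast_sign `"increasing"`, `"decreasing"` or `"flat"`; decreasing
#'   neurons use the reflected Naka-Rushton curve `1 - NR(c)`.
#' @param visual_gain peak visually evoked rate, events/s.
#' @param noise_sd Gaussian measurement noise on the somatic trace,
#'   fluorescence a.u.
#' @param neuropil_weight fraction of the shared neuropil signal mixed into
#'   the somatic ROI, in `[0, 1)`.
#' @param dir_asymmetry optional direction asymmetry in `[0, 1)`; > 0 makes
#'   the response at the preferred direction exceed its 180 deg opposite so
#'   that DSI recovery can be exercised.
#' @return An object of class `gt_neuron`.
#' @export
gt_neuron <- function(id = 1L,
                      baseline_rate = 0.1,
                      run_gain = 1,
                      speed_coupling = 0,
                      pref_orientation = 0,
                      tuning_concentration = 1,
                      contrast_c50 = 30,
                      contrast_exponent = 2,
                      contrast_sign = c("flat", "increasing", "decreasing"),
                      visual_gain = 0,
                      noise_sd = 4,
                      neuropil_weight = 0.7,
                      dir_asymmetry = 0) {
  contrast_sign <- match.arg(contrast_sign)
  check_scalar(baseline_rate, "baseline_rate", nonneg = TRUE)
  check_scalar(run_gain, "run_gain", nonneg = TRUE)
  check_scalar(speed_coupling, "speed_coupling", nonneg = TRUE)
  check_scalar(pref_orientation, "pref_orientation")
  if (pref_orientation < 0 || pref_orientation >= 360)
    stop("`pref_orientation` must lie in [0, 360)", call. = FALSE)
  check_scalar(tuning_concentration, "tuning_concentration", nonneg = TRUE)
  check_scalar(contrast_c50, "contrast_c50", positive = TRUE)
  if (contrast_c50 > 100) stop("`contrast_c50` must be in (0, 100]", call. = FALSE)
  check_scalar(contrast_exponent, "contrast_exponent", positive = TRUE)
  check_scalar(visual_gain, "visual_gain", nonneg = TRUE)
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  check_scalar(neuropil_weight, "neuropil_weight", nonneg = TRUE)
  if (neuropil_weight >= 1) stop("`neuropil_weight` must be in [0, 1)", call. = FALSE)
  if (dir_asymmetry < 0 || dir_asymmetry >= 1)
    stop("`dir_asymmetry` must be in [0, 1)", call. = FALSE)
  structure(list(
    id = as.integer(id), baseline_rate = baseline_rate, run_gain = run_gain,
    speed_coupling = speed_coupling, pref_orientation = pref_orientation,
    tuning_concentration = tuning_concentration, contrast_c50 = contrast_c50,
    contrast_exponent = contrast_exponent, contrast_sign = contrast_sign,
    visual_gain = visual_gain, noise_sd = noise_sd,
    neuropil_weight = neuropil_weight, dir_asymmetry = dir_asymmetry),
    class = "gt_neuron")
}

#' Orientation tuning term of a ground-truth neuron
#'
#' von Mises curve on the doubled angle, peak-normalized to 1 at the preferred
#' orientation, optionally multiplied by a direction-asymmetry factor with
#' period 360 deg.
#'
#' @param neuron a [gt_neuron()].
#' @param theta_deg grating direction(s) in degrees.
#' @return Tuning weight(s) in `[0, 1]`.
#' @export
gt_tuning <- function(neuron, theta_deg) {
  k <- neuron$tuning_concentration
  d <- (theta_deg - neuron$pref_orientation) * pi / 180
  ori <- exp(k * (cos(2 * d) - 1))
  dir <- (1 + neuron$dir_asymmetry * cos(d)) / (1 + neuron$dir_asymmetry)
  ori * dir
}

#' Contrast response term of a ground-truth neuron
#'
#' Naka-Rushton `c^n / (c^n + c50^n)` for increasing neurons, its reflection
#' `1 - NR(c)` for decreasing neurons, and 1 for flat neurons.  Contrast 0
#' (blank) always yields 0 for increasing, 1 for decreasing and is treated as
#' no visual drive upstream (blank trials present no grating).
#'
#' @param neuron a [gt_neuron()].
#' @param contrast_pct contrast(s), percent.
#' @return Contrast weight(s) in `[0, 1]`.
#' @export
gt_contrast_response <- function(neuron, contrast_pct) {
  nr <- contrast_pct^neuron$contrast_exponent /
    (contrast_pct^neuron$contrast_exponent + neuron$contrast_c50^neuron$contrast_exponent)
  switch(neuron$contrast_sign,
         increasing = nr,
         decreasing = 1 - nr,
         flat = rep(1, length(contrast_pct)))
}

#' Ground-truth populations for the simulated experiments
#'
#' Convenience builders for the neuron mixes used across the analyses.
#' `gt_population_spontaneous()` mixes locomotion-coupled neurons
#' (`speed_coupling > 0`) with near-silent uncoupled neurons whose traces are
#' dominated by white measurement noise (the low-autocorrelation regime in
#' which a value-permutation null is well behaved).
#' `gt_population_orientation()` mixes visually driven, orientation-tuned
#' neurons (preferred directions on the stimulus grid) with non-visual
#' sparsely firing neurons.  `gt_population_contrast()` builds
#' contrast-increasing, contrast-decreasing and non-visual neurons.
#'
#' @param n_coupled,n_uncoupled,n_visual,n_nonvisual,n_increasing,n_decreasing
#'   group sizes.
#' @param speed_coupling events/s per cm/s for coupled neurons.
#' @param visual_gain peak evoked rate, events/s, for driven neurons.
#' @param kappa tuning concentration for driven neurons (scalar or vector
#'   recycled across neurons).
#' @param seed seed for drawing preferred orientations.
#' @return List of [gt_neuron()] objects.
#' @name gt_population
NULL

#' @rdname gt_population
#' @export
gt_population_spontaneous <- function(n_coupled = 20, n_uncoupled = 20,
                                      speed_coupling = 0.3) {
  c(
    lapply(seq_len(n_coupled), function(i)
      gt_neuron(id = i, baseline_rate = 0.1, speed_coupling = speed_coupling)),
    lapply(seq_len(n_uncoupled), function(i)
      gt_neuron(id = n_coupled + i, baseline_rate = 0.02, speed_coupling = 0))
  )
}

#' @rdname gt_population
#' @export
gt_population_orientation <- function(n_visual = 40, n_nonvisual = 40,
                                      visual_gain = 5, kappa = 2, seed = 1) {
  kappa <- rep_len(kappa, n_visual)
  prefs <- with_seed(seed, sample(seq(0, 330, by = 30), n_visual, replace = TRUE))
  c(
    lapply(seq_len(n_visual), function(i)
      gt_neuron(id = i, baseline_rate = 0.1, visual_gain = visual_gain,
                pref_orientation = prefs[i], tuning_concentration = kappa[i])),
    lapply(seq_len(n_nonvisual), function(i)
      gt_neuron(id = n_visual + i, baseline_rate = 0.02, visual_gain = 0))
  )
}

#' @rdname gt_population
#' @export
gt_population_contrast <- function(n_increasing = 100, n_decreasing = 100,
                                   n_nonvisual = 0, visual_gain = 5, seed = 1) {
  n <- n_increasing + n_decreasing
  prefs <- with_seed(seed, sample(seq(0, 315, by = 45), n, replace = TRUE))
  c(
    lapply(seq_len(n_increasing), function(i)
      gt_neuron(id = i, baseline_rate = 0.1, visual_gain = visual_gain,
                pref_orientation = prefs[i], tuning_concentration = 1,
                contrast_sign = "increasing")),
    lapply(seq_len(n_decreasing), function(i)
      gt_neuron(id = n_increasing + i, baseline_rate = 0.1,
                visual_gain = visual_gain,
                pref_orientation = prefs[n_increasing + i],
                tuning_concentration = 1, contrast_sign = "decreasing")),
    lapply(seq_len(n_nonvisual), function(i)
      gt_neuron(id = n + i, baseline_rate = 0.02, visual_gain = 0))
  )
}
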