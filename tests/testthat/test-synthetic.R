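test_that("locomotion generator honours duration, determinism and degenerate chains", {
  sp <- gen_locomotion(730, 30, seed = 7)
  expect_length(sp, 21900)
  expect_true(all(sp >= 0))
  expect_identical(sp, gen_locomotion(730, 30, seed = 7))
  # both states occur in a long trace
  expect_gt(mean(sp > 1), 0.05)
  expect_gt(mean(sp <= 1), 0.05)
  never <- gen_locomotion(300, 30, bout_params = list(run_prob = 0), seed = 3)
  expect_true(all(never < 1))
  expect_error(gen_locomotion(-5), "duration")
  expect_error(gen_locomotion(10, bout_params = list(run_mean_s = 0)),
               "bout mean")
})

test_that("pupil generator produces Poisson-distributed blinks and is seeded", {
  p0 <- gen_pupil_with_blinks(60, blink_rate_per_min = 0, seed = 1)
  expect_identical(nrow(p0$blinks), 0L)
  p1 <- gen_pupil_with_blinks(60, blink_rate_per_min = 6, seed = 5)
  expect_identical(p1, gen_pupil_with_blinks(60, blink_rate_per_min = 6, seed = 5))
  expect_length(p1$pupil, round(60 * 19.06))
  # Monte-Carlo mean count over seeds ~ rate * duration (6/min for 60 s)
  counts <- vapply(1:40, function(s)
    nrow(gen_pupil_with_blinks(60, blink_rate_per_min = 6, seed = s)$blinks),
    numeric(1))
  expect_lt(abs(mean(counts) - 6), 1.5)
  expect_error(gen_pupil_with_blinks(60, blink_rate_per_min = -1), ">= 0")
})

test_that("stimulus schedules satisfy their protocol invariants", {
  sch <- make_schedule("orientation", n_repeats = 10, seed = 2)
  tr <- sch$trials
  expect_identical(nrow(tr), 120L)
  expect_true(all(diff(tr$trial_start_s) > 0))
  expect_true(all(tr$stim_on_s < tr$stim_off_s))
  # non-overlap: each trial ends before the next starts
  expect_true(all(head(tr$trial_start_s + 6, -1) <= tr$trial_start_s[-1] + 1e-9))
  expect_equal(sort(unique(tr$orientation_deg)), seq(0, 330, by = 30))
  expect_true(all(table(tr$orientation_deg) == 10))

  schc <- make_schedule("contrast", n_repeats = 15, seed = 3)
  trc <- schc$trials
  gr <- trc[!trc$blank, ]
  expect_identical(nrow(gr), 8L * 6L * 15L)
  expect_equal(sort(unique(gr$contrast_pct)), c(5, 10, 20, 40, 60, 80))
  expect_equal(sort(unique(gr$orientation_deg)), seq(0, 315, by = 45))
  expect_identical(sum(trc$blank), (8L * 6L * 15L) %/% 20L)
  expect_true(all(trc$contrast_pct[trc$blank] == 0))
})

test_that("forward model obeys its rate structure", {
  sch <- make_schedule("spontaneous", duration_s = 60)
  speed <- gen_locomotion(60, seed = 2)
  # all gains zero, no noise: constant somatic fluorescence
  n0 <- gt_neuron(baseline_rate = 0, visual_gain = 0, noise_sd = 0)
  rec0 <- gen_recording(list(n0), sch, speed, deterministic = TRUE)
  expect_equal(max(rec0$f_soma) - min(rec0$f_soma), 0)
  # run_gain 3 vs 1: higher event rate in running frames for the gained neuron
  ns <- list(gt_neuron(baseline_rate = 0.5, run_gain = 3),
             gt_neuron(baseline_rate = 0.5, run_gain = 1))
  long <- make_schedule("spontaneous", duration_s = 600)
  spl <- gen_locomotion(600, seed = 4)
  rec <- gen_recording(ns, long, spl, seed = 9, return_events = TRUE)
  run <- spl[seq_len(ncol(rec$events))] > 1
  expect_gt(mean(rec$events[1, run]), mean(rec$events[2, run]))
  # empirical run/stationary rate ratio approaches run_gain
  ratio <- mean(rec$events[1, run]) / mean(rec$events[1, !run])
  expect_lt(abs(ratio - 3), 0.8)
  # increasing contrast sign: noiseless response non-decreasing in contrast
  nc <- gt_neuron(baseline_rate = 0, visual_gain = 4, contrast_sign = "increasing",
                  tuning_concentration = 0)
  schc <- make_schedule("contrast", n_repeats = 1, seed = 5)
  spc <- gen_locomotion(schc$duration_s, seed = 6)
  recc <- gen_recording(list(nc), schc, spc, deterministic = TRUE,
                        return_events = TRUE)
  rate_at <- function(cc) {
    idx <- unlist(lapply(which(!schc$trials$blank & schc$trials$contrast_pct == cc),
                         function(i) {
      (floor(schc$trials$stim_on_s[i] * 30) + 1):floor(schc$trials$stim_off_s[i] * 30)
    }))
    mean(recc$events[1, idx])
  }
  expect_gte(rate_at(80), rate_at(5))
  # schedule longer than the speed trace is rejected
  expect_error(gen_recording(ns, long, spl[1:100]), "speed trace")
})

test_that("deterministic tuning peaks at the ground-truth orientation (mod 180)", {
  prefs <- seq(0, 330, by = 30)
  neurons <- lapply(seq_along(prefs), function(i)
    gt_neuron(id = i, baseline_rate = 0.05, visual_gain = 5,
              pref_orientation = prefs[i], tuning_concentration = 2))
  sess <- fixture_orientation_session(neurons, n_repeats = 2)
  trt <- extract_trial_responses(sess$processed$std_dff, sess$schedule, 30)
  oris <- seq(0, 330, by = 30)
  for (j in seq_along(prefs)) {
    curve <- sapply(oris, function(o)
      mean(trt$response[j, trt$trials$orientation_deg == o]))
    expect_equal(preferred_orientation(curve, oris) %% 180, prefs[j] %% 180)
  }
})

test_that("traced-cell generator matches its multinomial spec", {
  sp1 <- traced_cell_spec(region_probs = c(A = 1), n_inputs = 50, n_starters = 0)
  tc1 <- gen_traced_cells(sp1, seed = 1)
  expect_identical(nrow(tc1), 50L)
  expect_true(all(tc1$region == "A"))
  expect_identical(sum(tc1$gfp), 0L)
  sp2 <- traced_cell_spec(region_probs = c(A = 0.5, B = 0.3, C = 0.2),
                          n_inputs = 10000, n_starters = 0)
  tc2 <- gen_traced_cells(sp2, seed = 2)
  frac <- table(tc2$region) / nrow(tc2)
  expect_lt(max(abs(frac[c("A", "B", "C")] - c(0.5, 0.3, 0.2))), 0.02)
  expect_identical(tc2, gen_traced_cells(sp2, seed = 2))
  expect_error(traced_cell_spec(region_probs = numeric(0)), "non-empty")
  expect_error(traced_cell_spec(region_probs = c(A = 0.5, B = 0.6)), "sum to 1")
})
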