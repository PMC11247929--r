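test_that("trial responses are baseline-subtracted window means", {
  fr <- 30
  trials <- data.frame(trial_start_s = c(2, 8), stim_on_s = c(3, 9),
                       stim_off_s = c(5, 11), orientation_deg = c(0, 90),
                       contrast_pct = 80, blank = FALSE)
  n <- 15 * fr
  act <- matrix(2, 1, n)                     # baseline level b = 2
  for (i in 1:2) {
    idx <- (floor(trials$stim_on_s[i] * fr) + 1):floor(trials$stim_off_s[i] * fr)
    expect_length(idx, 60)                   # 2 s stimulus at 30 Hz
    act[1, idx] <- 2 + 0.5                   # b + delta
  }
  trt <- extract_trial_responses(act, trials, fr)
  expect_equal(as.numeric(trt$response), c(0.5, 0.5))
  expect_equal(as.numeric(trt$baseline_sd), c(0, 0))
  cst <- extract_trial_responses(matrix(1, 1, n), trials, fr)
  expect_equal(as.numeric(cst$response), c(0, 0))
  bad <- trials; bad$stim_off_s[2] <- 20
  expect_error(extract_trial_responses(act, bad, fr), "outside")
})

test_that("responsiveness needs the 3xSD rule in at least two trials", {
  trials <- data.frame(trial_start_s = 1:10, stim_on_s = 1:10 + 0.5,
                       stim_off_s = 1:10 + 1, orientation_deg = 0,
                       contrast_pct = 80, blank = FALSE)
  mk <- function(resp) fixture_trial_table(matrix(resp, 1), matrix(1, 1, 10),
                                           trials)
  expect_true(responsive_mask(mk(c(4, 4, 4, rep(0, 7)))))
  expect_false(responsive_mask(mk(c(4, rep(0, 9)))))
  expect_false(responsive_mask(mk(rep(-1, 10))))
  # zero baseline SD: any positive response counts
  tab0 <- fixture_trial_table(matrix(c(0.1, 0.2, rep(0, 8)), 1),
                              matrix(0, 1, 10), trials)
  expect_true(responsive_mask(tab0))
})

test_that("min-max normalization and its degenerate case", {
  expect_equal(minmax_normalize(c(0, 5, 10)), c(0, 0.5, 1))
  expect_equal(minmax_normalize(c(-2, 0, 2)), c(0, 0.5, 1))
  expect_equal(minmax_normalize(c(0, 0.3, 1)), c(0, 0.3, 1))
  expect_error(minmax_normalize(rep(1, 12)), "degenerate")
})

test_that("gOSI boundary identities and invariances", {
  oris <- seq(0, 330, by = 30)
  single <- c(1, rep(0, 11))
  expect_equal(gosi(single, oris), 1)
  expect_lt(gosi(rep(1, 12), oris), 1e-12)
  expect_equal(gosi(c(2, rep(1, 11)), oris), 1 / 13, tolerance = 1e-12)
  set.seed(3)
  r <- runif(12)
  expect_equal(gosi(5 * r, oris), gosi(r, oris), tolerance = 1e-12)
  expect_equal(gosi(r, (oris + 40) %% 360), gosi(r, oris), tolerance = 1e-9)
  expect_error(gosi(rep(0, 12), oris), "sum to zero")
  expect_error(gosi(c(-1, rep(1, 11)), oris), "nonnegative")
})

test_that("DSI contrasts the preferred direction with its opposite", {
  oris <- seq(0, 330, by = 30)
  r <- rep(0, 12); r[1] <- 1                 # pref 0, null 180 absent response
  expect_equal(dsi(r, oris), 1)
  r2 <- rep(0.5, 12)
  expect_equal(dsi(r2, oris), 0)
  r3 <- rep(0, 12); r3[3] <- 3; r3[9] <- 1   # 60 vs 240 deg
  expect_equal(dsi(r3, oris), 0.5)
  expect_error(dsi(c(1, 0, 0), c(0, 45, 135)), "opposite")
})

test_that("SNR follows the mean-squared over sample-SD definition", {
  resp <- cbind(c(1, 2, 3))
  expect_equal(tuning_snr(resp), 4)          # mean 2, sample SD 1
  resp2 <- cbind(c(1, 2, 3), c(-1, 0, 1))
  expect_equal(tuning_snr(resp2), mean(c(4, 0)))
  expect_equal(tuning_snr(2 * resp), 8)      # doubling scales SNR by 2
  expect_warning(snrv <- tuning_snr(cbind(c(1, 2, 3), c(1, 1, 1))), "zero-variance")
  expect_equal(snrv, 4)
  expect_error(tuning_snr(cbind(c(1, 1), c(2, 2))), "zero variance")
})

test_that("signal and noise correlations behave on constructed pairs", {
  oris <- 12
  curve <- exp(2 * cos(2 * pi * (seq_len(oris) - 3) / oris))
  noiseless <- matrix(rep(curve, each = 6), 6, oris)
  expect_equal(signal_correlation(noiseless, noiseless, seed = 1), 1)
  expect_equal(signal_correlation(noiseless, -noiseless, seed = 1), -1)
  set.seed(4)
  a <- matrix(rnorm(72), 6, 12)
  expect_equal(noise_correlation(a, a), 1)
  expect_equal(noise_correlation(a, -a), -1)
  # independent tuning: both statistics centre on zero over many pairs
  sig <- vapply(1:1000, function(i) {
    x <- matrix(rnorm(48), 4, 12); y <- matrix(rnorm(48), 4, 12)
    c(signal_correlation(x, y, seed = i), noise_correlation(x, y))
  }, numeric(2))
  expect_lt(abs(mean(sig[1, ])), 0.05)
  expect_lt(abs(mean(sig[2, ])), 0.05)
  expect_error(signal_correlation(a[, 1, drop = FALSE], a[, 1, drop = FALSE]),
               "orientations")
})

test_that("per-neuron tuning summary aligns curves at pseudo-90 degrees", {
  neurons <- list(gt_neuron(baseline_rate = 0.05, visual_gain = 5,
                            pref_orientation = 240, tuning_concentration = 2))
  sess <- fixture_orientation_session(neurons, n_repeats = 2)
  trt <- extract_trial_responses(sess$processed$std_dff, sess$schedule, 30)
  tm <- tuning_metrics(trt)
  expect_equal(tm$neurons$pref_orientation %% 180, 60)
  expect_true(tm$neurons$responsive)
  expect_true(tm$neurons$gosi >= 0 && tm$neurons$gosi <= 1)
  expect_equal(which.max(tm$aligned[1, ]), which(tm$orientations == 90))
})
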