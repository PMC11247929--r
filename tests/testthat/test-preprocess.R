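test_that("neuropil correction is the stated linear unmixing", {
  expect_equal(neuropil_correct(100, 50, 0.7), 65)
  x <- rnorm(100)
  expect_equal(neuropil_correct(x, rep(0, 100), 0.5), x)
  expect_equal(neuropil_correct(80, 100, 0.8), 0)
  expect_equal(neuropil_factor("GCaMP6f"), 0.7)
  expect_equal(neuropil_factor("jGCaMP8m"), 0.8)
  expect_error(neuropil_correct(1:5, 1:4), "length")
  expect_error(neuropil_correct(1, 1, r = 1), "0, 1")
})

test_that("rolling-percentile baseline matches a per-window oracle", {
  expect_equal(rolling_percentile_baseline(rep(3, 200), 10, window_s = 5),
               rep(3, 200))
  # plateau with sparse transients: baseline stays at the plateau
  x <- rep(1, 600)
  x[seq(50, 550, by = 60)] <- 10
  f0 <- rolling_percentile_baseline(x, 10, window_s = 5)
  expect_true(all(f0[30:570] == 1))
  # linear ramp: 30th percentile of a centred window sits below the centre
  ramp <- seq(0, 10, length.out = 6000)
  f0r <- rolling_percentile_baseline(ramp, 10, window_s = 60)
  interior <- 400:5600
  expect_true(all(f0r[interior] < ramp[interior]))
  # exact agreement with the brute-force oracle on random traces
  set.seed(42)
  for (i in 1:5) {
    y <- rnorm(300)
    h <- round(4 * 10 / 2)
    expect_equal(rolling_percentile_baseline(y, 10, window_s = 4),
                 oracle_rolling_percentile(y, h, 0.3), tolerance = 1e-12)
  }
  expect_error(rolling_percentile_baseline(numeric(0), 10), "empty")
})

test_that("dF/F0 arithmetic and degenerate-baseline guard", {
  f0 <- rep(10, 4)
  expect_equal(dff(f0, f0), rep(0, 4))
  expect_equal(dff(2 * f0, f0), rep(1, 4))
  expect_equal(dff(c(11, 9), c(10, 10)), c(0.1, -0.1))
  expect_error(dff(c(1, 2, 3), c(1, 0, 1)), "index 2")
})

test_that("standardization centres the median and scales the sample SD", {
  x <- rnorm(500, 3, 5)
  s <- standardize(x)
  expect_equal(median(s), 0, tolerance = 1e-12)
  expect_equal(sd(s), 1, tolerance = 1e-12)
  expect_equal(standardize(s), s, tolerance = 1e-12)   # idempotent
  expect_equal(standardize(c(0, 0, 0, 4)), c(0, 0, 0, 2))  # sample SD = 2
  expect_error(standardize(rep(2, 10)), "zero variance")
})

test_that("ROI inclusion uses an inclusive threshold on the standardized trace", {
  m <- rbind(c(rep(0, 9), 2.9), c(rep(0, 9), 3.0))
  expect_identical(unname(roi_inclusion_mask(m, 3)), c(FALSE, TRUE))
  expect_true(all(roi_inclusion_mask(m, 0)))
})

test_that("5 Hz resampling chain matches its oracle and smooths", {
  cst <- resample_5hz(rep(2.5, 301), 30)   # 10 s trace
  expect_true(all(abs(cst - 2.5) < 1e-12))
  expect_length(cst, floor(10 * 5) + 1)
  set.seed(8)
  for (i in 1:5) {
    x <- rnorm(400)
    expect_equal(as.numeric(resample_5hz(x, 30)), oracle_resample_5hz(x, 30),
                 tolerance = 1e-10)
  }
  wn <- rnorm(3000)
  expect_lt(var(as.numeric(resample_5hz(wn, 30))), var(wn))
  expect_error(resample_5hz(c(1, 2), 30), "shorter")
})

test_that("the preprocessing chain is scale covariant and tracks ground-truth rate", {
  neurons <- list(gt_neuron(baseline_rate = 0.05, visual_gain = 5,
                            pref_orientation = 90, tuning_concentration = 2))
  sch <- make_schedule("orientation", n_repeats = 2, seed = 1)
  speed <- gen_locomotion(sch$duration_s, seed = 2)
  rec <- gen_recording(neurons, sch, speed, seed = 3, deterministic = TRUE,
                       return_events = TRUE)
  std1 <- standardize(dff(
    f <- neuropil_correct(rec$f_soma, rec$f_neuropil, 0.7),
    rolling_percentile_baseline(f, 30)))
  # multiplying both channels by a positive gain leaves the output unchanged
  f2 <- neuropil_correct(3.7 * rec$f_soma, 3.7 * rec$f_neuropil, 0.7)
  std2 <- standardize(dff(f2, rolling_percentile_baseline(f2, 30)))
  expect_equal(std2, std1, tolerance = 1e-9)
  # per-trial mean activity rank-correlates with the ground-truth rate
  tr <- sch$trials
  by_trial <- function(x) vapply(seq_len(nrow(tr)), function(i)
    mean(x[(floor(tr$stim_on_s[i] * 30) + 1):floor(tr$stim_off_s[i] * 30)]),
    numeric(1))
  rho <- cor(by_trial(std1[1, ]), by_trial(rec$events[1, ]),
             method = "spearman")
  expect_gt(rho, 0.9)
})
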