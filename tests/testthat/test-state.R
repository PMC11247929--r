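test_that("frame classification uses an inclusive stationary boundary", {
  expect_identical(as.character(classify_frames(c(0, 0.5, 1.0, 1.5))),
                   c("stationary", "stationary", "stationary", "running"))
  expect_true(all(classify_frames(rep(0, 10)) == "stationary"))
  expect_identical(as.character(classify_frames(c(0, 0.2), threshold = 0)),
                   c("stationary", "running"))
})

test_that("state means difference is running minus stationary", {
  speed <- c(0, 0, 0, 5, 5)
  lab <- classify_frames(speed)
  act <- rbind(speed, rep(0, 5), as.numeric(lab == "running"))
  sm <- state_means(act, lab)
  expect_gt(sm$mean_run[1], sm$mean_stationary[1])
  expect_equal(sm$run_minus_stationary[2], 0)
  expect_equal(sm$run_minus_stationary[3], 1)
  expect_error(state_means(act, classify_frames(rep(0, 5))), "state missing")
})

test_that("zero-lag correlation, p-value and lag conventions hold", {
  set.seed(1)
  x <- rnorm(600)
  r_self <- xcorr_speed(x, x, n_shuffles = 200, seed = 2)
  expect_equal(r_self$r_zero, 1)
  expect_equal(r_self$p, 1 / 201)
  expect_true(r_self$significant)
  expect_equal(r_self$peak_lag_s, 0)
  # activity = speed delayed by 2 s -> positive peak lag of +2 s
  sp <- as.numeric(stats::filter(rnorm(700), 0.9, method = "recursive"))
  act <- c(rep(0, 10), sp[1:690])           # 10 samples at 5 Hz = 2 s
  r_lag <- xcorr_speed(act, sp, n_shuffles = 200, seed = 3)
  expect_true(r_lag$significant)
  expect_equal(r_lag$peak_lag_s, 2)
  # correlogram at lag 0 equals the direct Pearson coefficient
  y <- rnorm(600)
  rr <- xcorr_speed(x, y, n_shuffles = 50, seed = 4)
  expect_equal(rr$correlogram$r[rr$correlogram$lag_s == 0], cor(x, y),
               tolerance = 1e-12)
  expect_equal(rr$r_zero, cor(x, y), tolerance = 1e-12)
  expect_error(xcorr_speed(rep(1, 100), rnorm(100)), "zero variance")
  expect_error(xcorr_speed(x, y[1:100]), "length")
})

test_that("pairwise synchrony flags duplicates and sign-flips", {
  set.seed(5)
  base <- rnorm(500)
  m <- rbind(base, base + rnorm(500, 0, 1e-8), -base, rnorm(500))
  sync <- pairwise_synchrony(m, n_shuffles = 200, seed = 6)
  p12 <- sync$pairs[sync$pairs$i == 1 & sync$pairs$j == 2, ]
  expect_gt(p12$r_zero, 0.999)
  expect_true(p12$significant)
  p13 <- sync$pairs[sync$pairs$i == 1 & sync$pairs$j == 3, ]
  expect_lt(p13$r_zero, -0.999)
  expect_identical(nrow(sync$pairs), 6L)    # unordered pairs, no self-pairs
  expect_true(all(sync$pairs$i < sync$pairs$j))
  expect_error(pairwise_synchrony(m[1, , drop = FALSE]), "insufficient")
})

test_that("shuffle-test p-values are calibrated on exchangeable noise", {
  # super-uniformity spot check at a modest scale (the full-scale calibration
  # lives in the acceptance suite)
  set.seed(9)
  ps <- vapply(1:60, function(i)
    xcorr_speed(rnorm(400), rnorm(400), n_shuffles = 200, seed = i)$p,
    numeric(1))
  expect_lte(mean(ps <= 0.05), 0.05 + 1.96 * sqrt(0.05 * 0.95 / 60) + 1e-9)
})
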