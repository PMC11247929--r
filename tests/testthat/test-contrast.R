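test_that("trial state labels use mean stimulus-window speed, boundary stationary", {
  sch <- make_schedule("contrast", n_repeats = 1, seed = 1)
  n <- round(sch$duration_s * 30)
  expect_true(all(label_trial_state(rep(0, n), sch, 30) == "stationary"))
  expect_true(all(label_trial_state(rep(5, n), sch, 30) == "running"))
  expect_true(all(label_trial_state(rep(1, n), sch, 30) == "stationary"))
  expect_error(label_trial_state(rep(0, 100), sch, 30), "outside")
})

test_that("contrast curves pool orientations and hold blanks apart", {
  trials <- data.frame(
    trial_start_s = seq_len(14), stim_on_s = seq_len(14) + 0.1,
    stim_off_s = seq_len(14) + 0.5,
    orientation_deg = c(rep(c(0, 90), 6), NA, NA),
    contrast_pct = c(rep(c(5, 10, 20, 40, 60, 80), each = 2), 0, 0),
    blank = c(rep(FALSE, 12), TRUE, TRUE))
  ones <- fixture_trial_table(matrix(1, 1, 14), matrix(0.1, 1, 14), trials)
  cv <- contrast_curve(ones)
  expect_equal(cv$Rc, rep(1, 6))
  expect_equal(cv$blank_response, 1)
  bycontrast <- fixture_trial_table(matrix(trials$contrast_pct, 1),
                                    matrix(0.1, 1, 14), trials)
  cv2 <- contrast_curve(bycontrast)
  expect_equal(cv2$Rc, c(5, 10, 20, 40, 60, 80))
  expect_equal(cv2$blank_response, 0)
  # all-stationary: running curve is NA, stationary equals pooled
  st <- factor(rep("stationary", 14), levels = c("stationary", "running"))
  expect_warning(cv3 <- contrast_curve(ones, states = st), "no trials")
  expect_equal(cv3$Rc_stationary, cv3$Rc)
  expect_true(all(is.na(cv3$Rc_running)))
})

test_that("cCOM identities match a direct oracle", {
  cc <- c(5, 10, 20, 40, 60, 80)
  delta <- c(0, 0, 1, 0, 0, 0)
  expect_equal(ccom(delta, cc), 20)
  geo <- oracle_ccom(rep(1, 6), cc)
  expect_equal(ccom(rep(1, 6), cc), geo, tolerance = 1e-12)
  expect_equal(geo, 24.02, tolerance = 1e-3)     # geometric mean of the set
  expect_equal(ccom(cc, cc), oracle_ccom(cc, cc), tolerance = 1e-12)
  # invariant to positive scaling; bounded by the contrast range
  set.seed(2)
  r <- runif(6)
  expect_equal(ccom(3 * r, cc), ccom(r, cc), tolerance = 1e-12)
  expect_true(ccom(r, cc) >= 5 && ccom(r, cc) <= 80)
  # negative weights floored at zero
  expect_equal(ccom(c(-1, -2, 1, 0, 0, 0), cc), 20)
  expect_error(ccom(rep(-1, 6), cc), "undefined cCOM")
  expect_error(ccom(c(1, 1), c(0, 10)), "> 0")
})

test_that("preference classes follow the low/high contrast bands", {
  cc <- c(5, 10, 20, 40, 60, 80)
  expect_identical(preference_class(1:6, cc), "high")
  expect_identical(preference_class(6:1, cc), "low")
  expect_identical(preference_class(c(0, 1, 5, 1, 0, 0), cc), "other")
  # ties break to the lower contrast
  expect_identical(preference_class(c(1, 1, 1, 1, 1, 1), cc), "low")
  expect_error(preference_class(c(NA, 1:5), cc), "undefined")
})
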