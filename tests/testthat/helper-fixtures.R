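# Shared fixtures and independent brute-force oracles used across test files.
# Oracles are deliberately written as plain loops/direct formulas, independent
# of the package implementation paths they check.

# ---- brute-force metric oracles -------------------------------------------

oracle_gosi <- function(r, theta_deg) {
  num_re <- 0; num_im <- 0; den <- 0
  for (i in seq_along(r)) {
    th <- 2 * theta_deg[i] * pi / 180
    num_re <- num_re + r[i] * cos(th)
    num_im <- num_im + r[i] * sin(th)
    den <- den + r[i]
  }
  sqrt(num_re^2 + num_im^2) / den
}

oracle_dsi <- function(r, theta_deg) {
  pref <- which.max(r)
  opp <- ((theta_deg[pref] + 180) %% 360)
  null <- which(theta_deg == opp)
  (r[pref] - r[null]) / (r[pref] + r[null])
}

oracle_snr <- function(resp) {
  vals <- c()
  for (o in seq_len(ncol(resp))) {
    x <- resp[, o]
    m <- sum(x) / length(x)
    s <- sqrt(sum((x - m)^2) / (length(x) - 1))
    vals <- c(vals, m^2 / s)
  }
  mean(vals)
}

oracle_signal_correlation <- function(resp_j, resp_k, split) {
  mj <- apply(resp_j[split, , drop = FALSE], 2, mean)
  mk <- apply(resp_k[-split, , drop = FALSE], 2, mean)
  stats::cor(mj, mk)
}

oracle_noise_correlation <- function(resp_j, resp_k) {
  rs <- c()
  for (o in seq_len(ncol(resp_j)))
    rs <- c(rs, stats::cor(resp_j[, o], resp_k[, o]))
  mean(rs)
}

oracle_ccom <- function(rc, contrasts) {
  w <- ifelse(rc > 0, rc, 0)
  exp(sum(w * log(contrasts)) / sum(w))
}

oracle_rolling_percentile <- function(x, halfwidth, p) {
  n <- length(x)
  sapply(seq_len(n), function(i)
    unname(quantile(x[max(1, i - halfwidth):min(n, i + halfwidth)], p, type = 7)))
}

oracle_resample_5hz <- function(x, src_rate) {
  n <- length(x)
  dur <- (n - 1) / src_rate
  t10 <- seq(0, by = 0.1, length.out = floor(dur * 10 + 1e-9) + 1)
  z <- approx((seq_len(n) - 1) / src_rate, x, xout = t10)$y
  m <- length(z)
  sm <- numeric(m)
  for (i in seq_len(m)) {
    w <- max(1, i - 2):min(m, i + 2)
    sm[i] <- sum(z[w]) / length(w)
  }
  sm[seq(1, m, by = 2)]
}

# ---- small session fixtures ------------------------------------------------

# minimal orientation schedule + deterministic recording for tuning checks
fixture_orientation_session <- function(neurons, n_repeats = 3, seed = 7,
                                        deterministic = TRUE, ...) {
  sch <- make_schedule("orientation", n_repeats = n_repeats, seed = seed)
  speed <- gen_locomotion(sch$duration_s, seed = seed + 1)
  rec <- gen_recording(neurons, sch, speed, seed = seed + 2,
                       deterministic = deterministic, ...)
  sess <- new_session(rec, speed, schedule = sch, seed = seed)
  preprocess_session(sess)
}

# hand-built trial-response table (bypasses trace extraction)
fixture_trial_table <- function(response, baseline_sd, trials) {
  structure(list(response = response, baseline_sd = baseline_sd,
                 trials = trials, frame_rate = 30, baseline_s = 0.5),
            class = "trial_response_table")
}
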