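test_that("speed computation is exact for constant and linear motion", {
  t <- seq(0, 200, by = 2)
  const <- data.frame(t_ms = t, x_deg = rep(1.5, length(t)),
                      y_deg = rep(-2, length(t)))
  expect_true(all(compute_speed(const) == 0))

  # pure x-ramp at 10 deg/s: central differences are exact for linear signals
  ramp <- data.frame(t_ms = t, x_deg = 10 * t / 1000, y_deg = 0)
  sp <- compute_speed(ramp, smooth_window_samples = 1L)
  expect_equal(sp, rep(10, length(t)), tolerance = 1e-9, ignore_attr = TRUE)

  expect_error(compute_speed(const[1:2, ]), "at least 3 samples")
  expect_error(compute_speed(const, smooth_window_samples = 4L), "odd")
})

test_that("fixation-only noise produces no detections", {
  set.seed(42)
  t <- seq(0, 1000, by = 2)
  tr <- data.frame(t_ms = t, x_deg = rnorm(length(t), 0, 0.05),
                   y_deg = rnorm(length(t), 0, 0.05))
  expect_equal(nrow(detect_saccades(tr)), 0L)
})

test_that("single and double saccades are detected with accurate onsets", {
  tr <- one_saccade_trace(onset_ms = 150, noise_sd = 0.05, seed = 1)
  iv <- detect_saccades(tr)
  expect_equal(nrow(iv), 1L)
  expect_lt(abs(iv$onset_ms - 150), 4 + 1e-9)

  # two saccades 300 ms apart -> two ordered intervals
  set.seed(2)
  t <- seq(0, 900, by = 2)
  seg1 <- synth_saccade_segment(c(0, 0), c(7, 0), 200)
  seg2 <- synth_saccade_segment(c(7, 0), c(0, 0), 500)
  x <- numeric(length(t))
  x[t >= 200] <- stats::approx(seg1$t_ms, seg1$x_deg, t[t >= 200], rule = 2)$y
  x[t >= 500] <- stats::approx(seg2$t_ms, seg2$x_deg, t[t >= 500], rule = 2)$y
  tr2 <- data.frame(t_ms = t, x_deg = x + rnorm(length(t), 0, 0.05),
                    y_deg = rnorm(length(t), 0, 0.05))
  iv2 <- detect_saccades(tr2)
  expect_equal(nrow(iv2), 2L)
  expect_true(all(diff(iv2$onset_ms) > 0))
  expect_true(all(iv2$offset_ms[-nrow(iv2)] <= iv2$onset_ms[-1]))
})

test_that("raising the threshold never increases the number of detections", {
  set.seed(3)
  for (rep in 1:5) {
    tr <- one_saccade_trace(end = c(stats::runif(1, 3, 9), stats::runif(1, -3, 3)),
                            onset_ms = stats::runif(1, 100, 300),
                            noise_sd = 0.05)
    counts <- vapply(c(50, 100, 150, 250, 400), function(th)
      nrow(detect_saccades(tr, v_threshold = th)), integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("candidate runs touching missing samples are excluded with a reason", {
  # track loss starting right at the movement's tail: the suprathreshold
  # run abuts NA-speed samples and must be dropped, not truncated
  tr <- one_saccade_trace(onset_ms = 200, noise_sd = 0)
  tr$x_deg[tr$t_ms >= 236 & tr$t_ms < 262] <- NA
  iv <- detect_saccades(tr)
  expect_equal(nrow(iv), 0L)
  ex <- attr(iv, "excluded")
  expect_true(nrow(ex) >= 1L)
  expect_true(all(ex$reason == "touches-missing-samples"))

  # a gap far away from the saccade leaves detection untouched
  tr2 <- one_saccade_trace(onset_ms = 300, noise_sd = 0)
  tr2$x_deg[tr2$t_ms < 50] <- NA
  expect_equal(nrow(detect_saccades(tr2)), 1L)
})

test_that("metrics: latency arithmetic, direction convention and invariances", {
  tr <- one_saccade_trace(end = c(-7, 0), onset_ms = 150, noise_sd = 0)
  iv <- detect_saccades(tr)
  m <- saccade_metrics(tr, iv[1, ], jump_time_ms = 0, target_xy = c(-7, 0))
  expect_equal(m$latency_ms, m$onset_ms)
  expect_equal(m$direction_deg, 180, tolerance = 2)
  expect_lt(m$endpoint_error_deg, 0.1)

  # jump at 0 vs jump at 100 only shifts latency
  m2 <- saccade_metrics(tr, iv[1, ], jump_time_ms = 100)
  expect_equal(m2$latency_ms, m$latency_ms - 100)

  # rigid translation leaves amplitude/direction/peak velocity unchanged
  tr_shift <- tr
  tr_shift$x_deg <- tr_shift$x_deg + 3; tr_shift$y_deg <- tr_shift$y_deg - 2
  iv_s <- detect_saccades(tr_shift)
  m_s <- saccade_metrics(tr_shift, iv_s[1, ], jump_time_ms = 0)
  expect_equal(m_s$amplitude_deg, m$amplitude_deg, tolerance = 1e-9)
  expect_equal(m_s$direction_deg, m$direction_deg, tolerance = 1e-9)
  expect_equal(m_s$peak_velocity_deg_s, m$peak_velocity_deg_s,
               tolerance = 1e-9)

  # 90 degree coordinate rotation rotates the direction by 90 degrees
  tr_rot <- tr
  tr_rot$x_deg <- -tr$y_deg; tr_rot$y_deg <- tr$x_deg
  iv_r <- detect_saccades(tr_rot)
  m_r <- saccade_metrics(tr_rot, iv_r[1, ], jump_time_ms = 0)
  expect_equal((m_r$direction_deg - m$direction_deg) %% 360, 90,
               tolerance = 1e-6)

  expect_error(
    saccade_metrics(tr, list(onset_ms = 100, offset_ms = 100), 0),
    "degenerate")
})

test_that("detect_session agrees with the per-trace API", {
  s <- simulate_session(small_config(trials_per_block = 4L), seed = 13)
  tab <- detect_session(s)
  for (id in as.character(s$trials$trial_id[1:10])) {
    tr <- s$traces[[id]]
    iv <- detect_saccades(tr)
    sub <- tab[tab$trial_id == as.integer(id), ]
    expect_equal(nrow(sub), nrow(iv))
    if (nrow(iv)) {
      expect_equal(sub$onset_ms, iv$onset_ms)
      row <- s$trials[s$trials$trial_id == as.integer(id), ]
      m <- saccade_metrics(tr, iv[1, ], jump_time_ms = row$jump_time_ms,
                           target_xy = c(ifelse(row$jump_dir == "contra",
                                                7, -7), 0))
      expect_equal(sub$amplitude_deg[1], m$amplitude_deg, tolerance = 1e-9)
      expect_equal(sub$peak_velocity_deg_s[1], m$peak_velocity_deg_s,
                   tolerance = 1e-9)
      expect_equal(sub$endpoint_error_deg[1], m$endpoint_error_deg,
                   tolerance = 1e-9)
    }
  }
})
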