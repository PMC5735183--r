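test_that("main-sequence parameters follow the linear law and increase with amplitude", {
  ms7 <- main_sequence_params(7)
  expect_equal(ms7$duration_ms, 36.4)
  expect_equal(ms7$peak_velocity_deg_s, 2 * 7 / 0.0364, tolerance = 1e-12)

  ms14 <- main_sequence_params(14)
  expect_equal(ms14$duration_ms, 51.8)
  expect_gt(ms14$duration_ms, ms7$duration_ms)
  expect_gt(ms14$peak_velocity_deg_s, ms7$peak_velocity_deg_s)

  amps <- seq(0.5, 20, by = 0.5)
  out <- main_sequence_params(amps)
  expect_true(all(diff(out$duration_ms) > 0))
  expect_true(all(diff(out$peak_velocity_deg_s) > 0))

  expect_error(main_sequence_params(0), "positive")
  expect_error(main_sequence_params(-3), "positive")
})

test_that("saccade segment follows the raised-cosine profile exactly", {
  seg <- synth_saccade_segment(c(0, 0), c(7, 0), onset_ms = 100)
  D <- 36.4
  # boundary: final sample lands on the endpoint
  expect_equal(seg$x_deg[nrow(seg)], 7, tolerance = 1e-9)
  expect_equal(seg$y_deg[nrow(seg)], 0, tolerance = 1e-9)
  # symmetry: half the displacement at mid-flight (sampled on a grid that
  # contains D/2 exactly)
  seg_hi <- synth_saccade_segment(c(0, 0), c(7, 0), onset_ms = 0,
                                  sample_rate = 1e4)
  mid <- seg_hi$x_deg[which.min(abs(seg_hi$t_ms - D / 2))]
  expect_equal(mid, 3.5, tolerance = 1e-9)
  expect_error(synth_saccade_segment(c(1, 1), c(1, 1), 0), "zero-length")
})

test_that("finite-difference peak speed matches the dense-resampling oracle", {
  # oracle: the same profile sampled at 100 kHz, differenced numerically
  A <- 7; D <- 36.4
  t_hi <- seq(0, D, by = 0.01)
  s_hi <- A * (t_hi / D - sin(2 * pi * t_hi / D) / (2 * pi))
  v_oracle <- max(diff(s_hi) / 0.01) * 1000  # deg/s
  expect_equal(v_oracle, 2 * A / (D / 1000), tolerance = 1e-5)

  tr <- one_saccade_trace(end = c(7, 0))
  v500 <- max(compute_speed(tr, smooth_window_samples = 1L))
  expect_lt(abs(v500 - v_oracle) / v_oracle, 0.03)
})

test_that("trial simulation is deterministic and honours its ground truth", {
  cfg <- small_config()
  spec <- list(jump_dir = "contra", stim = 1L, electrode_id = 1L,
               current_uA = 250)
  a <- simulate_trial(cfg, spec, seed = 11)
  b <- simulate_trial(cfg, spec, seed = 11)
  expect_identical(a$trace, b$trace)
  expect_identical(a$truth, b$truth)

  # evocation probability 1 forces an evoked saccade inside [0, 100) ms
  ev <- cfg$evoking_electrodes
  ev$prob <- 1
  cfg1 <- sim_config(n_electrodes = 8L, evoking_electrodes = ev)
  tr <- simulate_trial(cfg1, spec, seed = 2)
  expect_true(tr$truth$evoked_present)
  expect_gte(tr$truth$evoked_onset_ms, 0)
  expect_lt(tr$truth$evoked_onset_ms, 100)

  # missing effect-map key is a configuration error
  cfg_bad <- small_config()
  cfg_bad$effect_map <- cfg_bad$effect_map[-1, ]
  expect_error(validate_sim_config(cfg_bad), "missing entries")
})

test_that("noiseless trial amplitude is recovered by the detector", {
  cfg <- sim_config(n_electrodes = 8L, noise_sd_deg = 0,
                    endpoint_sd_deg = 0, evoking_electrodes = NULL)
  tr <- simulate_trial(cfg, list(jump_dir = "contra", stim = 0L,
                                 electrode_id = 8L, current_uA = 100),
                       seed = 5)
  iv <- detect_saccades(tr$trace)
  expect_equal(nrow(iv), 1L)
  m <- saccade_metrics(tr$trace, iv[1, ], jump_time_ms = 800,
                       target_xy = c(7, 0))
  expect_equal(m$amplitude_deg, 7, tolerance = 0.05)
})

test_that("session layout: blocks, stimulation balance and grid split", {
  cfg <- small_config()
  s <- simulate_session(cfg, seed = 3)
  expect_equal(nrow(s$trials), 8 * 2 * 20)
  expect_equal(sum(s$trials$stim), 8 * 2 * 10)
  # per-block stimulation proportion exactly 0.5, directions within +/-1
  by_block <- split(s$trials, s$trials$block_id)
  expect_true(all(vapply(by_block, function(b) sum(b$stim) == 10, logical(1))))
  expect_true(all(vapply(by_block, function(b)
    abs(sum(b$jump_dir == "contra") - sum(b$jump_dir == "ipsi")) <= 1,
    logical(1))))
  # electrode map split into equal halves
  expect_equal(sum(s$electrode_map$group == "caudal"),
               sum(s$electrode_map$group == "rostral"))
  em96 <- electrode_grid(96L)
  expect_equal(unname(table(em96$group)[c("caudal", "rostral")]),
               c(48L, 48L), ignore_attr = TRUE)
  # every trial has exactly one ground-truth row
  expect_setequal(s$ground_truth$trial_id, s$trials$trial_id)
  expect_equal(anyDuplicated(s$ground_truth$trial_id), 0L)

  expect_error(sim_config(trials_per_block = 19L), "integer")
})

test_that("identical seed and config give identical sessions", {
  cfg <- small_config()
  s1 <- simulate_session(cfg, seed = 21)
  s2 <- simulate_session(cfg, seed = 21)
  expect_identical(s1$traces, s2$traces)
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$ground_truth, s2$ground_truth)
})

test_that("latency marginals converge to mu + tau + shift", {
  # 2000 control-like draws per direction through the trial worker
  cfg <- sim_config(n_electrodes = 2L, trials_per_block = 20L)
  n <- 2000
  set.seed(17)
  for (dir in c("contra", "ipsi")) {
    lats <- replicate(n, simulate_trial(cfg, list(
      jump_dir = dir, stim = 0L, electrode_id = 1L,
      current_uA = 100))$truth$true_task_latency_ms)
    lmod <- cfg$latency_model[[dir]]
    expected <- lmod[["mu"]] + lmod[["tau"]]
    se <- sqrt(lmod[["sigma"]]^2 + lmod[["tau"]]^2) / sqrt(n)
    expect_lt(abs(mean(lats) - expected), 3 * se)
  }
})

test_that("config YAML and session CSV round-trip", {
  cfg <- small_config(broken_electrodes = 4L)
  dir <- withr::local_tempdir()
  write_sim_config(cfg, file.path(dir, "cfg.yaml"))
  cfg2 <- read_sim_config(file.path(dir, "cfg.yaml"))
  expect_equal(cfg2$effect_map, cfg$effect_map, ignore_attr = TRUE)
  expect_equal(cfg2$latency_model, cfg$latency_model)
  expect_equal(cfg2$broken_electrodes, 4L)

  s <- simulate_session(small_config(trials_per_block = 4L), seed = 9)
  write_session(s, dir)
  expect_true(all(file.exists(file.path(dir,
    c("traces.csv", "trials.csv", "electrodes.csv", "ground_truth.csv",
      "config.yaml", "manifest.json")))))
  s2 <- read_session(dir)
  expect_equal(nrow(s2$trials), nrow(s$trials))
  expect_equal(length(s2$traces), length(s$traces))
  expect_equal(unname(s2$traces[["1"]][, "x_deg"]),
               unname(s$traces[["1"]][, "x_deg"]), tolerance = 1e-12)
})
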