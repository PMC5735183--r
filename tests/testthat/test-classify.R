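test_that("taxonomy windows match the evoked/task definitions", {
  expect_equal(classify_saccade(50, 40), "evoked")
  expect_equal(classify_saccade(150, 40), "task")
  expect_equal(classify_saccade(90, 80), "other")   # too long for evoked
  expect_equal(classify_saccade(450, 40), "other")  # outside both windows
  # boundary behaviour: evoked right-open at 100, task left-closed;
  # evoked duration <= 75, task duration < 75
  expect_equal(classify_saccade(99.99, 75), "evoked")
  expect_equal(classify_saccade(100, 74.9), "task")
  expect_equal(classify_saccade(100, 75), "other")
  expect_equal(classify_saccade(-5, 40), "other")
})

test_that("labels partition random events: every saccade gets exactly one class", {
  set.seed(1)
  lat <- runif(500, -50, 500)
  dur <- runif(500, 5, 120)
  lab <- classify_saccade(lat, dur)
  expect_true(all(lab %in% c("evoked", "task", "other")))
  in_evoked <- lat >= 0 & lat < 100 & dur <= 75
  in_task <- lat >= 100 & lat <= 400 & dur < 75
  expect_false(any(in_evoked & in_task))
  expect_equal(lab[in_evoked], rep("evoked", sum(in_evoked)))
  expect_equal(lab[in_task], rep("task", sum(in_task)))
})

test_that("evoked inclusion generalizes the 3-out-of-10 rule", {
  expect_true(evoked_inclusion(3, 10))
  expect_false(evoked_inclusion(2, 10))
  expect_true(evoked_inclusion(6, 20))
  expect_false(evoked_inclusion(2, 5))   # proportion ok but < 10 trials
  expect_error(evoked_inclusion(11, 10), "n_evoked")
  expect_error(evoked_inclusion(1, 0), "n_stim_trials")
})

test_that("confidence ellipse matches the chi-square quantile and coverage", {
  set.seed(7)
  pts <- matrix(rnorm(20000), ncol = 2)
  ell <- endpoint_ellipse(pts, level = 0.95)
  target <- sqrt(qchisq(0.95, 2))  # ~2.4477 for the unit isotropic Gaussian
  expect_lt(abs(ell$semi_axes_deg[1] - target) / target, 0.03)
  expect_lt(abs(ell$semi_axes_deg[2] - target) / target, 0.03)

  # coverage: fraction of same-distribution points inside the ellipse
  S <- stats::cov(pts); ctr <- colMeans(pts)
  d2 <- stats::mahalanobis(pts, ctr, S)
  expect_equal(mean(d2 <= qchisq(0.95, 2)), 0.95, tolerance = 0.01)

  expect_error(endpoint_ellipse(matrix(1, 5, 2)), "degenerate|collinear")
  expect_error(endpoint_ellipse(pts[1:2, ]), "at least 3")
})

test_that("ellipse is equivariant under rotation and translation", {
  set.seed(8)
  pts <- cbind(rnorm(500, sd = 2), rnorm(500, sd = 0.5))
  e0 <- endpoint_ellipse(pts)
  # translation moves only the center
  e_t <- endpoint_ellipse(sweep(pts, 2, c(-3, 10), "+"))
  expect_equal(e_t$center, e0$center + c(-3, 10), tolerance = 1e-9)
  expect_equal(e_t$semi_axes_deg, e0$semi_axes_deg, tolerance = 1e-9)
  # rotation by 90 degrees rotates the orientation, keeps the axes
  R <- matrix(c(0, 1, -1, 0), 2)
  e_r <- endpoint_ellipse(pts %*% t(R))
  expect_equal(sort(e_r$semi_axes_deg), sort(e0$semi_axes_deg),
               tolerance = 1e-9)
  expect_equal((e_r$orientation_deg - e0$orientation_deg) %% 180, 90,
               tolerance = 1e-6)
})

test_that("evoking electrodes are recovered and excluded with reasons", {
  # evocation probability 1 on the default evoking set -> exactly those
  # electrodes are flagged (>= 10 stimulation trials each)
  cfg <- small_config()
  ev <- cfg$evoking_electrodes
  ev$prob <- 1
  cfg <- sim_config(n_electrodes = 8L, evoking_electrodes = ev,
                    broken_electrodes = 8L)
  s <- simulate_session(cfg, seed = 4)
  sac <- classify_saccades(detect_session(s), s$trials)
  summ <- summarize_evoked(sac, s$trials)
  evoking_ids <- sort(unique(ev$electrode_id))
  hi <- max(summ$current_uA)
  flagged <- sort(summ$electrode_id[summ$included & summ$current_uA == hi])
  expect_equal(flagged, evoking_ids)

  excl <- flag_excluded_electrodes(summ, s$electrode_map)
  expect_setequal(excl$electrode_id, c(evoking_ids, 8L))
  expect_equal(sort(excl$reason[excl$electrode_id %in% evoking_ids]),
               rep("evokes-saccades", length(evoking_ids)))
  expect_equal(excl$reason[excl$electrode_id == 8L], "broken")

  # non-evoking, working electrode is retained
  expect_false(5L %in% excl$electrode_id ||
                 any(summ$included[summ$electrode_id == 5L]))
})

test_that("first task saccade per trial is flagged exactly once", {
  s <- simulate_session(small_config(trials_per_block = 6L), seed = 6)
  sac <- classify_saccades(detect_session(s), s$trials)
  per_trial <- tapply(sac$first_task, sac$trial_id, sum)
  expect_true(all(per_trial <= 1))
  has_task <- tapply(sac$label == "task", sac$trial_id, any)
  expect_equal(unname(per_trial[has_task]),
               rep(1L, sum(has_task)), ignore_attr = TRUE)
})
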