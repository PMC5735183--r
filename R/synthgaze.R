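# Synthetic eye-trace generation: main-sequence saccades, ex-Gaussian
# latencies, stimulation-evoked saccades, additive gaze noise.

#' Main-sequence saccade kinematics
#'
#' Linear amplitude-duration main sequence `duration = d0 + d1 * A` with a
#' raised-cosine velocity profile, whose peak velocity is `2 A / duration`.
#' Both outputs are strictly increasing in amplitude.
#'
#' @param amplitude_deg saccade amplitude in degrees (> 0).
#' @param d0,d1 duration intercept (ms) and slope (ms/deg).
#' @return list with `duration_ms` and `peak_velocity_deg_s`.
#' @examples
#' main_sequence_params(7) # 36.4 ms, ~384.6 deg/s
#' @export
main_sequence_params <- function(amplitude_deg, d0 = 21, d1 = 2.2) {
  if (!is.numeric(amplitude_deg) || any(is.na(amplitude_deg)) ||
      any(amplitude_deg <= 0))
    .stopf("amplitude_deg must be positive")
  duration_ms <- d0 + d1 * amplitude_deg
  list(duration_ms = duration_ms,
       peak_velocity_deg_s = 2 * amplitude_deg / (duration_ms / 1000))
}

#' Synthesize one saccade segment
#'
#' Straight-line displacement from `start_xy` to `end_xy` following the
#' raised-cosine position profile
#' `s(t) = A (t/D - sin(2 pi t / D) / (2 pi))`, which starts and ends at
#' zero velocity and peaks at `2A/D` at mid-flight.
#'
#' @param start_xy,end_xy numeric length-2 positions in degrees.
#' @param onset_ms saccade onset time.
#' @param sample_rate sampling rate in Hz.
#' @param d0,d1 main-sequence constants, see [main_sequence_params()].
#' @return data.frame with `t_ms`, `x_deg`, `y_deg` covering
#'   `[onset, onset + duration]` on the sample grid.
#' @export
synth_saccade_segment <- function(start_xy, end_xy, onset_ms, sample_rate = 500,
                                  d0 = 21, d1 = 2.2) {
  delta <- c(end_xy[1] - start_xy[1], end_xy[2] - start_xy[2])
  amp <- sqrt(sum(delta^2))
  if (amp == 0) .stopf("zero-length saccade: start and end coincide")
  dur <- main_sequence_params(amp, d0, d1)$duration_ms
  dt <- 1000 / sample_rate
  t_rel <- seq(0, dur, by = dt)
  if (t_rel[length(t_rel)] < dur) t_rel <- c(t_rel, dur)
  frac <- .raised_cosine_frac(t_rel, dur)
  data.frame(t_ms = onset_ms + t_rel,
             x_deg = start_xy[1] + delta[1] * frac,
             y_deg = start_xy[2] + delta[2] * frac)
}

# fraction of total displacement covered at time t of a saccade of
# duration D under the raised-cosine velocity profile
.raised_cosine_frac <- function(t, D) {
  f <- t / D - sin(2 * pi * t / D) / (2 * pi)
  f[t <= 0] <- 0; f[t >= D] <- 1
  f
}

# von Mises sampler (Best & Fisher 1979 rejection scheme), degrees in/out.
rvonmises_deg <- function(n, mu_deg, kappa) {
  if (n == 0L) return(numeric(0))
  if (kappa < 1e-8) return(runif(n, 0, 360))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n); i <- 0L
  while (i < n) {
    u1 <- runif(1); z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- runif(1)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      u3 <- runif(1)
      i <- i + 1L
      out[i] <- sign(u3 - 0.5) * acos(pmin(1, pmax(-1, f)))
    }
  }
  .wrap360(mu_deg + .rad2deg(out))
}

# one ex-Gaussian latency draw per element of mu/shift; resampled while
# the shifted latency would be non-positive (vanishingly rare at defaults)
.rexgauss_shifted <- function(mu, sigma, tau, shift) {
  lat <- rnorm(1, mu, sigma) + (if (tau > 0) rexp(1, 1 / tau) else 0) + shift
  while (lat <= 10) {
    lat <- rnorm(1, mu, sigma) + (if (tau > 0) rexp(1, 1 / tau) else 0) + shift
  }
  lat
}

# Internal trial worker. trial_spec: list/1-row df with jump_dir ("ipsi"/
# "contra"), stim (0/1), electrode_id, current_uA (block current). Consumes
# the current RNG stream. Returns list(trace = matrix, truth = 1-row df).
.simulate_trial_core <- function(cfg, jump_dir, stim, electrode_id,
                                 block_current) {
  dt <- 1000 / cfg$sample_rate
  jump_t <- cfg$fixation_ms
  dir_sign <- if (jump_dir == "contra") 1 else -1
  target <- c(dir_sign * cfg$jump_amplitude_deg, 0)
  d0 <- cfg$main_sequence[["d0"]]; d1 <- cfg$main_sequence[["d1"]]

  emap <- cfg$electrode_map
  group <- emap$group[match(electrode_id, emap$electrode_id)]

  shift <- 0
  if (stim == 1L) {
    em <- cfg$effect_map
    hit <- em$group == group & em$current_uA == block_current &
      em$direction == jump_dir
    if (!any(hit))
      .stopf("effect_map has no entry for (%s, %s uA, %s)",
             group, block_current, jump_dir)
    shift <- em$shift_ms[which(hit)[1]]
  }

  # evoked saccade (stimulation-triggered, electrode- and current-specific)
  evoked <- FALSE; ev_onset <- NA_real_; ev_dir <- NA_real_; ev_amp <- NA_real_
  ev_end <- c(0, 0)
  if (stim == 1L && !is.null(cfg$evoking_electrodes) &&
      nrow(cfg$evoking_electrodes)) {
    ev <- cfg$evoking_electrodes
    row <- which(ev$electrode_id == electrode_id &
                 ev$current_uA == block_current)
    if (length(row) && runif(1) < ev$prob[row[1]]) {
      evoked <- TRUE
      row <- row[1]
      ev_onset <- runif(1, cfg$evoked_onset_window_ms[1],
                        cfg$evoked_onset_window_ms[2])
      ev_dir <- rvonmises_deg(1, ev$pref_dir_deg[row], ev$dir_kappa[row])
      ev_amp <- max(0.5, rnorm(1, ev$pref_amp_deg[row], ev$amp_sd_deg[row]))
      ev_end <- ev_amp * c(cos(.deg2rad(ev_dir)), sin(.deg2rad(ev_dir)))
    }
  }

  lm_ <- cfg$latency_model[[jump_dir]]
  latency <- .rexgauss_shifted(lm_[["mu"]], lm_[["sigma"]], lm_[["tau"]], shift)

  task_start <- if (evoked) ev_end else c(0, 0)
  landing <- target + rnorm(2, 0, cfg$endpoint_sd_deg)
  task_delta <- landing - task_start
  task_amp <- sqrt(sum(task_delta^2))
  task_dur <- d0 + d1 * task_amp
  task_onset <- jump_t + latency

  end_ms <- task_onset + task_dur + cfg$post_saccade_ms
  if (evoked) {
    ev_dur <- d0 + d1 * ev_amp
    end_ms <- max(end_ms, jump_t + ev_onset + ev_dur + cfg$post_saccade_ms)
  }
  n <- floor(end_ms / dt) + 1L
  t <- (seq_len(n) - 1L) * dt
  x <- numeric(n); y <- numeric(n)

  place <- function(x, y, start_xy, delta, onset, dur) {
    i0 <- which(t >= onset)[1]
    frac <- .raised_cosine_frac(t[i0:n] - onset, dur)
    x[i0:n] <- start_xy[1] + delta[1] * frac
    y[i0:n] <- start_xy[2] + delta[2] * frac
    list(x = x, y = y)
  }
  if (evoked) {
    p <- place(x, y, c(0, 0), ev_end, jump_t + ev_onset, ev_dur)
    x <- p$x; y <- p$y
  }
  p <- place(x, y, task_start, task_delta, task_onset, task_dur)
  x <- p$x; y <- p$y

  if (cfg$noise_sd_deg > 0) {
    x <- x + rnorm(n, 0, cfg$noise_sd_deg)
    y <- y + rnorm(n, 0, cfg$noise_sd_deg)
  }
  if (cfg$blink_rate > 0 && runif(1) < cfg$blink_rate) {
    g0 <- runif(1, 100, cfg$fixation_ms - cfg$blink_ms - 100)
    gap <- t >= g0 & t < g0 + cfg$blink_ms
    x[gap] <- NA_real_; y[gap] <- NA_real_
  }

  trace <- cbind(t_ms = t, x_deg = x, y_deg = y)
  truth <- c(
    true_task_latency_ms = latency,
    applied_shift_ms = shift,
    true_task_onset_ms = task_onset,
    true_task_amplitude_deg = task_amp,
    true_task_direction_deg = .wrap360(.rad2deg(atan2(task_delta[2],
                                                      task_delta[1]))),
    evoked_present = as.numeric(evoked),
    evoked_onset_ms = ev_onset,
    evoked_direction_deg = ev_dir,
    evoked_amplitude_deg = ev_amp)
  list(trace = trace, truth = truth)
}

.truth_to_df <- function(truth_rows, trial_ids) {
  m <- do.call(rbind, truth_rows)
  df <- as.data.frame(m)
  df$evoked_present <- df$evoked_present > 0
  cbind(data.frame(trial_id = trial_ids), df)
}

#' Simulate a single trial
#'
#' Generates one trial's eye trace (fixation epoch, optional
#' stimulation-evoked saccade, task saccade to the jumped target, additive
#' Gaussian gaze noise) together with its metadata row and ground truth.
#'
#' @param config a [sim_config()].
#' @param trial_spec list with `jump_dir` (`"ipsi"`/`"contra"`), `stim`
#'   (0/1), `electrode_id`, `current_uA` (the block's stimulation current),
#'   and optionally `trial_id`, `block_id`.
#' @param seed optional integer; when given, seeds the trial
#'   deterministically (callers running many trials should instead seed
#'   once and call repeatedly).
#' @return list with `trace` (data.frame `t_ms`, `x_deg`, `y_deg`),
#'   `trial` (1-row [TrialRecord][simulate_session] metadata) and `truth`
#'   (1-row ground-truth data.frame).
#' @export
simulate_trial <- function(config, trial_spec, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) {
    old <- .save_seed(); on.exit(.restore_seed(old), add = TRUE)
    set.seed(seed)
  }
  jump_dir <- match.arg(trial_spec$jump_dir, c("ipsi", "contra"))
  stim <- as.integer(trial_spec$stim)
  electrode_id <- as.integer(trial_spec$electrode_id)
  block_current <- as.numeric(trial_spec$current_uA)
  trial_id <- if (is.null(trial_spec$trial_id)) 1L else
    as.integer(trial_spec$trial_id)
  block_id <- if (is.null(trial_spec$block_id)) 1L else
    as.integer(trial_spec$block_id)
  core <- .simulate_trial_core(config, jump_dir, stim, electrode_id,
                               block_current)
  trial <- data.frame(
    trial_id = trial_id, block_id = block_id,
    jump_time_ms = config$fixation_ms, jump_dir = jump_dir, stim = stim,
    electrode_id = electrode_id,
    current_uA = if (stim == 1L) block_current else 0,
    block_current_uA = block_current, outcome = "correct",
    stringsAsFactors = FALSE)
  truth <- .truth_to_df(list(core$truth), trial_id)
  list(trace = as.data.frame(core$trace), trial = trial, truth = truth)
}

#' Simulate a full stimulation session
#'
#' Runs one block of `trials_per_block` trials per electrode x current with
#' exactly `stim_fraction` of each block stimulated, left/right jumps
#' balanced within each stimulation arm and the trial order shuffled within
#' block. With the defaults this yields 96 x 2 x 20 = 3840 trials, 1920 of
#' them stimulated.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return object of class `stim_session`: list with `traces` (list of
#'   per-trial matrices `t_ms`/`x_deg`/`y_deg`, named by trial id),
#'   `trials` (trial metadata), `electrode_map`, `ground_truth`, `config`,
#'   `seed`.
#' @export
simulate_session <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  old <- .save_seed(); on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)

  tpb <- config$trials_per_block
  n_stim <- round(tpb * config$stim_fraction)
  n_ctrl <- tpb - n_stim
  blocks <- expand.grid(electrode_id = config$electrode_map$electrode_id,
                        current_uA = config$currents_uA)
  blocks <- blocks[order(blocks$electrode_id, blocks$current_uA), ]
  n_trials <- nrow(blocks) * tpb

  traces <- vector("list", n_trials)
  trials <- vector("list", n_trials)
  truths <- vector("list", n_trials)
  tid <- 0L

  balanced_dirs <- function(k) {
    # left/right balanced within +/-1; order randomized
    base <- rep(c("contra", "ipsi"), length.out = k)
    sample(base)
  }

  for (b in seq_len(nrow(blocks))) {
    el <- blocks$electrode_id[b]; cur <- blocks$current_uA[b]
    stim_flags <- sample(c(rep(1L, n_stim), rep(0L, n_ctrl)))
    dirs <- character(tpb)
    dirs[stim_flags == 1L] <- balanced_dirs(n_stim)
    dirs[stim_flags == 0L] <- balanced_dirs(n_ctrl)
    for (k in seq_len(tpb)) {
      tid <- tid + 1L
      core <- .simulate_trial_core(config, dirs[k], stim_flags[k], el, cur)
      traces[[tid]] <- core$trace
      trials[[tid]] <- list(trial_id = tid, block_id = b,
                            jump_dir = dirs[k], stim = stim_flags[k],
                            electrode_id = el,
                            current_uA = if (stim_flags[k] == 1L) cur else 0,
                            block_current_uA = cur)
      truths[[tid]] <- core$truth
    }
  }

  trials_df <- data.frame(
    trial_id = vapply(trials, `[[`, integer(1), "trial_id"),
    block_id = vapply(trials, `[[`, integer(1), "block_id"),
    jump_time_ms = config$fixation_ms,
    jump_dir = vapply(trials, `[[`, character(1), "jump_dir"),
    stim = vapply(trials, `[[`, integer(1), "stim"),
    electrode_id = vapply(trials, function(x) as.integer(x$electrode_id),
                          integer(1)),
    current_uA = vapply(trials, function(x) as.numeric(x$current_uA),
                        numeric(1)),
    block_current_uA = vapply(trials, function(x)
      as.numeric(x$block_current_uA), numeric(1)),
    outcome = "correct",
    stringsAsFactors = FALSE)
  truth_df <- .truth_to_df(truths, trials_df$trial_id)
  names(traces) <- as.character(trials_df$trial_id)

  structure(list(traces = traces, trials = trials_df,
                 electrode_map = config$electrode_map,
                 ground_truth = truth_df, config = config, seed = seed),
            class = "stim_session")
}

#' @export
print.stim_session <- function(x, ...) {
  cat(sprintf("Synthetic stimulation session: %d trials (%d stimulated), %d electrodes, seed %d\n",
              nrow(x$trials), sum(x$trials$stim), nrow(x$electrode_map),
              x$seed))
  invisible(x)
}

#' Write / read a session as plain-text CSV
#'
#' `write_session` writes `traces.csv` (long format: trial_id, t_ms, x_deg,
#' y_deg), `trials.csv`, `electrodes.csv`, `ground_truth.csv`, the
#' configuration as `config.yaml` and a `manifest.json` recording the seed.
#' `read_session` reconstructs the session from such a directory (or from
#' the three analysis inputs alone, without ground truth).
#'
#' @param session a `stim_session`.
#' @param dir output directory (created if needed).
#' @return `write_session`: `dir`, invisibly. `read_session`: a
#'   `stim_session` (with `ground_truth`/`config` `NULL` when absent).
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "stim_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  long <- do.call(rbind, lapply(names(session$traces), function(id) {
    tr <- session$traces[[id]]
    cbind(trial_id = as.integer(id), as.data.frame(tr))
  }))
  write.csv(long, file.path(dir, "traces.csv"), row.names = FALSE)
  write.csv(session$trials, file.path(dir, "trials.csv"), row.names = FALSE)
  write.csv(session$electrode_map, file.path(dir, "electrodes.csv"),
            row.names = FALSE)
  if (!is.null(session$ground_truth))
    write.csv(session$ground_truth, file.path(dir, "ground_truth.csv"),
              row.names = FALSE)
  if (!is.null(session$config))
    write_sim_config(session$config, file.path(dir, "config.yaml"))
  manifest <- list(seed = session$seed,
                   n_trials = nrow(session$trials),
                   sample_rate = if (!is.null(session$config))
                     session$config$sample_rate else NA,
                   package_version = as.character(packageVersion("stimsacc")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_session
#' @param traces,trials,electrodes,ground_truth,config optional explicit
#'   file paths overriding the defaults inside `dir`.
#' @export
read_session <- function(dir = NULL, traces = NULL, trials = NULL,
                         electrodes = NULL, ground_truth = NULL,
                         config = NULL) {
  pick <- function(explicit, default) {
    if (!is.null(explicit)) explicit
    else if (!is.null(dir) && file.exists(file.path(dir, default)))
      file.path(dir, default) else NULL
  }
  f_traces <- pick(traces, "traces.csv")
  f_trials <- pick(trials, "trials.csv")
  f_map <- pick(electrodes, "electrodes.csv")
  f_truth <- pick(ground_truth, "ground_truth.csv")
  f_cfg <- pick(config, "config.yaml")
  for (f in list(f_traces, f_trials, f_map)) if (is.null(f))
    .stopf("traces, trials and electrodes files are all required")
  long <- read.csv(f_traces)
  .require_cols(long, c("trial_id", "t_ms", "x_deg", "y_deg"), "traces")
  trials_df <- read.csv(f_trials, stringsAsFactors = FALSE)
  .require_cols(trials_df, c("trial_id", "jump_time_ms", "jump_dir", "stim",
                             "electrode_id", "current_uA"), "trials")
  if (is.null(trials_df$block_current_uA)) {
    # recover block current for control trials from the block's stim trials
    key <- if (!is.null(trials_df$block_id)) trials_df$block_id
      else trials_df$electrode_id
    bc <- tapply(trials_df$current_uA, key, max)
    trials_df$block_current_uA <- as.numeric(bc[as.character(key)])
  }
  if (is.null(trials_df$outcome)) trials_df$outcome <- "correct"
  map_df <- read.csv(f_map, stringsAsFactors = FALSE)
  .require_cols(map_df, c("electrode_id", "row", "col", "group", "status"),
                "electrodes")
  split_idx <- split(seq_len(nrow(long)), long$trial_id)
  traces_list <- lapply(split_idx, function(ix)
    cbind(t_ms = long$t_ms[ix], x_deg = long$x_deg[ix], y_deg = long$y_deg[ix]))
  # keep trial order, not alphabetical
  traces_list <- traces_list[as.character(trials_df$trial_id)]
  truth_df <- if (!is.null(f_truth)) read.csv(f_truth) else NULL
  cfg <- if (!is.null(f_cfg)) read_sim_config(f_cfg) else NULL
  structure(list(traces = traces_list, trials = trials_df,
                 electrode_map = map_df, ground_truth = truth_df,
                 config = cfg, seed = NA_integer_),
            class = "stim_session")
}

.require_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    .stopf("%s table is missing column(s): %s", what,
           paste(missing, collapse = ", "))
  invisible(df)
}
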