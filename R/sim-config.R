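# Simulation configuration for synthetic center-out saccade sessions.

#' Default stimulation latency-effect map
#'
#' Latency shifts (ms, added to the ex-Gaussian draw on stimulation trials)
#' per electrode group x current x saccade direction. The default encodes
#' the study conditions the generator emulates: ipsiversive saccades are
#' speeded everywhere on the array (-9 ms at 100 uA, -22 ms at 250 uA)
#' while contraversive saccades are delayed only by caudal stimulation
#' (+4 ms at 100 uA, +25 ms at 250 uA; rostral shift 0).
#'
#' @param currents_uA stimulation currents the session uses.
#' @return data.frame with columns `group`, `current_uA`, `direction`,
#'   `shift_ms` covering the full grid.
#' @export
default_effect_map <- function(currents_uA = c(100, 250)) {
  grid <- expand.grid(group = c("rostral", "caudal"),
                      current_uA = currents_uA,
                      direction = c("ipsi", "contra"),
                      stringsAsFactors = FALSE)
  ipsi_shift <- c("100" = -9, "250" = -22)
  contra_shift <- c("100" = 4, "250" = 25)
  grid$shift_ms <- ifelse(
    grid$direction == "ipsi",
    ipsi_shift[as.character(grid$current_uA)],
    ifelse(grid$group == "caudal",
           contra_shift[as.character(grid$current_uA)], 0))
  grid$shift_ms[is.na(grid$shift_ms)] <- 0
  grid
}

#' Default saccade-evoking electrode set
#'
#' A small cluster of electrodes on the caudal border of the grid evokes
#' saccades under stimulation: four "robust" sites evoke at both currents
#' (probability 0.5 at 100 uA, 0.85 at 250 uA) and three adjacent sites
#' evoke essentially only at the high current (0.05 vs 0.7). Preferred
#' vectors point into the contralateral (rightward) hemifield with
#' electrode-specific directions; amplitude scales with current
#' (gain 1.3 at 250 uA) and direction rotates by +8 degrees at 250 uA.
#'
#' @param electrode_map as produced by [electrode_grid()]; evokers are
#'   placed on its caudal-most column.
#' @param currents_uA stimulation currents.
#' @return data.frame keyed by (`electrode_id`, `current_uA`) with columns
#'   `prob`, `pref_dir_deg`, `pref_amp_deg`, `dir_kappa`, `amp_sd_deg`.
#' @export
default_evoking_electrodes <- function(electrode_map,
                                       currents_uA = c(100, 250)) {
  caudal <- electrode_map[electrode_map$group == "caudal", ]
  border <- caudal[caudal$col == min(caudal$col), ]
  border <- border[order(border$row), ]
  n_sites <- min(7L, nrow(border))
  ids <- border$electrode_id[seq_len(n_sites)]
  robust <- ids[seq_len(min(4L, n_sites))]
  dirs <- c(-45, -15, 15, 45, -30, 0, 30)[seq_len(n_sites)]
  amps <- c(4.5, 5.5, 5, 6, 4, 4.5, 5)[seq_len(n_sites)]
  hi <- max(currents_uA)
  out <- do.call(rbind, lapply(seq_len(n_sites), function(i) {
    is_robust <- ids[i] %in% robust
    data.frame(electrode_id = ids[i], current_uA = currents_uA,
               prob = ifelse(currents_uA == hi,
                             if (is_robust) 0.85 else 0.7,
                             if (is_robust) 0.5 else 0.05),
               pref_dir_deg = dirs[i] + ifelse(currents_uA == hi, 8, 0),
               pref_amp_deg = amps[i] * ifelse(currents_uA == hi, 1.3, 1),
               dir_kappa = 20, amp_sd_deg = 0.6,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Electrode-grid map
#'
#' Lays `n_electrodes` out on a square grid (a 96-channel array occupies a
#' 10 x 10 grid minus the four corners) and splits it into equal-sized
#' caudal and rostral halves along the column (rostro-caudal) axis; lower
#' column indices are caudal (towards the arcuate sulcus / FEF).
#'
#' @param n_electrodes number of electrodes (default 96).
#' @param broken integer ids flagged `status = "broken"`.
#' @return data.frame with `electrode_id`, `row`, `col`, `group`
#'   (`"caudal"`/`"rostral"`), `status` (`"ok"`/`"broken"`).
#' @export
electrode_grid <- function(n_electrodes = 96L, broken = integer(0)) {
  if (n_electrodes < 2L) .stopf("need at least 2 electrodes")
  if (n_electrodes %% 2L != 0L)
    .stopf("n_electrodes must be even for equal rostral/caudal halves")
  if (n_electrodes == 96L) {
    side <- 10L
    cells <- expand.grid(row = seq_len(side), col = seq_len(side))
    corner <- (cells$row %in% c(1L, side)) & (cells$col %in% c(1L, side))
    cells <- cells[!corner, ]
  } else {
    side <- ceiling(sqrt(n_electrodes))
    cells <- expand.grid(row = seq_len(side), col = seq_len(side))
    cells <- cells[seq_len(n_electrodes), ]
  }
  cells <- cells[order(cells$col, cells$row), ]
  cells$electrode_id <- seq_len(nrow(cells))
  # equal split along the rostro-caudal (column) axis by electrode count
  half <- nrow(cells) %/% 2L
  cells$group <- c(rep("caudal", half), rep("rostral", nrow(cells) - half))
  cells$status <- ifelse(cells$electrode_id %in% broken, "broken", "ok")
  rownames(cells) <- NULL
  cells[c("electrode_id", "row", "col", "group", "status")]
}

#' Simulation configuration
#'
#' Bundles the task constants and the generative model of a synthetic
#' stimulation session. Defaults reproduce the experiment's layout: 500 Hz
#' sampling, 800 ms fixation, a +/-7 degree horizontal fixation-point jump,
#' a 96-channel grid stimulated blockwise (20 trials per electrode x
#' current, 50% stimulated), currents of 100 and 250 uA, ex-Gaussian
#' latencies with a 26 ms contraversive baseline advantage, the latency
#' effect map of [default_effect_map()], and the evoked-saccade cluster of
#' [default_evoking_electrodes()].
#'
#' @param sample_rate sampling rate in Hz.
#' @param fixation_ms fixation duration before the jump, ms.
#' @param jump_amplitude_deg horizontal target eccentricity, degrees.
#' @param fixation_radius_deg fixation tolerance window radius, degrees.
#' @param n_electrodes electrodes on the array.
#' @param trials_per_block trials per electrode x current block;
#'   `trials_per_block * stim_fraction` must be an integer.
#' @param stim_fraction fraction of stimulated trials per block.
#' @param currents_uA stimulation currents in microampere.
#' @param latency_model list with elements `contra` and `ipsi`, each a
#'   named vector `c(mu, sigma, tau)` of ex-Gaussian parameters in ms. If
#'   `NULL`, `ipsi = c(186, 25, 40)` and `mu_contra = mu_ipsi -
#'   baseline_contra_advantage_ms`.
#' @param baseline_contra_advantage_ms mean latency advantage of
#'   contraversive over ipsiversive saccades on control trials, ms.
#' @param effect_map latency shift table, see [default_effect_map()].
#' @param evoking_electrodes evoked-saccade table, see
#'   [default_evoking_electrodes()]; `NULL` for none, `"default"` for the
#'   default cluster.
#' @param noise_sd_deg additive isotropic Gaussian gaze noise, degrees.
#' @param endpoint_sd_deg per-axis scatter of task-saccade landing points
#'   around the target, degrees.
#' @param main_sequence `c(d0, d1)`: saccade duration d0 + d1 * amplitude
#'   (ms, ms/deg).
#' @param evoked_onset_window_ms evoked-saccade onset window after
#'   stimulation onset, ms.
#' @param post_saccade_ms trace padding after the last saccade, ms.
#' @param broken_electrodes electrode ids flagged broken (excluded from
#'   analyses, still stimulated).
#' @param blink_rate probability per trial of a simulated track-loss gap
#'   (NaN samples) during fixation; off by default.
#' @param blink_ms gap duration, ms.
#' @param seed default seed used by [simulate_session()].
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(sample_rate = 500,
                       fixation_ms = 800,
                       jump_amplitude_deg = 7,
                       fixation_radius_deg = 2,
                       n_electrodes = 96L,
                       trials_per_block = 20L,
                       stim_fraction = 0.5,
                       currents_uA = c(100, 250),
                       latency_model = NULL,
                       baseline_contra_advantage_ms = 26,
                       effect_map = NULL,
                       evoking_electrodes = "default",
                       noise_sd_deg = 0.05,
                       endpoint_sd_deg = 0.35,
                       main_sequence = c(d0 = 21, d1 = 2.2),
                       evoked_onset_window_ms = c(20, 60),
                       post_saccade_ms = 100,
                       broken_electrodes = integer(0),
                       blink_rate = 0,
                       blink_ms = 100,
                       seed = 1L) {
  if (is.null(latency_model)) {
    ipsi <- c(mu = 186, sigma = 25, tau = 40)
    latency_model <- list(
      contra = c(mu = unname(ipsi["mu"]) - baseline_contra_advantage_ms,
                 sigma = 25, tau = 40),
      ipsi = ipsi)
  }
  if (is.null(names(main_sequence))) names(main_sequence) <- c("d0", "d1")
  electrode_map <- electrode_grid(n_electrodes, broken = broken_electrodes)
  if (is.null(effect_map)) effect_map <- default_effect_map(currents_uA)
  if (identical(evoking_electrodes, "default"))
    evoking_electrodes <- default_evoking_electrodes(electrode_map, currents_uA)
  cfg <- structure(list(
    sample_rate = sample_rate, fixation_ms = fixation_ms,
    jump_amplitude_deg = jump_amplitude_deg,
    fixation_radius_deg = fixation_radius_deg,
    n_electrodes = as.integer(n_electrodes),
    trials_per_block = as.integer(trials_per_block),
    stim_fraction = stim_fraction, currents_uA = sort(currents_uA),
    latency_model = latency_model,
    baseline_contra_advantage_ms = baseline_contra_advantage_ms,
    effect_map = effect_map, evoking_electrodes = evoking_electrodes,
    electrode_map = electrode_map,
    noise_sd_deg = noise_sd_deg, endpoint_sd_deg = endpoint_sd_deg,
    main_sequence = main_sequence,
    evoked_onset_window_ms = evoked_onset_window_ms,
    post_saccade_ms = post_saccade_ms,
    broken_electrodes = as.integer(broken_electrodes),
    blink_rate = blink_rate, blink_ms = blink_ms,
    seed = as.integer(seed)), class = "sim_config")
  validate_sim_config(cfg)
}

#' Validate a simulation configuration
#'
#' @param cfg a `sim_config`.
#' @return the configuration, invisibly checked; errors describe the
#'   offending field.
#' @export
validate_sim_config <- function(cfg) {
  if (cfg$sample_rate <= 0) .stopf("sample_rate must be > 0")
  if (cfg$stim_fraction < 0 || cfg$stim_fraction > 1)
    .stopf("stim_fraction must be in [0, 1]")
  n_stim <- cfg$trials_per_block * cfg$stim_fraction
  if (abs(n_stim - round(n_stim)) > 1e-9)
    .stopf("trials_per_block (%d) times stim_fraction (%g) must be an integer",
           cfg$trials_per_block, cfg$stim_fraction)
  for (dir in c("contra", "ipsi")) {
    lm_ <- cfg$latency_model[[dir]]
    if (is.null(lm_) || !all(c("mu", "sigma", "tau") %in% names(lm_)))
      .stopf("latency_model$%s must provide mu, sigma, tau", dir)
    if (lm_[["sigma"]] <= 0) .stopf("latency sigma must be > 0")
    if (lm_[["tau"]] < 0) .stopf("latency tau must be >= 0")
  }
  em <- cfg$effect_map
  need <- c("group", "current_uA", "direction", "shift_ms")
  if (!all(need %in% names(em)))
    .stopf("effect_map must have columns %s", paste(need, collapse = ", "))
  want <- expand.grid(group = c("rostral", "caudal"),
                      current_uA = cfg$currents_uA,
                      direction = c("ipsi", "contra"),
                      stringsAsFactors = FALSE)
  key <- function(d) paste(d$group, d$current_uA, d$direction)
  missing_keys <- setdiff(key(want), key(em))
  if (length(missing_keys))
    .stopf("effect_map is missing entries for: %s",
           paste(missing_keys, collapse = "; "))
  ev <- cfg$evoking_electrodes
  if (!is.null(ev) && nrow(ev)) {
    if (any(ev$prob < 0 | ev$prob > 1))
      .stopf("evocation probabilities must be in [0, 1]")
    if (!all(ev$electrode_id %in% cfg$electrode_map$electrode_id))
      .stopf("evoking_electrodes references unknown electrode ids")
  }
  if (cfg$noise_sd_deg < 0) .stopf("noise_sd_deg must be >= 0")
  if (cfg$blink_rate < 0 || cfg$blink_rate > 1)
    .stopf("blink_rate must be in [0, 1]")
  w <- cfg$evoked_onset_window_ms
  if (length(w) != 2L || w[1] < 0 || w[2] >= 100 || w[1] > w[2])
    .stopf("evoked_onset_window_ms must lie within [0, 100)")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic stimulation-session configuration\n")
  cat(sprintf("  %d electrodes x %d currents (%s uA), %d trials/block, %.0f%% stimulated\n",
              x$n_electrodes, length(x$currents_uA),
              paste(x$currents_uA, collapse = "/"),
              x$trials_per_block, 100 * x$stim_fraction))
  cat(sprintf("  %g Hz, fixation %g ms, jump +/-%g deg, gaze noise sd %g deg\n",
              x$sample_rate, x$fixation_ms, x$jump_amplitude_deg, x$noise_sd_deg))
  cat(sprintf("  latency contra ~ exGauss(%g, %g, %g), ipsi ~ exGauss(%g, %g, %g) ms\n",
              x$latency_model$contra[["mu"]], x$latency_model$contra[["sigma"]],
              x$latency_model$contra[["tau"]], x$latency_model$ipsi[["mu"]],
              x$latency_model$ipsi[["sigma"]], x$latency_model$ipsi[["tau"]]))
  cat(sprintf("  %d saccade-evoking electrode/current entries, seed %d\n",
              if (is.null(x$evoking_electrodes)) 0L else nrow(x$evoking_electrodes),
              x$seed))
  invisible(x)
}

#' Read / write a simulation configuration as YAML
#'
#' Serializes every scalar field plus the effect map and evoking-electrode
#' tables so a configuration round-trips exactly.
#'
#' @param cfg a `sim_config`.
#' @param path YAML file path.
#' @return `write_sim_config` returns `path` invisibly;
#'   `read_sim_config` returns a validated `sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$effect_map <- as.list(cfg$effect_map)
  x$evoking_electrodes <- if (is.null(cfg$evoking_electrodes)) NULL
    else as.list(cfg$evoking_electrodes)
  x$electrode_map <- NULL  # derived from n_electrodes + broken_electrodes
  x$latency_model <- lapply(cfg$latency_model, as.list)
  x$main_sequence <- as.list(cfg$main_sequence)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  lat <- lapply(x$latency_model, function(v) unlist(v))
  em <- if (is.null(x$effect_map)) NULL else
    as.data.frame(x$effect_map, stringsAsFactors = FALSE)
  ev <- if (is.null(x$evoking_electrodes)) NULL else
    as.data.frame(x$evoking_electrodes, stringsAsFactors = FALSE)
  sim_config(
    sample_rate = x$sample_rate, fixation_ms = x$fixation_ms,
    jump_amplitude_deg = x$jump_amplitude_deg,
    fixation_radius_deg = x$fixation_radius_deg,
    n_electrodes = x$n_electrodes, trials_per_block = x$trials_per_block,
    stim_fraction = x$stim_fraction, currents_uA = unlist(x$currents_uA),
    latency_model = lat,
    baseline_contra_advantage_ms = x$baseline_contra_advantage_ms,
    effect_map = em, evoking_electrodes = ev,
    noise_sd_deg = x$noise_sd_deg, endpoint_sd_deg = x$endpoint_sd_deg,
    main_sequence = unlist(x$main_sequence),
    evoked_onset_window_ms = unlist(x$evoked_onset_window_ms),
    post_saccade_ms = x$post_saccade_ms,
    broken_electrodes = if (is.null(x$broken_electrodes)) integer(0)
      else unlist(x$broken_electrodes),
    blink_rate = x$blink_rate, blink_ms = x$blink_ms, seed = x$seed)
}
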