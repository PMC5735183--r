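# Saccade taxonomy (evoked / task / other), inclusion and exclusion rules,
# and evoked-saccade endpoint summaries.

#' Classify one saccade as evoked, task-related, or other
#'
#' A saccade is *evoked* by the stimulation if it is initiated within
#' 100 ms of stimulation onset (latency in `[0, 100)` ms) and lasts no
#' longer than 75 ms (duration `<= 75`). It is *task-related* if initiated
#' between 100 and 400 ms after the fixation-point jump (latency in
#' `[100, 400]`) with duration `< 75` ms. Everything else is *other*. The
#' two windows share the 100 ms boundary; the evoked window is taken
#' right-open and the task window left-closed so the classes are disjoint.
#' Stimulation is delivered concurrently with the jump, so one reference
#' time serves both definitions.
#'
#' @param latency_ms saccade onset minus the stimulation/jump onset, ms.
#' @param duration_ms saccade duration, ms.
#' @return character vector over `{"evoked", "task", "other"}`
#'   (vectorized; a total function of its inputs).
#' @examples
#' classify_saccade(50, 40)   # "evoked"
#' classify_saccade(150, 40)  # "task"
#' classify_saccade(90, 80)   # "other"
#' @export
classify_saccade <- function(latency_ms, duration_ms) {
  if (length(latency_ms) != length(duration_ms))
    .stopf("latency and duration must have equal length")
  out <- rep("other", length(latency_ms))
  out[latency_ms >= 0 & latency_ms < 100 & duration_ms <= 75] <- "evoked"
  out[latency_ms >= 100 & latency_ms <= 400 & duration_ms < 75] <- "task"
  out
}

#' Evoked-saccade inclusion criterion for an electrode
#'
#' An electrode counts as saccade-evoking when saccades were evoked on at
#' least 3 of 10 stimulation trials; generalized as an evoked proportion
#' >= 0.3 with at least 10 stimulation trials, which reduces exactly to
#' "3 out of 10" at the standard block size.
#'
#' @param n_evoked number of stimulation trials with an evoked saccade.
#' @param n_stim_trials number of stimulation trials (>= 1).
#' @return logical.
#' @examples
#' evoked_inclusion(3, 10)  # TRUE
#' evoked_inclusion(2, 10)  # FALSE
#' @export
evoked_inclusion <- function(n_evoked, n_stim_trials) {
  if (any(n_stim_trials < 1)) .stopf("n_stim_trials must be >= 1")
  if (any(n_evoked < 0) || any(n_evoked > n_stim_trials))
    .stopf("n_evoked must lie in [0, n_stim_trials]")
  n_stim_trials >= 10 & (n_evoked / n_stim_trials) >= 0.3
}

#' Bivariate-normal confidence ellipse of saccade endpoints
#'
#' Fits a bivariate normal to 2-D points and returns the `level` confidence
#' ellipse: center at the sample mean, axes along the eigenvectors of the
#' sample covariance, semi-axis lengths `sqrt(chi2_2(level) * eigenvalue)`.
#'
#' @param points_xy n x 2 matrix (or data.frame) of endpoints in degrees;
#'   at least 3 non-collinear points.
#' @param level confidence level (default 0.95).
#' @return list with `center` (length 2), `semi_axes_deg` (major, minor),
#'   `orientation_deg` (major-axis angle in `[0, 180)`), `level`, `n`.
#' @export
endpoint_ellipse <- function(points_xy, level = 0.95) {
  m <- as.matrix(points_xy)
  if (ncol(m) != 2L) .stopf("points must be n x 2")
  m <- m[complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3L) .stopf("need at least 3 points for an ellipse")
  if (level <= 0 || level >= 1) .stopf("level must be in (0, 1)")
  ctr <- colMeans(m)
  S <- stats::cov(m)
  ev <- eigen(S, symmetric = TRUE)
  if (min(ev$values) < 1e-12 * max(ev$values, 1e-300))
    .stopf("degenerate input: points are (near-)collinear, covariance singular")
  q <- qchisq(level, df = 2)
  semi <- sqrt(q * ev$values)
  ang <- .rad2deg(atan2(ev$vectors[2, 1], ev$vectors[1, 1])) %% 180
  list(center = unname(ctr), semi_axes_deg = semi, orientation_deg = ang,
       level = level, n = nrow(m))
}

#' Label all detected saccades of a session
#'
#' Joins the saccade table with the trial table and applies
#' [classify_saccade()] relative to each trial's jump (= stimulation)
#' onset; also flags, per trial, the first task-classified saccade, which
#' is the one entering latency analyses.
#'
#' @param saccades output of [detect_session()].
#' @param trials trial metadata table.
#' @return `saccades` with added columns `label` and `first_task`.
#' @export
classify_saccades <- function(saccades, trials) {
  .require_cols(saccades, c("trial_id", "latency_ms", "duration_ms"),
                "saccades")
  .require_cols(trials, c("trial_id"), "trials")
  if (!all(saccades$trial_id %in% trials$trial_id))
    .stopf("saccades reference trial ids missing from the trial table")
  saccades$label <- classify_saccade(saccades$latency_ms,
                                     saccades$duration_ms)
  saccades$first_task <- FALSE
  is_task <- saccades$label == "task"
  if (any(is_task)) {
    task <- saccades[is_task, ]
    ord <- order(task$trial_id, task$onset_ms)
    first_idx <- which(is_task)[ord][!duplicated(task$trial_id[ord])]
    saccades$first_task[first_idx] <- TRUE
  }
  saccades
}

#' Per-electrode evoked-saccade summary
#'
#' Counts, per electrode x current, the stimulation trials on which at
#' least one evoked-classified saccade occurred; applies
#' [evoked_inclusion()]; and summarizes evoked-saccade vectors (circular
#' mean direction, mean amplitude) and endpoints (95% confidence ellipse,
#' when estimable). Only the first evoked saccade of each trial is counted.
#'
#' @param saccades labelled saccade table from [classify_saccades()].
#' @param trials trial metadata table.
#' @return data.frame with one row per electrode x current:
#'   `electrode_id`, `current_uA`, `n_stim_trials`, `n_evoked`, `included`,
#'   `mean_direction_deg`, `resultant_length`, `mean_amplitude_deg`, and
#'   ellipse columns (`ellipse_x`, `ellipse_y`, `ellipse_major_deg`,
#'   `ellipse_minor_deg`, `ellipse_orientation_deg`, `NA` when fewer than
#'   3 usable endpoints).
#' @export
summarize_evoked <- function(saccades, trials) {
  .require_cols(trials, c("trial_id", "stim", "electrode_id",
                          "current_uA"), "trials")
  stim_trials <- trials[trials$stim == 1L, ]
  if (nrow(stim_trials) == 0L)
    return(data.frame(electrode_id = integer(0), current_uA = numeric(0),
                      n_stim_trials = integer(0), n_evoked = integer(0),
                      included = logical(0)))
  ev <- saccades[saccades$label == "evoked" &
                 saccades$trial_id %in% stim_trials$trial_id, ]
  # first evoked saccade per trial
  if (nrow(ev)) {
    ev <- ev[order(ev$trial_id, ev$onset_ms), ]
    ev <- ev[!duplicated(ev$trial_id), ]
    ev <- merge(ev, stim_trials[c("trial_id", "electrode_id", "current_uA")],
                by = "trial_id")
  }
  cells <- unique(stim_trials[c("electrode_id", "current_uA")])
  cells <- cells[order(cells$electrode_id, cells$current_uA), ]
  out <- lapply(seq_len(nrow(cells)), function(i) {
    el <- cells$electrode_id[i]; cur <- cells$current_uA[i]
    n_stim <- sum(stim_trials$electrode_id == el &
                  stim_trials$current_uA == cur)
    sub <- if (nrow(ev)) ev[ev$electrode_id == el & ev$current_uA == cur, ]
      else ev
    n_ev <- if (is.null(nrow(sub))) 0L else nrow(sub)
    row <- data.frame(electrode_id = el, current_uA = cur,
                      n_stim_trials = n_stim, n_evoked = n_ev,
                      included = evoked_inclusion(n_ev, max(n_stim, 1L)) &
                        n_stim >= 1L,
                      mean_direction_deg = NA_real_,
                      resultant_length = NA_real_,
                      mean_amplitude_deg = NA_real_,
                      ellipse_x = NA_real_, ellipse_y = NA_real_,
                      ellipse_major_deg = NA_real_,
                      ellipse_minor_deg = NA_real_,
                      ellipse_orientation_deg = NA_real_)
    if (n_ev > 0L) {
      cd <- circ_descriptives(sub$direction_deg)
      row$mean_direction_deg <- cd$mean_direction_deg
      row$resultant_length <- cd$resultant_length
      row$mean_amplitude_deg <- mean(sub$amplitude_deg)
      if (n_ev >= 3L) {
        ell <- tryCatch(endpoint_ellipse(cbind(sub$end_x, sub$end_y)),
                        error = function(e) NULL)
        if (!is.null(ell)) {
          row$ellipse_x <- ell$center[1]; row$ellipse_y <- ell$center[2]
          row$ellipse_major_deg <- ell$semi_axes_deg[1]
          row$ellipse_minor_deg <- ell$semi_axes_deg[2]
          row$ellipse_orientation_deg <- ell$orientation_deg
        }
      }
    }
    row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Electrodes excluded from behavioral analyses
#'
#' Excludes (i) electrodes that evoke saccades at the highest stimulation
#' current (their stimulation trials are contaminated by the evoked
#' movement) and (ii) electrodes whose status is not `"ok"` (disconnected
#' or broken). Used by all latency, spatial and kinematics analyses.
#'
#' @param evoked_summaries output of [summarize_evoked()].
#' @param electrode_map electrode map table.
#' @return data.frame `electrode_id`, `reason`
#'   (`"evokes-saccades"`/`"broken"`); zero rows when nothing is excluded.
#' @export
flag_excluded_electrodes <- function(evoked_summaries, electrode_map) {
  .require_cols(electrode_map, c("electrode_id", "status"), "electrodes")
  out <- data.frame(electrode_id = integer(0), reason = character(0),
                    stringsAsFactors = FALSE)
  if (nrow(evoked_summaries)) {
    hi <- max(evoked_summaries$current_uA)
    evokers <- evoked_summaries$electrode_id[
      evoked_summaries$current_uA == hi & evoked_summaries$included]
    if (length(evokers))
      out <- rbind(out, data.frame(electrode_id = sort(unique(evokers)),
                                   reason = "evokes-saccades",
                                   stringsAsFactors = FALSE))
  }
  broken <- electrode_map$electrode_id[electrode_map$status != "ok"]
  broken <- setdiff(broken, out$electrode_id)
  if (length(broken))
    out <- rbind(out, data.frame(electrode_id = sort(broken),
                                 reason = "broken", stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}
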