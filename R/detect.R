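# Velocity-threshold saccade detection and per-saccade kinematics.

# Accept either a data.frame or a matrix with t_ms/x_deg/y_deg columns.
.trace_parts <- function(trace) {
  if (is.matrix(trace)) {
    list(t = trace[, "t_ms"], x = trace[, "x_deg"], y = trace[, "y_deg"])
  } else {
    .require_cols(trace, c("t_ms", "x_deg", "y_deg"), "trace")
    list(t = trace$t_ms, x = trace$x_deg, y = trace$y_deg)
  }
}

# Raw and boxcar-smoothed speed in one pass (vector in, vectors out);
# shared by compute_speed() and the session-level detection loop.
.speed_core <- function(x, y, dt_ms, w) {
  n <- length(x)
  dt_s <- dt_ms / 1000
  vx <- numeric(n); vy <- numeric(n)
  vx[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt_s)
  vy[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (2 * dt_s)
  vx[1] <- (x[2] - x[1]) / dt_s; vy[1] <- (y[2] - y[1]) / dt_s
  vx[n] <- (x[n] - x[n - 1]) / dt_s; vy[n] <- (y[n] - y[n - 1]) / dt_s
  raw <- sqrt(vx^2 + vy^2)
  smoothed <- raw
  if (w > 1L && n >= w) {
    half <- w %/% 2L
    nas <- is.na(raw)
    s0 <- if (any(nas)) ifelse(nas, 0, raw) else raw
    cs <- cumsum(s0)
    cn <- if (any(nas)) cumsum(!nas) else seq_len(n)
    idx <- seq_len(n)
    lo <- pmax(idx - half, 1L); hi <- pmin(idx + half, n)
    tot <- cs[hi] - c(0, cs)[lo]
    cnt <- cn[hi] - c(0, cn)[lo]
    sm <- tot / cnt
    sm[cnt == 0] <- NA_real_
    sm[nas] <- NA_real_
    smoothed <- sm
  }
  list(raw = raw, smoothed = smoothed)
}

# Suprathreshold-run extraction on a speed series: merge short gaps, drop
# short or missing-contaminated runs. Returns integer start/end sample
# indices of kept runs (and of excluded ones, with reasons).
.runs_core <- function(smoothed, missing, dt, v_threshold,
                       merge_gap_ms, min_duration_ms) {
  n <- length(smoothed)
  above <- !missing & !is.na(smoothed) & smoothed > v_threshold
  if (!any(above))
    return(list(start = integer(0), end = integer(0),
                ex_start = integer(0), ex_end = integer(0),
                ex_reason = character(0)))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  rs <- starts[r$values]; re <- ends[r$values]
  if (length(rs) > 1L) {
    ks <- rs[1]; ke <- re[1]; ms <- integer(0); me <- integer(0)
    for (i in 2:length(rs)) {
      gap <- rs[i] - ke[length(ke)] - 1L
      gap_has_na <- gap > 0L && any(missing[(ke[length(ke)] + 1L):(rs[i] - 1L)])
      if (gap * dt < merge_gap_ms && !gap_has_na) {
        ke[length(ke)] <- re[i]
      } else {
        ks <- c(ks, rs[i]); ke <- c(ke, re[i])
      }
    }
    rs <- ks; re <- ke
  }
  dur_ok <- (re - rs + 1L) * dt >= min_duration_ms
  touch_na <- vapply(seq_along(rs), function(i)
    any(missing[max(1L, rs[i] - 1L):min(n, re[i] + 1L)]), logical(1))
  keep <- dur_ok & !touch_na
  list(start = rs[keep], end = re[keep],
       ex_start = rs[!keep], ex_end = re[!keep],
       ex_reason = ifelse(touch_na[!keep], "touches-missing-samples",
                          "below-min-duration"))
}

#' Gaze speed from an eye-position trace
#'
#' Differentiates x and y by central differences (one-sided at the
#' endpoints), takes the Euclidean norm and optionally applies a centered
#' boxcar smoother (windows shrink at the trace edges). The default
#' 15-sample window corresponds to 30 ms at 500 Hz; a window wide relative
#' to the ~6 ms a 7-degree saccade needs to exceed 100 deg/s pulls the
#' detected threshold crossing towards the kinematic onset (and
#' symmetrically extends the offset), making onset timing and amplitude
#' nearly unbiased, at the cost of a low-biased *smoothed* peak speed --
#' which is why peak velocity is measured on the unsmoothed series. Samples
#' whose differentiation stencil touches a missing (NaN) sample yield `NA`
#' speed.
#'
#' @param trace eye trace (data.frame or matrix with `t_ms`, `x_deg`,
#'   `y_deg`); at least 3 samples, uniformly spaced.
#' @param smooth_window_samples odd window length in samples; 1 disables
#'   smoothing.
#' @return numeric speed series in deg/s, same length as the trace, with
#'   attribute `dt_ms`.
#' @export
compute_speed <- function(trace, smooth_window_samples = 15L) {
  p <- .trace_parts(trace)
  n <- length(p$t)
  if (n < 3L) .stopf("trace must have at least 3 samples")
  dt_ms <- p$t[2] - p$t[1]
  if (dt_ms <= 0 || any(abs(diff(p$t) - dt_ms) > 1e-6))
    .stopf("trace time stamps must be strictly increasing and uniform")
  w <- as.integer(smooth_window_samples)
  if (w < 1L || w %% 2L == 0L)
    .stopf("smooth_window_samples must be a positive odd integer")
  speed <- .speed_core(p$x, p$y, dt_ms, w)$smoothed
  attr(speed, "dt_ms") <- dt_ms
  speed
}

#' Detect saccades by velocity thresholding
#'
#' Finds maximal runs of samples whose (smoothed) speed exceeds
#' `v_threshold`; runs separated by less than `merge_gap_ms` are merged and
#' merged runs shorter than `min_duration_ms` are discarded. Onset is the
#' time of the first suprathreshold sample, offset the time of the last
#' suprathreshold sample plus one step. Candidate runs containing or
#' touching missing (NaN) samples are excluded and logged, not
#' interpolated.
#'
#' @param trace eye trace, see [compute_speed()].
#' @param v_threshold speed criterion in deg/s (default 100).
#' @param smooth_window_samples see [compute_speed()].
#' @param merge_gap_ms sub-threshold gaps shorter than this are merged.
#' @param min_duration_ms minimal event duration retained.
#' @return data.frame with columns `onset_ms`, `offset_ms` (time-ordered,
#'   non-overlapping); attribute `excluded` is a data.frame of dropped
#'   candidate runs with a `reason` string.
#' @export
detect_saccades <- function(trace, v_threshold = 100,
                            smooth_window_samples = 15L,
                            merge_gap_ms = 10, min_duration_ms = 6) {
  if (v_threshold <= 0) .stopf("v_threshold must be positive")
  p <- .trace_parts(trace)
  speed <- compute_speed(trace, smooth_window_samples)
  dt <- attr(speed, "dt_ms")
  n <- length(speed)
  # missingness propagated through the differentiation stencil: a run is
  # considered to touch a gap when adjacent to any NA-speed sample
  missing <- is.na(p$x) | is.na(p$y) | is.na(speed)
  runs <- .runs_core(speed, missing, dt, v_threshold, merge_gap_ms,
                     min_duration_ms)
  out <- data.frame(onset_ms = p$t[runs$start],
                    offset_ms = pmin(p$t[runs$end] + dt, p$t[n]))
  attr(out, "excluded") <- data.frame(
    onset_ms = p$t[runs$ex_start],
    offset_ms = pmin(p$t[runs$ex_end] + dt, p$t[n]),
    reason = runs$ex_reason, stringsAsFactors = FALSE)
  out
}

#' Kinematic metrics for one detected saccade
#'
#' @param trace eye trace, see [compute_speed()].
#' @param interval one row of [detect_saccades()] output (or a list with
#'   `onset_ms`, `offset_ms`).
#' @param jump_time_ms time of the fixation-point jump (and stimulation
#'   onset, when delivered); latency is `onset - jump_time` and may be
#'   negative for saccades preceding the jump.
#' @param target_xy length-2 target position in degrees (for the endpoint
#'   error); `NULL` yields `NA` endpoint error.
#' @return one-row data.frame (a saccade event): `onset_ms`, `offset_ms`,
#'   `latency_ms`, `duration_ms`, `start_x`, `start_y`, `end_x`, `end_y`,
#'   `amplitude_deg`, `direction_deg` (0 = rightward/contraversive, CCW
#'   positive, in `[0, 360)`), `peak_velocity_deg_s` (unsmoothed
#'   central-difference speed within the interval), `endpoint_error_deg`.
#' @export
saccade_metrics <- function(trace, interval, jump_time_ms = 0,
                            target_xy = NULL) {
  p <- .trace_parts(trace)
  onset <- interval$onset_ms; offset <- interval$offset_ms
  if (length(onset) != 1L || length(offset) != 1L || offset <= onset)
    .stopf("degenerate interval: need offset_ms > onset_ms")
  dt <- p$t[2] - p$t[1]
  i0 <- which.min(abs(p$t - onset)); i1 <- which.min(abs(p$t - offset))
  i1 <- min(i1, length(p$t))
  start_xy <- c(p$x[i0], p$y[i0]); end_xy <- c(p$x[i1], p$y[i1])
  delta <- end_xy - start_xy
  amplitude <- sqrt(sum(delta^2))
  direction <- .wrap360(.rad2deg(atan2(delta[2], delta[1])))
  raw_speed <- compute_speed(trace, smooth_window_samples = 1L)
  pv <- max(raw_speed[i0:i1], na.rm = TRUE)
  err <- if (is.null(target_xy)) NA_real_ else
    sqrt(sum((end_xy - target_xy)^2))
  data.frame(onset_ms = onset, offset_ms = offset,
             latency_ms = onset - jump_time_ms,
             duration_ms = offset - onset,
             start_x = start_xy[1], start_y = start_xy[2],
             end_x = end_xy[1], end_y = end_xy[2],
             amplitude_deg = amplitude, direction_deg = direction,
             peak_velocity_deg_s = pv, endpoint_error_deg = err)
}

#' Detect and measure all saccades of a session
#'
#' Applies [detect_saccades()] and [saccade_metrics()] to every trial of a
#' session; the target position for the endpoint error is the jumped
#' fixation point of that trial.
#'
#' @param session a `stim_session` (simulated or read from CSV).
#' @param v_threshold,smooth_window_samples,merge_gap_ms,min_duration_ms
#'   detection parameters, see [detect_saccades()].
#' @return data.frame with one row per detected saccade: `trial_id` plus
#'   all [saccade_metrics()] columns.
#' @export
detect_session <- function(session, v_threshold = 100,
                           smooth_window_samples = 15L,
                           merge_gap_ms = 10, min_duration_ms = 6) {
  stopifnot(inherits(session, "stim_session"))
  trials <- session$trials
  amp <- if (!is.null(session$config)) session$config$jump_amplitude_deg else 7
  w <- as.integer(smooth_window_samples)
  if (w < 1L || w %% 2L == 0L)
    .stopf("smooth_window_samples must be a positive odd integer")
  n_tr <- nrow(trials)
  acc <- vector("list", n_tr)
  for (i in seq_len(n_tr)) {
    tr <- session$traces[[as.character(trials$trial_id[i])]]
    p <- .trace_parts(tr)
    n <- length(p$t)
    if (n < 3L) next
    dt <- p$t[2] - p$t[1]
    sp <- .speed_core(p$x, p$y, dt, w)
    miss <- is.na(p$x) | is.na(p$y) | is.na(sp$smoothed)
    runs <- .runs_core(sp$smoothed, miss, dt, v_threshold, merge_gap_ms,
                       min_duration_ms)
    k <- length(runs$start)
    if (k == 0L) next
    i1 <- pmin(runs$end + 1L, n)
    sx <- p$x[runs$start]; sy <- p$y[runs$start]
    ex <- p$x[i1]; ey <- p$y[i1]
    dx <- ex - sx; dy <- ey - sy
    tx <- if (trials$jump_dir[i] == "contra") amp else -amp
    pv <- vapply(seq_len(k), function(j)
      max(sp$raw[runs$start[j]:i1[j]], na.rm = TRUE), numeric(1))
    onset <- p$t[runs$start]
    offset <- pmin(p$t[runs$end] + dt, p$t[n])
    acc[[i]] <- list(
      trial_id = rep(trials$trial_id[i], k), onset_ms = onset,
      offset_ms = offset,
      latency_ms = onset - trials$jump_time_ms[i],
      duration_ms = offset - onset,
      start_x = sx, start_y = sy, end_x = ex, end_y = ey,
      amplitude_deg = sqrt(dx^2 + dy^2),
      direction_deg = .wrap360(.rad2deg(atan2(dy, dx))),
      peak_velocity_deg_s = pv,
      endpoint_error_deg = sqrt((ex - tx)^2 + ey^2))
  }
  acc <- acc[!vapply(acc, is.null, logical(1))]
  cols <- c("trial_id", "onset_ms", "offset_ms", "latency_ms", "duration_ms",
            "start_x", "start_y", "end_x", "end_y", "amplitude_deg",
            "direction_deg", "peak_velocity_deg_s", "endpoint_error_deg")
  res <- as.data.frame(lapply(setNames(cols, cols), function(cn)
    if (length(acc)) unlist(lapply(acc, `[[`, cn), use.names = FALSE)
    else if (cn == "trial_id") integer(0) else numeric(0)))
  res
}
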