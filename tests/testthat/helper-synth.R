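# Shared fixtures: small configurations built in code.

# 8-electrode session config (320 trials): fast enough for unit tests
# while keeping the full block/current/direction structure.
small_config <- function(...) {
  sim_config(n_electrodes = 8L, ...)
}

# configuration with no stimulation effects at all: no latency shifts,
# no saccade-evoking electrodes
null_config <- function(n_electrodes = 8L, ...) {
  em <- default_effect_map()
  em$shift_ms <- 0
  sim_config(n_electrodes = n_electrodes, effect_map = em,
             evoking_electrodes = NULL, ...)
}

# single clean synthetic trace: fixation at origin, one saccade to `end`
# at `onset_ms`, optional noise, length `total_ms`
one_saccade_trace <- function(end = c(7, 0), onset_ms = 150,
                              total_ms = 500, sample_rate = 500,
                              noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  seg <- synth_saccade_segment(c(0, 0), end, onset_ms,
                               sample_rate = sample_rate)
  t <- seq(0, total_ms, by = 1000 / sample_rate)
  x <- numeric(length(t)); y <- numeric(length(t))
  after <- t >= onset_ms
  x[after] <- stats::approx(seg$t_ms, seg$x_deg, xout = t[after], rule = 2)$y
  y[after] <- stats::approx(seg$t_ms, seg$y_deg, xout = t[after], rule = 2)$y
  if (noise_sd > 0) {
    x <- x + rnorm(length(t), 0, noise_sd)
    y <- y + rnorm(length(t), 0, noise_sd)
  }
  data.frame(t_ms = t, x_deg = x, y_deg = y)
}
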