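# Harrison-Kanji two-factor ANOVA for circular data.

# Maximum-likelihood approximation to the von Mises concentration kappa
# from a mean resultant length r (Fisher 1993 piecewise approximation).
est_kappa <- function(r) {
  if (r < 0) r <- 0
  if (r >= 1) return(Inf)
  if (r < 0.53) {
    2 * r + r^3 + 5 * r^5 / 6
  } else if (r < 0.85) {
    -0.4 + 1.39 * r + 0.43 / (1 - r)
  } else {
    1 / (r^3 - 4 * r^2 + 3 * r)
  }
}

# Core Harrison-Kanji decomposition. Returns the per-term statistics for a
# given response/factor layout; used both for the observed data and inside
# the permutation loop, so it must stay allocation-light.
.hk_core <- function(th, ia, ib, a, b, with_inter) {
  n <- length(th)
  co <- cos(th); si <- sin(th)
  # resultant lengths: total, per level of A, per level of B, per cell
  tr2 <- sum(co)^2 + sum(si)^2
  pa_c <- rowsum(co, ia, reorder = TRUE); pa_s <- rowsum(si, ia, reorder = TRUE)
  pb_c <- rowsum(co, ib, reorder = TRUE); pb_s <- rowsum(si, ib, reorder = TRUE)
  na_ <- tabulate(ia, a); nb_ <- tabulate(ib, b)
  pr2 <- pa_c^2 + pa_s^2   # squared resultants per A level
  qr2 <- pb_c^2 + pb_s^2
  eff_a <- sum(pr2 / na_) - tr2 / n
  eff_b <- sum(qr2 / nb_) - tr2 / n
  eff_t <- n - tr2 / n
  if (with_inter) {
    cell <- (ia - 1L) * b + ib
    cc <- rowsum(co, cell, reorder = TRUE); cs <- rowsum(si, cell, reorder = TRUE)
    ncell <- tabulate(cell, a * b)
    nz <- ncell > 0L
    cell_term <- sum((cc^2 + cs^2) / ncell[nz])
    eff_r <- n - cell_term
    eff_i <- eff_t - eff_r - (eff_a + eff_b)
  } else {
    eff_r <- eff_t - (eff_a + eff_b)
    eff_i <- NA_real_
  }
  r_bar <- sqrt(tr2) / n
  list(eff_a = eff_a, eff_b = eff_b, eff_i = eff_i, eff_r = eff_r,
       r_bar = r_bar)
}

#' Two-way ANOVA for circular data (Harrison-Kanji)
#'
#' Decomposes the variation of a circular response (saccade direction) into
#' two factor effects and their interaction following the Harrison-Kanji
#' two-factor scheme, as used for evoked-saccade direction ~ electrode x
#' current analyses. The overall concentration kappa is estimated from the
#' grand mean resultant length; for high concentration (kappa > 2) the
#' method's F approximation with the 1 + 3/(8 kappa) correction applies,
#' otherwise a chi-squared approximation is used and the result is flagged
#' unreliable. A permutation companion p-value (shuffling responses across
#' cells, seeded) is computed alongside so downstream decisions need not
#' rely on the asymptotic regime.
#'
#' @param angles_deg circular response in degrees.
#' @param factor_a,factor_b explanatory factors (coerced to factor).
#' @param interaction logical; include the interaction term (requires all
#'   cells of the a x b design non-empty).
#' @param n_perm number of permutations for the companion p-values
#'   (0 disables; default 9999).
#' @param seed integer seed for the permutation draw.
#' @return object of class `circ_anova`: data.frame `table` with rows
#'   `factor_a`, `factor_b`, `interaction` (statistic, df, p_value,
#'   p_perm), plus `kappa_hat`, `regime` ("F" or "chisq"),
#'   `low_kappa_warning`, `n`, `n_cells`.
#' @export
hk_circ_anova <- function(angles_deg, factor_a, factor_b,
                          interaction = TRUE, n_perm = 9999, seed = 1L) {
  fa <- factor(factor_a); fb <- factor(factor_b)
  n <- length(angles_deg)
  if (length(fa) != n || length(fb) != n)
    .stopf("angles and factors must have equal length")
  if (anyNA(angles_deg) || anyNA(fa) || anyNA(fb))
    .stopf("missing values not supported")
  a <- nlevels(fa); b <- nlevels(fb)
  if (a < 2L) .stopf("factor_a must have at least 2 levels")
  .assert_flag(interaction, "interaction")
  ia <- as.integer(fa); ib <- as.integer(fb)
  # single-level factor B collapses its term (df 0) rather than failing
  with_inter <- interaction && b >= 2L
  cell_n <- table(fa, fb)
  if (with_inter && any(cell_n == 0L))
    .stopf("interaction requires all %d x %d cells non-empty", a, b)
  if (any(cell_n > 0L & cell_n < 2L))
    .stopf("every non-empty cell needs >= 2 observations")

  th <- .deg2rad(angles_deg)
  obs <- .hk_core(th, ia, ib, a, b, with_inter)
  kappa_hat <- est_kappa(obs$r_bar)
  low_kappa <- kappa_hat < 2
  if (low_kappa)
    warning("estimated concentration kappa < 2: asymptotic approximation ",
            "unreliable; prefer the permutation p-values", call. = FALSE)

  df_a <- a - 1L
  df_b <- if (b >= 2L) b - 1L else 0L
  df_i <- if (with_inter) (a - 1L) * (b - 1L) else 0L
  df_r <- if (with_inter) n - a * b else n - a - df_b

  stat_of <- function(eff, df_eff, core) {
    if (df_eff == 0L || is.na(eff)) return(NA_real_)
    if (!low_kappa) {
      (1 + 3 / (8 * kappa_hat)) * (eff / df_eff) / (core$eff_r / df_r)
    } else {
      # chi-squared regime: weighted resultant decomposition scaled by
      # the concentration-dependent factor 2 / (1 - rho^2), rho = A1(kappa)
      rho <- besselI(kappa_hat, 1) / besselI(kappa_hat, 0)
      2 / (1 - rho^2) * eff
    }
  }
  p_of <- function(stat, df_eff) {
    if (is.na(stat)) return(NA_real_)
    if (!low_kappa) pf(stat, df_eff, df_r, lower.tail = FALSE)
    else pchisq(stat, df_eff, lower.tail = FALSE)
  }

  stats_obs <- c(stat_of(obs$eff_a, df_a, obs),
                 stat_of(obs$eff_b, df_b, obs),
                 stat_of(if (with_inter) obs$eff_i else NA_real_, df_i, obs))
  ps <- c(p_of(stats_obs[1], df_a), p_of(stats_obs[2], df_b),
          p_of(stats_obs[3], df_i))

  p_perm <- rep(NA_real_, 3L)
  if (n_perm > 0L) {
    exceed <- c(0L, 0L, 0L)
    counted <- !is.na(stats_obs)
    old_seed <- .save_seed(); on.exit(.restore_seed(old_seed), add = TRUE)
    set.seed(seed)
    for (i in seq_len(n_perm)) {
      idx <- sample.int(n)
      perm <- .hk_core(th[idx], ia, ib, a, b, with_inter)
      st <- c(stat_of(perm$eff_a, df_a, perm),
              stat_of(perm$eff_b, df_b, perm),
              stat_of(if (with_inter) perm$eff_i else NA_real_, df_i, perm))
      exceed <- exceed + ifelse(counted & !is.na(st) & st >= stats_obs, 1L, 0L)
    }
    p_perm <- ifelse(counted, (1 + exceed) / (n_perm + 1), NA_real_)
  }

  tab <- data.frame(term = c("factor_a", "factor_b", "interaction"),
                    statistic = stats_obs,
                    df = c(df_a, df_b, df_i),
                    df_resid = if (!low_kappa) df_r else NA_real_,
                    p_value = ps, p_perm = p_perm,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, kappa_hat = kappa_hat,
                 regime = if (!low_kappa) "F" else "chisq",
                 low_kappa_warning = low_kappa, n = n,
                 n_cells = a * max(b, 1L), n_perm = n_perm),
            class = "circ_anova")
}

#' @export
print.circ_anova <- function(x, ...) {
  cat(sprintf("Harrison-Kanji circular two-way ANOVA (%s regime, kappa_hat = %.3g, n = %d)\n",
              x$regime, x$kappa_hat, x$n))
  print(x$table, row.names = FALSE)
  if (x$low_kappa_warning)
    cat("  note: kappa_hat < 2 - use permutation p-values\n")
  invisible(x)
}

# Save/restore the caller's RNG state around internally seeded loops.
.save_seed <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE) else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
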