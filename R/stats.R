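# Statistical procedures for latency, frequency and kinematics comparisons.

#' Reciprocal-latency (rate) transform
#'
#' Maps saccadic onset latencies in milliseconds to rates in 1/s,
#' `rate = 1000 / latency`. The reciprocal transform normalizes the
#' right-skewed distribution of saccadic reaction times towards Gaussian,
#' which is why latency comparisons in this package are run on rates by
#' default. The map is strictly order-reversing.
#'
#' @param latencies_ms numeric vector of positive latencies in ms.
#' @return numeric vector of rates in 1/s.
#' @examples
#' reciprocal_transform(c(200, 250)) # 5, 4
#' @export
reciprocal_transform <- function(latencies_ms) {
  if (length(latencies_ms) == 0L) return(numeric(0))
  if (!is.numeric(latencies_ms) || anyNA(latencies_ms))
    .stopf("latencies must be numeric and non-missing")
  if (any(latencies_ms <= 0))
    .stopf("latencies must be strictly positive (got min = %g)", min(latencies_ms))
  1000 / latencies_ms
}

#' Bonferroni-adjusted significance level
#'
#' @param alpha family-wise error rate.
#' @param n_tests number of tests in the family (>= 1).
#' @return `alpha / n_tests`.
#' @examples
#' bonferroni_alpha(0.05, 4) # 0.0125
#' @export
bonferroni_alpha <- function(alpha = 0.05, n_tests = 1L) {
  if (n_tests < 1) .stopf("n_tests must be >= 1")
  alpha / n_tests
}

#' Two-group latency comparison
#'
#' Two-sided comparison of two latency samples, optionally on
#' reciprocal-transformed values (the primary analysis scale) with the raw
#' millisecond effect always reported alongside. The parametric test is the
#' pooled-variance Student t-test (Welch available via `welch = TRUE`); the
#' non-parametric alternative is the Wilcoxon rank-sum / signed-rank test,
#' exact for small samples without ties and normal-approximated (with tie
#' correction) otherwise.
#'
#' @param group_a,group_b numeric latency vectors in ms (a = e.g. stimulated,
#'   b = control); for `paired = TRUE` they must have equal length.
#' @param method `"t"` or `"ranksum"`.
#' @param paired logical; paired-sample variant.
#' @param transform logical; test reciprocal-transformed latencies
#'   (requires strictly positive input).
#' @param welch logical; Welch (unpooled) t instead of Student pooled t.
#' @return object of class `stimsacc_test`: a list with `statistic`, `df`,
#'   `p_value`, `effect_estimate` (difference a - b on the tested scale),
#'   `mean_diff_ms`, `median_diff_ms` (always on the raw ms scale), `method`,
#'   `sidedness`, `n`, and `degenerate` flag (zero pooled variance).
#' @export
latency_test <- function(group_a, group_b,
                         method = c("t", "ranksum"),
                         paired = FALSE, transform = TRUE,
                         welch = FALSE) {
  method <- match.arg(method)
  .assert_flag(paired, "paired"); .assert_flag(transform, "transform")
  if (length(group_a) == 0L || length(group_b) == 0L)
    .stopf("both groups must be non-empty")
  if (paired && length(group_a) != length(group_b))
    .stopf("paired test requires equal group lengths (%d vs %d)",
           length(group_a), length(group_b))
  a <- as.numeric(group_a); b <- as.numeric(group_b)
  if (anyNA(a) || anyNA(b)) .stopf("latency groups must not contain NA")
  ta <- if (transform) reciprocal_transform(a) else a
  tb <- if (transform) reciprocal_transform(b) else b

  mean_diff_ms <- mean(a) - mean(b)
  median_diff_ms <- median(a) - median(b)

  degenerate <- FALSE
  if (method == "t") {
    if (paired) {
      d <- ta - tb
      if (length(d) < 2L || var(d) == 0) {
        degenerate <- TRUE
        statistic <- if (all(d == 0)) 0 else NaN
        df <- length(d) - 1
        p <- if (all(d == 0)) 1 else NA_real_
      } else {
        ht <- t.test(ta, tb, paired = TRUE)
        statistic <- unname(ht$statistic); df <- unname(ht$parameter)
        p <- ht$p.value
      }
    } else {
      pooled_var <- if (length(ta) + length(tb) > 2L)
        (sum((ta - mean(ta))^2) + sum((tb - mean(tb))^2)) /
          (length(ta) + length(tb) - 2L) else 0
      if (pooled_var == 0 && !welch) {
        degenerate <- TRUE
        statistic <- if (mean(ta) == mean(tb)) 0 else NaN
        df <- length(ta) + length(tb) - 2L
        p <- if (mean(ta) == mean(tb)) 1 else NA_real_
      } else {
        ht <- t.test(ta, tb, var.equal = !welch)
        statistic <- unname(ht$statistic); df <- unname(ht$parameter)
        p <- ht$p.value
      }
    }
    meth <- paste0(if (paired) "paired " else if (welch) "Welch " else "",
                   "t-test", if (transform) " (reciprocal)" else "")
  } else {
    n_max <- max(length(ta), length(tb))
    has_ties <- anyDuplicated(c(ta, tb)) > 0L
    exact <- n_max <= 25L && !has_ties
    ht <- suppressWarnings(
      wilcox.test(ta, tb, paired = paired, exact = exact, correct = TRUE))
    statistic <- unname(ht$statistic); df <- NA_real_; p <- ht$p.value
    meth <- paste0(if (paired) "Wilcoxon signed-rank" else "Wilcoxon rank-sum",
                   if (transform) " (reciprocal)" else "")
  }

  structure(list(
    statistic = statistic, df = df, p_value = p,
    effect_estimate = mean(ta) - mean(tb),
    mean_diff_ms = mean_diff_ms, median_diff_ms = median_diff_ms,
    method = meth, sidedness = "two-sided",
    n = c(a = length(a), b = length(b)), degenerate = degenerate),
    class = "stimsacc_test")
}

#' @export
print.stimsacc_test <- function(x, ...) {
  cat(sprintf("%s (%s): statistic = %.4g, df = %s, p = %.4g\n",
              x$method, x$sidedness, x$statistic,
              if (is.na(x$df[1])) "NA" else paste(signif(x$df, 4), collapse = ","),
              x$p_value))
  if (!is.null(x$mean_diff_ms))
    cat(sprintf("  mean diff = %.3f ms, median diff = %.3f ms (n = %s)\n",
                x$mean_diff_ms, x$median_diff_ms, paste(x$n, collapse = "/")))
  invisible(x)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact test by full hypergeometric enumeration over the support
#' with fixed margins: the p-value is the sum of the probabilities of all
#' tables no more probable than the observed one (with a small relative
#' slack to absorb floating-point noise in the comparison). The odds ratio
#' is the sample cross-product ratio `(a*d)/(b*c)`, reported as 0 or `Inf`
#' when a zero cell makes it degenerate.
#'
#' @param table_2x2 2x2 matrix of non-negative integer counts
#'   (rows = condition, columns = outcome).
#' @return `stimsacc_test` with `p_value`, `effect_estimate` (odds ratio).
#' @examples
#' fisher_exact(matrix(c(5, 5, 5, 5), 2)) # p = 1, OR = 1
#' @export
fisher_exact <- function(table_2x2) {
  m <- as.matrix(table_2x2)
  if (!all(dim(m) == c(2L, 2L))) .stopf("table must be 2x2")
  if (anyNA(m) || any(m < 0) || any(m != round(m)))
    .stopf("table cells must be non-negative integers")
  a <- m[1, 1]; b <- m[1, 2]; c_ <- m[2, 1]; d <- m[2, 2]
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    .stopf("all margins must be positive")
  mr1 <- a + b; mr2 <- c_ + d; mc1 <- a + c_
  support <- max(0, mc1 - mr2):min(mr1, mc1)
  probs <- dhyper(support, mr1, mr2, mc1)
  p_obs <- dhyper(a, mr1, mr2, mc1)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  or <- if (b * c_ == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c_)
  structure(list(
    statistic = a, df = NA_real_, p_value = p, effect_estimate = or,
    odds_ratio = or, method = "Fisher's exact test", sidedness = "two-sided",
    n = sum(m), degenerate = is.nan(or)), class = "stimsacc_test")
}

#' Circular descriptive statistics
#'
#' Mean direction and resultant length of a set of angles. The mean
#' direction is the angle of the vector sum of unit vectors; the resultant
#' length `R` in `[0, 1]` measures angular concentration (1 = all angles
#' identical, 0 = perfectly dispersed).
#'
#' @param angles_deg numeric vector of angles in degrees.
#' @return list with `mean_direction_deg` (in `[0, 360)`, `NA` and
#'   `undefined = TRUE` when R is numerically zero), `resultant_length`, `n`.
#' @examples
#' circ_descriptives(c(0, 90)) # mean 45, R = cos(45 deg)
#' @export
circ_descriptives <- function(angles_deg) {
  if (length(angles_deg) < 1L) .stopf("need at least one angle")
  th <- .deg2rad(angles_deg)
  cs <- sum(cos(th)); sn <- sum(sin(th))
  r <- sqrt(cs^2 + sn^2) / length(th)
  undefined <- r < 1e-12
  list(mean_direction_deg = if (undefined) NA_real_
       else .wrap360(.rad2deg(atan2(sn, cs))),
       resultant_length = r, n = length(th), undefined = undefined)
}

#' Two-way fixed-effects ANOVA with interaction
#'
#' Linear two-factor ANOVA used for evoked-saccade amplitudes
#' (amplitude ~ electrode x current). Sums of squares are Type II by
#' default, which coincides with the classical decomposition on balanced
#' designs and does not depend on factor order on unbalanced ones;
#' Type I/III are available for comparison.
#'
#' @param y numeric response.
#' @param factor_a,factor_b factors (coerced); `factor_a` is the first term.
#' @param ss_type 2 (default), 1 or 3.
#' @return data.frame with rows `factor_a`, `factor_b`, `interaction` and
#'   columns `term`, `F`, `df`, `df_resid`, `p`, plus attribute
#'   `constant_response` when y has zero variance (F undefined).
#' @export
twoway_linear_anova <- function(y, factor_a, factor_b, ss_type = 2) {
  if (!(ss_type %in% c(1, 2, 3))) .stopf("ss_type must be 1, 2 or 3")
  y <- as.numeric(y)
  fa <- factor(factor_a); fb <- factor(factor_b)
  if (length(y) != length(fa) || length(y) != length(fb))
    .stopf("y and factors must have equal length")
  if (anyNA(y) || anyNA(fa) || anyNA(fb)) .stopf("missing values not supported")
  a <- nlevels(fa); b <- nlevels(fb)
  constant <- var(y) == 0
  terms_out <- data.frame(term = c("factor_a", "factor_b", "interaction"),
                          F = NA_real_, df = c(a - 1L, b - 1L, (a - 1L) * (b - 1L)),
                          df_resid = NA_real_, p = NA_real_,
                          stringsAsFactors = FALSE)
  # single-level factors collapse their terms (df 0) instead of failing
  if (a < 2L && b < 2L) .stopf("at least one factor must have >= 2 levels")
  form <- if (a >= 2L && b >= 2L) y ~ fa * fb else if (a >= 2L) y ~ fa else y ~ fb
  dat <- data.frame(y = y, fa = fa, fb = fb)
  fit <- lm(form, data = dat)
  if (!constant) {
    if (ss_type == 1) {
      av <- anova(fit)
      tab <- av[setdiff(rownames(av), "Residuals"), , drop = FALSE]
      fs <- tab[["F value"]]; dfs <- tab[["Df"]]; ps <- tab[["Pr(>F)"]]
      rn <- rownames(tab)
      df_res <- av["Residuals", "Df"]
    } else {
      av <- car::Anova(fit, type = ss_type)
      rn <- rownames(av)
      keep <- !(rn %in% c("Residuals", "(Intercept)"))
      fs <- av[keep, "F value"]; dfs <- av[keep, "Df"]; ps <- av[keep, "Pr(>F)"]
      rn <- rn[keep]
      df_res <- av["Residuals", "Df"]
    }
    map <- c("fa" = "factor_a", "fb" = "factor_b", "fa:fb" = "interaction")
    for (i in seq_along(rn)) {
      row <- match(map[[rn[i]]], terms_out$term)
      terms_out$F[row] <- fs[i]
      terms_out$df[row] <- dfs[i]
      terms_out$p[row] <- ps[i]
      terms_out$df_resid[row] <- df_res
    }
  }
  attr(terms_out, "constant_response") <- constant
  terms_out
}
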