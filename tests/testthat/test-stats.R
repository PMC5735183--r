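test_that("reciprocal transform is exact and order-reversing", {
  expect_equal(reciprocal_transform(200), 5)
  expect_equal(reciprocal_transform(250), 4)
  x <- sort(runif(50, 80, 500))
  expect_equal(order(reciprocal_transform(x)), 50:1)
  expect_error(reciprocal_transform(c(200, 0)), "positive")
  expect_error(reciprocal_transform(c(200, -3)), "positive")
})

test_that("pooled t-test reproduces the hand-computed example", {
  # a = (1,2,3), b = (4,5,6): pooled variance 1, se = sqrt(2/3),
  # t = -3/sqrt(2/3) = -3.674, df = 4, p = 2 P(T4 < -3.674) = 0.0213
  r <- latency_test(c(1, 2, 3), c(4, 5, 6), method = "t", transform = FALSE)
  expect_equal(r$statistic, -3 / sqrt(2 / 3), tolerance = 1e-6)
  expect_equal(r$statistic, -3.674, tolerance = 1e-3)
  expect_equal(r$df, 4)
  expect_equal(r$p_value, 2 * stats::pt(-3 / sqrt(2 / 3), 4),
               tolerance = 1e-9)
  expect_equal(r$mean_diff_ms, -3)
})

test_that("degenerate and identical inputs are handled explicitly", {
  r <- latency_test(c(100, 200, 300), c(100, 200, 300), method = "t",
                    transform = FALSE)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  z <- latency_test(c(5, 5, 5), c(7, 7, 7), method = "t", transform = FALSE)
  expect_true(z$degenerate)
  expect_true(is.nan(z$statistic))

  expect_error(latency_test(1:3, 1:4, paired = TRUE), "equal group lengths")
  expect_error(latency_test(numeric(0), 1:3), "non-empty")
})

test_that("rank-sum branch matches the reference implementation", {
  set.seed(5)
  a <- rnorm(12, 200, 30); b <- rnorm(15, 230, 30)
  r <- latency_test(a, b, method = "ranksum", transform = FALSE)
  expect_equal(r$p_value, stats::wilcox.test(a, b, exact = TRUE)$p.value)
  a2 <- rnorm(60, 200, 30); b2 <- rnorm(80, 220, 30)
  r2 <- latency_test(a2, b2, method = "ranksum", transform = FALSE)
  expect_equal(r2$p_value,
               stats::wilcox.test(a2, b2, exact = FALSE,
                                  correct = TRUE)$p.value)
})

test_that("transform flag changes the tested scale but not the ms effects", {
  set.seed(9)
  a <- runif(40, 150, 300); b <- runif(40, 150, 300)
  rt <- latency_test(a, b, transform = TRUE)
  rr <- latency_test(a, b, transform = FALSE)
  expect_equal(rt$mean_diff_ms, rr$mean_diff_ms)
  expect_equal(rt$effect_estimate, mean(1000 / a) - mean(1000 / b))
  expect_equal(rr$effect_estimate, mean(a) - mean(b))
})

test_that("Fisher test equals full enumeration with the cross-product OR", {
  r <- fisher_exact(matrix(c(5, 5, 5, 5), 2, byrow = TRUE))
  expect_equal(r$p_value, 1)
  expect_equal(r$odds_ratio, 1)

  r2 <- fisher_exact(matrix(c(0, 5, 5, 0), 2, byrow = TRUE))
  expect_equal(r2$p_value, 2 / 252, tolerance = 1e-12)
  expect_equal(r2$odds_ratio, 0)

  # independent oracle: enumerate all tables with the observed margins,
  # probabilities from binomial coefficients, minimum-likelihood two-sided
  enum_oracle <- function(m) {
    a <- m[1, 1]; r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
    ks <- max(0, c1 - r2):min(r1, c1)
    pr <- vapply(ks, function(k)
      exp(lchoose(r1, k) + lchoose(r2, c1 - k) - lchoose(r1 + r2, c1)),
      numeric(1))
    sum(pr[pr <= pr[ks == a] * (1 + 1e-7)])
  }
  set.seed(11)
  for (i in 1:200) {
    repeat {
      m <- matrix(rpois(4, sample(1:8, 1)), 2)
      if (sum(m) <= 40 && all(rowSums(m) > 0) && all(colSums(m) > 0)) break
    }
    expect_equal(fisher_exact(m)$p_value, enum_oracle(m), tolerance = 1e-12)
    # cross-check against the reference implementation's p-value
    expect_equal(fisher_exact(m)$p_value, stats::fisher.test(m)$p.value,
                 tolerance = 1e-7)
  }
  expect_error(fisher_exact(matrix(c(1, 2, -1, 3), 2)), "non-negative")
  expect_error(fisher_exact(matrix(c(1.5, 2, 1, 3), 2)), "integer")
})

test_that("Bonferroni adjustment reproduces the published alphas", {
  expect_equal(bonferroni_alpha(0.05, 4), 0.0125)
  expect_equal(bonferroni_alpha(0.05, 8), 0.00625)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_error(bonferroni_alpha(0.05, 0), ">= 1")
})

test_that("circular descriptives: mean direction and resultant length", {
  r <- circ_descriptives(c(0, 90))
  expect_equal(r$mean_direction_deg, 45)
  expect_equal(r$resultant_length, cos(pi / 4), tolerance = 1e-12)

  r4 <- circ_descriptives(c(0, 90, 180, 270))
  expect_true(r4$undefined)
  expect_true(is.na(r4$mean_direction_deg))
  expect_equal(r4$resultant_length, 0, tolerance = 1e-12)

  r1 <- circ_descriptives(123)
  expect_equal(r1$mean_direction_deg, 123)
  expect_equal(r1$resultant_length, 1)
  # wrap-around: angles near 0/360 average to ~0, not ~180
  rw <- circ_descriptives(c(350, 10))
  expect_equal(rw$mean_direction_deg %% 360, 0, tolerance = 1e-9)
})

test_that("two-way ANOVA matches hand-computed sums of squares when balanced", {
  # 2 x 2 with n = 3 per cell; classical balanced decomposition by hand
  fa <- factor(rep(c("a1", "a2"), each = 6))
  fb <- factor(rep(rep(c("b1", "b2"), each = 3), 2))
  y <- c(10, 11, 12, 14, 15, 16, 20, 21, 22, 30, 31, 32)
  hand_ss <- function(y, fa, fb) {
    g <- mean(y)
    ma <- tapply(y, fa, mean); mb <- tapply(y, fb, mean)
    mc <- tapply(y, interaction(fa, fb), mean)
    ss_a <- 6 * sum((ma - g)^2)
    ss_b <- 6 * sum((mb - g)^2)
    cell_means <- ave(y, fa, fb)
    ss_cells <- sum((cell_means - g)^2)
    ss_int <- ss_cells - ss_a - ss_b
    ss_e <- sum((y - cell_means)^2)
    c(ss_a, ss_b, ss_int, ss_e)
  }
  ss <- hand_ss(y, fa, fb)
  f_hand <- (ss[1:3] / c(1, 1, 1)) / (ss[4] / 8)
  res <- twoway_linear_anova(y, fa, fb)
  expect_equal(res$F, f_hand, tolerance = 1e-10)
  expect_equal(res$df, c(1, 1, 1))
  expect_equal(res$df_resid, rep(8, 3))

  # location invariance and label symmetry
  res_shift <- twoway_linear_anova(y + 100, fa, fb)
  expect_equal(res_shift$F, res$F, tolerance = 1e-10)
  expect_equal(res_shift$p, res$p, tolerance = 1e-10)
  relabel <- factor(fa, levels = c("a2", "a1"))
  res_rel <- twoway_linear_anova(y, relabel, fb)
  expect_equal(res_rel$F, res$F, tolerance = 1e-10)

  # constant response is flagged, not an error
  cst <- twoway_linear_anova(rep(1, 12), fa, fb)
  expect_true(attr(cst, "constant_response"))
  expect_true(all(is.na(cst$F)))
})

test_that("Type II sums of squares are order-invariant on unbalanced data", {
  set.seed(13)
  fa <- factor(sample(c("a1", "a2"), 40, TRUE))
  fb <- factor(sample(c("b1", "b2"), 40, TRUE))
  y <- rnorm(40) + (fa == "a2") * 0.8
  r_ab <- twoway_linear_anova(y, fa, fb)
  r_ba <- twoway_linear_anova(y, fb, fa)
  expect_equal(r_ab$F[1], r_ba$F[2], tolerance = 1e-10)
  expect_equal(r_ab$F[2], r_ba$F[1], tolerance = 1e-10)
  expect_equal(r_ab$F[3], r_ba$F[3], tolerance = 1e-10)
})

test_that("null p-values of the transformed t-test are uniform", {
  set.seed(23)
  n_rep <- 2000
  ps <- replicate(n_rep, {
    a <- rnorm(25, 220, 35); b <- rnorm(25, 220, 35)
    latency_test(pmax(a, 50), pmax(b, 50), method = "t",
                 transform = TRUE)$p_value
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 0.035)
})
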