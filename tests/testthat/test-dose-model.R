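# Regression models, segmented dose response, and the testing chain.

test_that("linear fit matches the closed-form normal equations", {
  dg <- c(-40, -30, -20, -10)
  fc <- c(0.05, 0.2, 0.6, 0.9)
  fit <- fit_linear(dg, fc)
  # independent oracle: solve the normal equations directly
  slope <- sum((dg - mean(dg)) * (fc - mean(fc))) / sum((dg - mean(dg))^2)
  intercept <- mean(fc) - slope * mean(dg)
  expect_equal(unname(fit$params[["slope"]]), slope)
  expect_equal(unname(fit$params[["intercept"]]), intercept)
  sse <- sum((fc - (intercept + slope * dg))^2)
  sst <- sum((fc - mean(fc))^2)
  expect_equal(fit$r2, 1 - sse / sst)
  # permutation invariance
  p <- c(3, 1, 4, 2)
  expect_equal(fit_linear(dg[p], fc[p])$params, fit$params)
  # degenerate and tiny inputs
  expect_error(fit_linear(rep(-5, 4), fc), "degenerate")
  expect_error(fit_linear(dg[1:2], fc[1:2]), "3 points")
  # perfectly collinear data
  expect_equal(fit_linear(dg, 0.01 * dg + 1)$r2, 1)
})

test_that("logistic4 recovers noise-free logistic data and beats linear SSE", {
  dg <- seq(-50, -5, length.out = 12)
  truth <- c(a = 1.05, d = 0.02, g50 = -30, b = 5)
  fc <- truth[["d"]] + (truth[["a"]] - truth[["d"]]) /
    (1 + exp((dg - truth[["g50"]]) / truth[["b"]]))
  fit <- fit_logistic4(dg, fc)
  expect_equal(unname(predict_fc(fit, dg)), fc, tolerance = 1e-4)
  expect_equal(unname(fit$params[["g50"]]), -30, tolerance = 1e-2)
  expect_gte(fit$r2, 0.9999)
  # richer model never loses to the line (multistart includes a linear-like start)
  lin <- fit_linear(dg, fc)
  sse_lin <- sum(lin$residuals^2)
  sse_log <- sum(fit$residuals^2)
  expect_lte(sse_log, sse_lin + 1e-8)
})

test_that("logistic4 recovers g50 within 2 kcal/mol under noise", {
  dg <- seq(-50, -5, length.out = 15)
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    fc <- 0.02 + (1 - 0.02) / (1 + exp((dg + 30) / 5)) + rnorm(15, 0, 0.05)
    fit <- fit_logistic4(dg, fc)
    abs(fit$params[["g50"]] + 30) < 2
  }, logical(1))
  expect_gt(mean(hits), 0.8)
})

test_that("predict_fc evaluates, flags extrapolation, and has logistic limits", {
  dg <- seq(-50, -5, length.out = 10)
  fc <- 0.02 + 0.98 / (1 + exp((dg + 28) / 4))
  fit <- fit_logistic4(dg, fc)
  at_train <- predict_fc(fit, dg[4])
  expect_equal(unname(at_train), fc[4], tolerance = 1e-3)
  far <- predict_fc(fit, c(-200, 100))
  expect_equal(unname(far[1]), unname(fit$params[["a"]]), tolerance = 1e-3)
  expect_equal(unname(far[2]), unname(fit$params[["d"]]), tolerance = 1e-3)
  expect_true(all(attr(far, "extrapolated")))
  expect_error(predict_fc(list(), -10), "not a fitted")
})

test_that("GC-pair differential arithmetic, sign convention and exclusions", {
  same <- data.frame(fc_high = c(0.5, 0.7), fc_low = c(0.5, 0.7))
  expect_equal(gc_pair_differential(same)$per_pair$diff, c(0, 0))
  d <- gc_pair_differential(data.frame(fc_high = c(0.4, 0.6),
                                       fc_low = c(0.5, 0.8)))
  expect_equal(d$per_pair$diff, c(-0.1, -0.2))
  expect_equal(d$mean_diff, -0.15)
  # excluded pair stays in the per-pair output but leaves the mean
  dd <- gc_pair_differential(
    data.frame(pair = c("p1", "p2"), fc_high = c(0.4, 0.6),
               fc_low = c(0.5, 0.8)), exclude = "p2")
  expect_equal(nrow(dd$per_pair), 2)
  expect_equal(dd$mean_diff, -0.1)
  expect_error(gc_pair_differential(same[0, ]), "at least one")
})

test_that("cross correlation: identity, independence, scale invariance", {
  x <- c(0.1, 0.3, 0.5, 0.8, 1.0)
  expect_equal(cross_correlation(x, x)$r2, 1)
  r2s <- vapply(1:20, function(s) {
    set.seed(s)
    cross_correlation(rnorm(20), rnorm(20))$r2
  }, numeric(1))
  expect_lt(median(r2s), 0.3)
  set.seed(7); y <- x + rnorm(5, 0, 0.1)
  expect_equal(cross_correlation(x, 10 * y)$r2, cross_correlation(x, y)$r2)
  expect_error(cross_correlation(x, y[1:3]), "mismatch")
})

test_that("segmented response: exact breakpoint on noise-free data", {
  level <- c(0.1, 0.2, 0.3, 0.4, 0.6, 0.8, 1.0, 1.2)
  resp <- 4.5 * pmin(level / 0.4, 1)
  est <- segmented_response(level, resp, mode = "estimate")
  expect_equal(est$breakpoint, 0.4)     # 0.4 is an observed level, so on-grid
  expect_equal(est$plateau, 4.5)
  expect_gte(est$r2, 1 - 1e-12)
  expect_error(segmented_response(level[1:4], resp[1:4], mode = "estimate"),
               "6 points")
})

test_that("segmented response: fixed-split group fits match closed-form OLS", {
  level <- c(0.1, 0.2, 0.3, 0.5, 0.7, 0.9, 1.1)
  resp <- c(1.0, 2.1, 2.9, 4.1, 4.0, 4.2, 3.9)
  sf <- segmented_response(level, resp, split = 0.4, mode = "fixed")
  ols_r2 <- function(x, y) {
    s <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    i <- mean(y) - s * mean(x)
    1 - sum((y - i - s * x)^2) / sum((y - mean(y))^2)
  }
  expect_equal(sf$low$r2, ols_r2(level[level < 0.4], resp[level < 0.4]))
  expect_equal(sf$high$r2, ols_r2(level[level >= 0.4], resp[level >= 0.4]))
  expect_error(segmented_response(level, resp, split = 0.01, mode = "fixed"),
               "nonempty")
})

test_that("breakpoint estimator error shrinks with sample size", {
  est_err <- function(n, seeds = 12) {
    median(vapply(seq_len(seeds), function(s) {
      cfg <- dose_response_sim_config(
        sumf1_levels = seq(0.05, 1.2, length.out = n), seed = s)
      dr <- simulate_sumf1_dose_response(cfg)
      abs(segmented_response(dr$level, dr$activity,
                             mode = "estimate")$breakpoint - 0.4)
    }, numeric(1)))
  }
  expect_lt(est_err(40), est_err(8) + 0.02)
})

test_that("Levene's test behaves on equal and unequal spreads", {
  g_eq <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
  expect_gt(levene_test(g_eq)$p_value, 0.5)
  g_ne <- list(a = c(1, 1.01, 0.99, 1.02), b = c(0, 10, -10, 20))
  expect_lt(levene_test(g_ne)$p_value, 0.05)
})

test_that("Dunnett chain: nulls stay quiet, large shifts light up, flags monotone", {
  cfg <- stat_config(control_name = "CMV")
  same <- list(CMV = c(1, 1.05, 0.95), a = c(1.01, 0.99, 1.0),
               b = c(0.98, 1.02, 1.0))
  res <- anova_dunnett(same, cfg)
  expect_false(any(res$comparisons$significant))
  # one group shifted by ~10 pooled SDs at n = 3
  shifted <- list(CMV = c(1, 1.05, 0.95), a = c(1.01, 0.99, 1.0),
                  b = c(1.5, 1.55, 1.45))
  res2 <- anova_dunnett(shifted, cfg)
  expect_true(res2$comparisons$significant[res2$comparisons$group == "b"])
  expect_false(res2$comparisons$significant[res2$comparisons$group == "a"])
  # p-values monotone in effect size at fixed noise
  shifts <- c(0.05, 0.2, 0.8)
  ps <- vapply(shifts, function(d) {
    g <- list(CMV = c(1, 1.05, 0.95), x = c(1, 1.05, 0.95) + d)
    anova_dunnett(g, cfg)$comparisons$p_adj
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_error(anova_dunnett(list(a = 1:3), cfg), "2 groups")
  expect_error(anova_dunnett(list(CMV = 1:3, a = 2), cfg), "replicates")
  expect_error(anova_dunnett(list(x = 1:3, y = 1:3), cfg), "control")
})

test_that("Dunnett adjusted p exceeds the unadjusted two-sided t p-value", {
  g <- list(CMV = c(1.0, 1.1, 0.9, 1.05), a = c(1.2, 1.3, 1.15, 1.25),
            b = c(0.95, 1.0, 1.05, 0.9), c = c(1.05, 1.1, 0.95, 1.0))
  res <- anova_dunnett(g, stat_config(control_name = "CMV"))
  k <- 3; df <- 16 - 4
  sp2 <- sum(vapply(g, function(x) sum((x - mean(x))^2), numeric(1))) / df
  for (i in seq_len(nrow(res$comparisons))) {
    tt <- abs(res$comparisons$t[i])
    p_un <- 2 * pt(-tt, df)
    expect_gte(res$comparisons$p_adj[i], p_un - 1e-9)
    expect_lte(res$comparisons$p_adj[i], min(1, k * p_un) + 0.01)
  }
})
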