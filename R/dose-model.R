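# Dose-response modeling and the hypothesis-testing chain.
#
# The relation between hairpin free energy and expression fold change is
# fitted both linearly (for the headline R^2) and with a four-parameter
# logistic in dG (sigmoid transition between the unrepressed and fully
# repressed plateaus).  Helper-factor dose responses use a continuous
# plateau model with a grid-searched breakpoint.  Group comparisons follow
# Levene -> one-way ANOVA -> Dunnett many-to-one at family-wise alpha.

.new_fit <- function(model, params, r2, residuals, fitted, predict_fun,
                     x_range) {
  structure(list(model = model, params = params, r2 = r2,
                 residuals = residuals, fitted = fitted,
                 predict_fun = predict_fun, x_range = x_range),
            class = "rge_fit")
}

#' @export
print.rge_fit <- function(x, ...) {
  cat(sprintf("<rge_fit> %s  R^2 = %.4f\n", x$model, x$r2))
  print(signif(x$params, 4))
  invisible(x)
}

#' Ordinary least-squares fit of fold change on free energy
#'
#' @param dg predictor (kcal/mol), n >= 3, non-constant.
#' @param fc response (fold change).
#' @return An `rge_fit` with `params = c(intercept, slope)` and
#'   `r2 = 1 - SSE/SST`.
#' @export
fit_linear <- function(dg, fc) {
  if (length(dg) != length(fc)) stop("length mismatch")
  if (length(dg) < 3L) stop("need at least 3 points")
  if (sd(dg) == 0) stop("degenerate predictor")
  fit <- lm(fc ~ dg)
  p <- c(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]))
  r2 <- summary(fit)$r.squared
  .new_fit("linear", p, r2, unname(stats::residuals(fit)), unname(fitted(fit)),
           function(x) p[["intercept"]] + p[["slope"]] * x, range(dg))
}

.logistic4 <- function(x, a, d, g50, b) d + (a - d) / (1 + exp((x - g50) / b))

#' Four-parameter logistic fit of fold change on free energy
#'
#' `fc(dG) = d + (a - d) / (1 + exp((dG - g50)/b))` fitted by least squares
#' with multistart (including a near-linear start, so the logistic SSE never
#' exceeds the linear SSE by more than numerical tolerance on data where
#' both converge).  `a` is the weak-hairpin (upper) plateau, `d` the
#' strong-hairpin (lower) plateau, `g50` the midpoint in kcal/mol and `b`
#' the transition width.
#'
#' @param dg predictor (kcal/mol), n >= 5.
#' @param fc response (fold change).
#' @return An `rge_fit` with `params = c(a, d, g50, b)`.
#' @export
fit_logistic4 <- function(dg, fc) {
  if (length(dg) != length(fc)) stop("length mismatch")
  if (length(dg) < 5L) stop("need at least 5 points")
  sse <- function(p) {
    yhat <- .logistic4(dg, p[1], p[2], p[3], p[4])
    if (any(!is.finite(yhat))) return(1e18)
    sum((fc - yhat)^2)
  }
  rng <- range(dg); span <- diff(rng)
  qs <- quantile(dg, c(0.25, 0.5, 0.75), names = FALSE)
  starts <- list(
    c(max(fc), min(fc), qs[2], span / 8),
    c(max(fc), min(fc), qs[1], span / 4),
    c(max(fc), min(fc), qs[3], span / 4),
    c(max(fc), min(fc), qs[2], -span / 8),
    # near-linear start: wide transition approximates a straight line
    c(max(fc) + diff(range(fc)), min(fc) - diff(range(fc)), mean(dg), span * 5))
  best <- NULL
  for (s in starts) {
    o <- tryCatch(optim(s, sse, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-12)),
                  error = function(e) NULL)
    if (!is.null(o)) {
      o <- tryCatch(optim(o$par, sse, method = "BFGS",
                          control = list(maxit = 1000)),
                    error = function(e) o)
      if (is.null(best) || o$value < best$value) best <- o
    }
  }
  if (is.null(best) || !is.finite(best$value))
    stop("logistic fit did not converge from any start (best residual ",
         if (is.null(best)) "none" else format(best$value), ")")
  p <- setNames(best$par, c("a", "d", "g50", "b"))
  yhat <- .logistic4(dg, p[1], p[2], p[3], p[4])
  sst <- sum((fc - mean(fc))^2)
  r2 <- if (sst > 0) max(0, min(1, 1 - best$value / sst)) else 1
  .new_fit("logistic4", p, r2, fc - yhat, yhat,
           function(x) .logistic4(x, p[["a"]], p[["d"]], p[["g50"]], p[["b"]]),
           rng)
}

#' Predict fold change from a fitted model
#'
#' @param fit an `rge_fit` from [fit_linear()] or [fit_logistic4()].
#' @param dg free-energy values to predict at.
#' @return Numeric predictions; extrapolation beyond the training range is
#'   flagged via the `extrapolated` attribute.
#' @export
predict_fc <- function(fit, dg) {
  if (!inherits(fit, "rge_fit")) stop("not a fitted model")
  out <- fit$predict_fun(dg)
  extra <- dg < fit$x_range[1] | dg > fit$x_range[2]
  if (any(extra)) attr(out, "extrapolated") <- extra
  out
}

#' GC-content fold-change differential for matched element pairs
#'
#' For pairs of elements with similar stability and position but high versus
#' low stem GC-content, the differential `fc_high - fc_low` is negative when
#' the high-GC element represses more strongly.  Flagged pairs stay in the
#' per-pair output but are excluded from the mean.
#'
#' @param pairs `data.frame` with columns `fc_high`, `fc_low` and optionally
#'   `pair` (names).
#' @param exclude pair names excluded from the mean.
#' @return List with `per_pair` (data.frame incl. `diff`) and `mean_diff`.
#' @export
gc_pair_differential <- function(pairs, exclude = character()) {
  if (!is.data.frame(pairs) || !all(c("fc_high", "fc_low") %in% names(pairs)))
    stop("pairs must have columns fc_high, fc_low")
  if (nrow(pairs) < 1L) stop("need at least one pair")
  if (is.null(pairs$pair)) pairs$pair <- paste0("pair", seq_len(nrow(pairs)))
  pairs$diff <- pairs$fc_high - pairs$fc_low
  keep <- !(pairs$pair %in% exclude)
  if (!any(keep)) stop("no pairs left after exclusions")
  list(per_pair = pairs, mean_diff = mean(pairs$diff[keep]))
}

#' Cross-condition fold-change correlation
#'
#' OLS of one condition's fold changes on another's (e.g. HEK on CHO, or
#' protein on mRNA), reporting the R^2.
#'
#' @param x_fc,y_fc matched fold-change vectors.
#' @return An `rge_fit` (linear).
#' @export
cross_correlation <- function(x_fc, y_fc) {
  if (length(x_fc) != length(y_fc)) stop("length mismatch")
  fit_linear(x_fc, y_fc)
}

#' Segmented dose-response analysis with a plateau breakpoint
#'
#' Fixed mode splits the data at a given level (`< split` = low, `>= split`
#' = high) and fits OLS within each group.  Estimate mode fits the
#' continuous plateau model `response = c * min(level, tau) / tau` by grid
#' search over candidate breakpoints (the observed levels plus 100 uniform
#' candidates), minimizing total SSE; `c` has a closed form per candidate.
#'
#' @param level helper expression levels.
#' @param response measured response (e.g. specific activity).
#' @param split fixed split point (default 0.4).
#' @param mode `"fixed"` or `"estimate"`.
#' @return Fixed mode: list with `low`, `high` (each an `rge_fit`) and
#'   `split`.  Estimate mode: list with `breakpoint`, `plateau` (fitted `c`),
#'   `sse` and `r2`.
#' @export
segmented_response <- function(level, response, split = 0.4,
                               mode = c("fixed", "estimate")) {
  mode <- match.arg(mode)
  if (length(level) != length(response)) stop("length mismatch")
  if (mode == "fixed") {
    lo <- level < split; hi <- !lo
    if (!any(lo) || !any(hi)) stop("both groups must be nonempty at split ", split)
    return(list(low = fit_linear(level[lo], response[lo]),
                high = fit_linear(level[hi], response[hi]),
                split = split))
  }
  if (length(level) < 6L) stop("estimate mode needs at least 6 points")
  cand <- sort(unique(c(level, seq(min(level), max(level), length.out = 100))))
  cand <- cand[cand > 0]
  sst <- sum((response - mean(response))^2)
  best <- NULL
  for (tau in cand) {
    g <- pmin(level, tau) / tau
    cc <- sum(response * g) / sum(g^2)
    sse <- sum((response - cc * g)^2)
    if (is.null(best) || sse < best$sse - 1e-12)
      best <- list(breakpoint = tau, plateau = cc, sse = sse)
  }
  best$r2 <- if (sst > 0) 1 - best$sse / sst else 1
  best
}

# --- hypothesis-testing chain ------------------------------------------------

#' Statistical configuration for group comparisons
#'
#' @param alpha family-wise significance level (0 < alpha < 1).
#' @param control_name name of the control group.
#' @return A list of class `stat_config`.
#' @export
stat_config <- function(alpha = 0.05, control_name = "CMV") {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  structure(list(alpha = alpha, control_name = control_name,
                 variance_check = "Levene"), class = "stat_config")
}

#' Levene's test for homogeneity of variances
#'
#' Classic mean-centered form: one-way ANOVA on the absolute deviations of
#' each observation from its group mean.
#'
#' @param groups named list of numeric replicate vectors.
#' @return List with `statistic` (F), `df` and `p_value`.
#' @export
levene_test <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  z <- unlist(lapply(groups, function(x) abs(x - mean(x))), use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)))
  fit <- lm(z ~ g)
  a <- anova(fit)
  list(statistic = a$`F value`[1], df = a$Df, p_value = a$`Pr(>F)`[1])
}

# null distribution of the Dunnett max-|t| statistic by seeded Monte Carlo;
# memoized per design (group sizes + df) in a package-local cache
.dunnett_cache <- new.env(parent = emptyenv())

.dunnett_null_maxt <- function(n_control, n_groups, df, draws = 1e5,
                               seed = 20201013) {
  key <- paste(n_control, paste(n_groups, collapse = "_"), df, draws, sep = "|")
  hit <- .dunnett_cache[[key]]
  if (!is.null(hit)) return(hit)
  k <- length(n_groups)
  maxt <- with_seed(seed, {
    z0 <- rnorm(draws) / sqrt(n_control)
    s <- sqrt(rchisq(draws, df) / df)
    m <- matrix(rnorm(draws * k), draws, k)
    tmat <- vapply(seq_len(k), function(j)
      abs(m[, j] / sqrt(n_groups[j]) - z0) /
        (s * sqrt(1 / n_groups[j] + 1 / n_control)),
      numeric(draws))
    if (k == 1L) as.numeric(tmat) else apply(tmat, 1L, max)
  })
  maxt <- sort(maxt)
  .dunnett_cache[[key]] <- maxt
  maxt
}

.dunnett_p_adj <- function(tstats, n_control, n_groups, df) {
  k <- length(n_groups)
  if (requireNamespace("mvtnorm", quietly = TRUE)) {
    lam <- sqrt(n_groups / (n_groups + n_control))
    corr <- outer(lam, lam); diag(corr) <- 1
    vapply(abs(tstats), function(tt) {
      pr <- mvtnorm::pmvt(lower = rep(-tt, k), upper = rep(tt, k),
                          delta = rep(0, k), df = df, corr = corr)
      max(0, min(1, 1 - as.numeric(pr)))
    }, numeric(1))
  } else {
    maxt <- .dunnett_null_maxt(n_control, n_groups, df)
    vapply(abs(tstats), function(tt)
      (sum(maxt >= tt) + 1) / (length(maxt) + 1), numeric(1))
  }
}

.p_flag <- function(p) {
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*"
  else if (p < 0.1) "#" else "n.s."
}

#' Levene / one-way ANOVA / Dunnett testing chain
#'
#' Checks variance homogeneity with Levene's test, tests for any group
#' difference with a one-way ANOVA, then compares every treatment against
#' the named control with Dunnett's many-to-one procedure at family-wise
#' `alpha` (two-sided).  Adjusted p-values come from the multivariate-t
#' formulation when the mvtnorm package is available, and otherwise from a
#' seeded Monte-Carlo null of the max-|t| statistic (1e5 draws, memoized per
#' design).
#'
#' @param groups named list of numeric replicate vectors (>= 2 groups, >= 2
#'   replicates each) including the control.
#' @param cfg a [stat_config()].
#' @return List with `levene`, `anova_f`, `anova_p` and `comparisons` (a
#'   `data.frame` with `group`, `estimate`, `t`, `p_adj`, `flag`,
#'   `significant`).
#' @export
anova_dunnett <- function(groups, cfg = stat_config()) {
  stopifnot(inherits(cfg, "stat_config"))
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (!cfg$control_name %in% names(groups))
    stop("control group '", cfg$control_name, "' missing")
  if (any(lengths(groups) < 2L)) stop("every group needs >= 2 replicates")
  lev <- levene_test(groups)
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  a <- anova(lm(y ~ g))
  treat <- setdiff(names(groups), cfg$control_name)
  n0 <- length(groups[[cfg$control_name]])
  nj <- lengths(groups)[treat]
  N <- length(y); df <- N - length(groups)
  sp2 <- sum(vapply(groups, function(x) sum((x - mean(x))^2), numeric(1))) / df
  m0 <- mean(groups[[cfg$control_name]])
  est <- vapply(groups[treat], mean, numeric(1)) - m0
  tstat <- est / sqrt(sp2 * (1 / nj + 1 / n0))
  p_adj <- .dunnett_p_adj(tstat, n0, nj, df)
  comp <- data.frame(group = treat, estimate = unname(est), t = unname(tstat),
                     p_adj = unname(p_adj),
                     flag = vapply(p_adj, .p_flag, character(1)),
                     significant = unname(p_adj < cfg$alpha),
                     stringsAsFactors = FALSE)
  list(levene = lev, anova_f = a$`F value`[1], anova_p = a$`Pr(>F)`[1],
       comparisons = comp)
}
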