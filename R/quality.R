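# Product-quality signals: SEC peak integration into HMW/main/LMW fractions,
# gel densitometry band ratios, and the helper-factor western-blot
# normalization scheme.

#' Integrate a chromatogram into a peak table
#'
#' A linear baseline is fitted to the low-signal flanking regions and
#' subtracted; peaks are local maxima above a prominence threshold; peak
#' boundaries are placed valley-to-valley (outermost peaks extend to the
#' trace ends); areas are trapezoidal and fractions normalized to 100.
#'
#' @param c `data.frame` with strictly increasing `time_min` and finite
#'   `a280` (>= 50 points).
#' @param prominence_frac minimum peak height as a fraction of the tallest
#'   baseline-subtracted signal.
#' @param flank_frac fraction of points at each end treated as baseline
#'   territory.
#' @param min_peak_sep minimum apex separation in minutes; closer maxima are
#'   treated as one peak (noise jitter on a single apex).  Defaults to 1/60
#'   of the time span.
#' @return `data.frame` of class `peak_table` with columns `left`, `right`,
#'   `apex`, `area`, `fraction`, `klass` (NA until [classify_peaks()]).
#' @export
integrate_chromatogram <- function(c, prominence_frac = 0.02,
                                   flank_frac = 0.15, min_peak_sep = NULL) {
  if (!is.data.frame(c) || !all(c("time_min", "a280") %in% names(c)))
    stop("chromatogram must have columns time_min, a280")
  if (nrow(c) < 50L) stop("chromatogram must have at least 50 points")
  if (any(diff(c$time_min) <= 0)) stop("time_min must be strictly increasing")
  if (!all(is.finite(c$a280))) stop("a280 must be finite")
  t <- c$time_min; y0 <- c$a280; n <- length(t)
  nf <- max(5L, floor(flank_frac * n))
  flank <- c(seq_len(nf), seq(n - nf + 1L, n))
  # linear baseline on the flanks, iteratively clipping high outliers so a
  # peak tail nudging into a flank cannot drag the fit up; symmetric noise
  # around the fit stays in, keeping the estimate unbiased
  base_pts <- flank
  bl_fit <- NULL
  for (it in 1:3) {
    bl_fit <- lm(y ~ x, data = data.frame(x = t[base_pts], y = y0[base_pts]))
    res <- y0[flank] - predict(bl_fit, newdata = data.frame(x = t[flank]))
    keep <- res <= 3 * mad(res) + 1e-12
    if (all(keep) || sum(keep) < 10L) break
    base_pts <- flank[keep]
  }
  y <- y0 - predict(bl_fit, newdata = data.frame(x = t))
  noise <- mad(y[base_pts])
  thr <- max(prominence_frac * max(y), 5 * noise)
  if (is.null(min_peak_sep)) min_peak_sep <- diff(range(t)) / 60
  # detect on a lightly smoothed copy so channel noise cannot split an apex
  k <- max(5L, 2L * (n %/% 400L) + 1L)
  ys <- as.numeric(stats::filter(y, rep(1 / k, k), sides = 2))
  ys[is.na(ys)] <- y[is.na(ys)]
  apex <- which(diff(sign(diff(ys))) < 0) + 1L
  apex <- apex[ys[apex] > thr]
  # flat-top saturation: identical consecutive raw values at an apex
  if (length(apex) && any(vapply(apex, function(i)
    i < n && abs(y0[i] - y0[i + 1L]) < 1e-12 && y[i] > 0.5 * max(y), logical(1))))
    warning("possible saturated flat-top peak")
  if (length(apex) == 0L) stop("no peaks above threshold")
  # merge apexes closer than the minimum separation
  if (length(apex) > 1L) {
    grp <- cumsum(c(TRUE, diff(t[apex]) > min_peak_sep))
    apex <- vapply(split(apex, grp), function(ix) ix[which.max(y[ix])], integer(1))
  }
  bounds <- integer(length(apex) + 1L)
  bounds[1L] <- 1L; bounds[length(bounds)] <- n
  if (length(apex) > 1L)
    for (i in seq_len(length(apex) - 1L)) {
      seg <- apex[i]:apex[i + 1L]
      bounds[i + 1L] <- seg[which.min(y[seg])]
    }
  trap <- function(ix) sum(diff(t[ix]) * (head(y[ix], -1) + tail(y[ix], -1)) / 2)
  area <- vapply(seq_along(apex), function(i)
    trap(bounds[i]:bounds[i + 1L]), numeric(1))
  area <- pmax(area, 0)
  out <- data.frame(left = t[bounds[-length(bounds)]],
                    right = t[bounds[-1L]],
                    apex = t[apex],
                    area = area,
                    fraction = 100 * area / sum(area),
                    klass = NA_character_,
                    stringsAsFactors = FALSE)
  class(out) <- c("peak_table", "data.frame")
  out
}

#' Classify peaks into HMW / main / LMW
#'
#' The main (native product) peak is the one whose apex falls in
#' `main_window` if given, otherwise the largest-area peak (area ties break
#' to earlier elution with a warning).  Peaks eluting earlier are high
#' molecular weight (HMW) aggregates, later ones low molecular weight (LMW)
#' fragments.
#'
#' @param p a `peak_table` from [integrate_chromatogram()].
#' @param main_window optional `c(min, max)` elution window of the main peak,
#'   minutes.
#' @return The peak table with `klass` filled in (`"HMW"`, `"mAb"`, `"LMW"`).
#' @export
classify_peaks <- function(p, main_window = NULL) {
  stopifnot(inherits(p, "peak_table"))
  if (!is.null(main_window)) {
    inw <- which(p$apex >= main_window[1] & p$apex <= main_window[2])
    if (length(inw) == 0L) stop("no peak apex inside main_window")
    main <- inw[which.max(p$area[inw])]
  } else {
    mx <- max(p$area)
    cand <- which(abs(p$area - mx) < 1e-9 * max(mx, 1))
    if (length(cand) > 1L)
      warning("two candidate main peaks of equal area; taking earlier elution")
    main <- cand[1L]
  }
  p$klass <- ifelse(seq_len(nrow(p)) < main, "HMW",
                    ifelse(seq_len(nrow(p)) > main, "LMW", "mAb"))
  p
}

#' Band-intensity ratio and fold change from a gel lane profile
#'
#' Band area is the trapezoidal integral of the background-subtracted
#' intensity inside the annotated window, background being the linear
#' interpolation between the window-edge intensities.  If the denominator
#' band falls below the detection floor (3x the MAD of the off-band
#' background), the ratio is reported missing rather than infinite.
#'
#' @param l `data.frame` with columns `position`, `intensity`.
#' @param windows named list of `c(lo, hi)` windows per species.
#' @param species_a,species_b numerator and denominator species (default
#'   full-size product over heavy-chain dimer).
#' @param control_ratio the same ratio measured on the control lane; fold
#'   change is `ratio / control_ratio`.
#' @return List of class `band_ratio`: `area_a`, `area_b`, `ratio`, `fc`,
#'   `detected`.
#' @export
lane_band_ratio <- function(l, windows, species_a = "fs", species_b = "2HC",
                            control_ratio = 1) {
  if (!is.data.frame(l) || !all(c("position", "intensity") %in% names(l)))
    stop("lane profile must have columns position, intensity")
  for (s in c(species_a, species_b))
    if (is.null(windows[[s]])) stop("no band window annotated for ", s)
  x <- l$position; y <- l$intensity
  band_area <- function(w) {
    ix <- which(x >= w[1] & x <= w[2])
    if (length(ix) < 3L) stop("band window too narrow for the profile grid")
    edge_n <- max(3L, ceiling(length(ix) * 0.05))
    lo_lev <- mean(y[head(ix, edge_n)]); hi_lev <- mean(y[tail(ix, edge_n)])
    bg <- lo_lev + (hi_lev - lo_lev) * (x[ix] - x[ix][1]) / diff(range(x[ix]))
    yy <- y[ix] - bg
    sum(diff(x[ix]) * (head(yy, -1) + tail(yy, -1)) / 2)
  }
  in_any <- rep(FALSE, length(x))
  for (w in windows) in_any <- in_any | (x >= w[1] & x <= w[2])
  off <- y[!in_any]
  # detrend the off-band background before estimating its noise floor
  off_res <- if (sum(!in_any) > 10)
    stats::residuals(lm(off ~ x[!in_any])) else off - median(off)
  floor_area <- 3 * mad(off_res) * diff(windows[[species_b]])
  a <- band_area(windows[[species_a]])
  b <- band_area(windows[[species_b]])
  detected <- b > floor_area
  ratio <- if (detected) a / b else NA_real_
  structure(list(area_a = a, area_b = b, ratio = ratio,
                 fc = if (detected) ratio / control_ratio else NA_real_,
                 detected = detected),
            class = "band_ratio")
}

#' One western-blot observation of helper-factor level
#'
#' @param lysate_band,supernatant_band band intensities (a.u.).
#' @param ladder55_band intensity of the 55 kDa ladder band used as the
#'   blot-to-blot loading normalizer (> 0).
#' @param vcd_day4 viable cell density at harvest, cells/mL (> 0).
#' @param ccd_0_4 cumulative cell days over days 0-4, cell.days/mL (> 0).
#' @return A list of class `sumf1_obs`.
#' @export
sumf1_obs <- function(lysate_band, supernatant_band, ladder55_band,
                      vcd_day4, ccd_0_4) {
  .check_scalar(lysate_band, "lysate_band", lower = 0)
  .check_scalar(supernatant_band, "supernatant_band", lower = 0)
  if (ladder55_band <= 0) stop("ladder55_band must be > 0")
  if (vcd_day4 <= 0 || ccd_0_4 <= 0) stop("cell densities must be > 0")
  structure(list(lysate_band = lysate_band,
                 supernatant_band = supernatant_band,
                 ladder55_band = ladder55_band,
                 vcd_day4 = vcd_day4, ccd_0_4 = ccd_0_4),
            class = "sumf1_obs")
}

#' Relative helper-factor level versus the unregulated control
#'
#' Each compartment is normalized to the 55 kDa ladder band and then to the
#' relevant cell amount: the intracellular (lysate) signal to the harvest-day
#' viable cell density, the secreted (supernatant) signal to the cumulative
#' cell days, because secreted factor accumulates over time.  The two
#' normalized compartment values are combined (`sum` by default; `mean`
#' offered because the original combination rule is ambiguous) and related to
#' the control.
#'
#' @param obs,control [sumf1_obs()] observations.
#' @param combine `"sum"` or `"mean"`.
#' @return Relative level (1 for the control vs itself).
#' @export
sumf1_relative_level <- function(obs, control, combine = c("sum", "mean")) {
  combine <- match.arg(combine)
  stopifnot(inherits(obs, "sumf1_obs"), inherits(control, "sumf1_obs"))
  comb <- function(o) {
    L <- (o$lysate_band / o$ladder55_band) / o$vcd_day4
    S <- (o$supernatant_band / o$ladder55_band) / o$ccd_0_4
    if (combine == "sum") L + S else (L + S) / 2
  }
  comb(obs) / comb(control)
}
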