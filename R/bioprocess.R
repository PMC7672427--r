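# Batch-culture product metrics: integral viable cell density (cumulative
# cell days), specific productivity qP, protein concentration from A280, and
# chromogenic sulfatase activity.
#
# Units: VCD cells/mL, titer ug/mL, qP pg/cell/day, activity U = umol
# product/min.

.check_batch <- function(b) {
  if (!is.data.frame(b) || !all(c("day", "vcd", "titer") %in% names(b)))
    stop("batch series must have columns day, vcd, titer")
  if (any(diff(b$day) <= 0)) stop("days must be strictly increasing")
  if (any(b$vcd < 0)) stop("vcd must be >= 0")
  invisible(b)
}

# linear interpolation of a batch column at time tt
.batch_at <- function(b, col, tt) approx(b$day, b[[col]], xout = tt, rule = 1)$y

#' Cumulative cell days (integral viable cell density)
#'
#' Trapezoidal integral of the viable cell density over `[t0, t1]`, in
#' cell.days/mL.  Endpoints inside the sampled span are linearly
#' interpolated; a zero-length interval integrates to 0.
#'
#' @param b batch series (`data.frame` with `day`, `vcd`, `titer`).
#' @param t0,t1 integration bounds (default full span); `t1 < t0` errors.
#' @return Cumulative cell days, cell.days/mL.
#' @examples
#' b <- data.frame(day = 0:4, vcd = 1e6, viability = 98, titer = 0)
#' cumulative_cell_days(b)   # 4e6
#' @export
cumulative_cell_days <- function(b, t0 = min(b$day), t1 = max(b$day)) {
  .check_batch(b)
  if (t1 < t0) stop("t1 must be >= t0")
  if (t0 < min(b$day) || t1 > max(b$day)) stop("[t0, t1] outside the series")
  if (t1 == t0) return(0)
  grid <- sort(unique(c(t0, t1, b$day[b$day > t0 & b$day < t1])))
  v <- .batch_at(b, "vcd", grid)
  sum(diff(grid) * (head(v, -1) + tail(v, -1)) / 2)
}

#' Specific productivity qP
#'
#' `qP = (titer_end - titer_start) * 1e6 / IVCD` over the chosen window,
#' pg/cell/day: the titer gain in pg/mL divided by the cumulative cell days.
#' The default window is the full batch (a single end-of-batch readout); the
#' per-interval mode returns one qP per sampling interval.
#'
#' @param b batch series.
#' @param t0,t1 window bounds (default full span).
#' @param per_interval return a `data.frame` of interval qPs instead of the
#'   single window value.
#' @return qP in pg/cell/day, or a `data.frame` in per-interval mode.
#' @export
specific_productivity <- function(b, t0 = min(b$day), t1 = max(b$day),
                                  per_interval = FALSE) {
  .check_batch(b)
  if (per_interval) {
    qs <- vapply(seq_len(nrow(b) - 1L), function(i)
      specific_productivity(b, b$day[i], b$day[i + 1L]), numeric(1))
    return(data.frame(t0 = head(b$day, -1), t1 = tail(b$day, -1), qp = qs))
  }
  ivcd <- cumulative_cell_days(b, t0, t1)
  if (ivcd == 0) stop("IVCD is zero over the window")
  d_titer <- .batch_at(b, "titer", t1) - .batch_at(b, "titer", t0)
  d_titer * 1e6 / ivcd
}

#' Protein spectral specification
#'
#' @param ext_coeff molar extinction coefficient at 280 nm, 1/(M cm) (> 0).
#' @param mw molecular weight, kDa (> 0).
#' @return A list of class `protein_spec`.
#' @export
protein_spec <- function(ext_coeff = 39350, mw = 52.677) {
  if (ext_coeff <= 0 || mw <= 0) stop("ext_coeff and mw must be > 0")
  structure(list(ext_coeff = ext_coeff, mw = mw), class = "protein_spec")
}

#' Protein concentration from A280
#'
#' Beer-Lambert: molarity `= A280 / (ext_coeff * path)`, converted to g/L
#' with the molecular weight (kDa * 1000 = g/mol).  The default spec is the
#' arylsulfatase used throughout: 39350 1/(M cm), 52.677 kDa, so A280 = 1
#' gives 1.3387 g/L.
#'
#' @param a280 absorbance at 280 nm (>= 0), vectorized.
#' @param spec a [protein_spec()].
#' @param path_cm light path, cm.
#' @return Concentration in g/L.
#' @export
protein_conc_a280 <- function(a280, spec = protein_spec(), path_cm = 1) {
  stopifnot(inherits(spec, "protein_spec"))
  if (any(a280 < 0)) stop("a280 must be >= 0")
  if (path_cm <= 0) stop("path_cm must be > 0")
  a280 / (spec$ext_coeff * path_cm) * spec$mw * 1000
}

#' Chromogenic activity assay container
#'
#' @param std_curve named vector `c(slope=, intercept=)`: absorbance per nmol
#'   of chromogenic product (slope > 0) and blank offset.
#' @param readings `data.frame` with columns `time_min`, `a515` (>= 2 rows
#'   spanning > 0 min).
#' @param sample_volume sample volume in the reaction, mL (> 0).
#' @param protein_conc optional protein concentration, mg/mL; without it the
#'   specific activity is omitted.
#' @return A list of class `activity_assay`.
#' @export
activity_assay <- function(std_curve, readings, sample_volume,
                           protein_conc = NULL) {
  if (!all(c("slope", "intercept") %in% names(std_curve)) ||
      std_curve[["slope"]] <= 0)
    stop("std_curve needs positive slope and an intercept")
  if (!is.data.frame(readings) ||
      !all(c("time_min", "a515") %in% names(readings)) || nrow(readings) < 2L)
    stop("readings must have >= 2 rows of time_min, a515")
  if (diff(range(readings$time_min)) <= 0) stop("readings must span > 0 min")
  if (sample_volume <= 0) stop("sample_volume must be > 0")
  structure(list(std_curve = std_curve, readings = readings,
                 sample_volume = sample_volume, protein_conc = protein_conc),
            class = "activity_assay")
}

#' Volumetric and specific sulfatase activity
#'
#' The product formation rate (nmol/min) is the least-squares slope of
#' `(A515 - intercept) / std_slope` against time.  One unit U = 1 umol
#' product/min, so `U/mL = rate * 1e-3 / sample_volume` and `U/mg =
#' (U/mL) / protein_conc`.  A negative fitted rate is clamped to 0 with a
#' warning.
#'
#' @param a an [activity_assay()].
#' @return List with `rate_nmol_min`, `u_per_ml` and `u_per_mg` (`NA` when
#'   the protein concentration is missing).
#' @export
asa_activity <- function(a) {
  stopifnot(inherits(a, "activity_assay"))
  nmol <- (a$readings$a515 - a$std_curve[["intercept"]]) / a$std_curve[["slope"]]
  fit <- lm(nmol ~ time_min, data = data.frame(time_min = a$readings$time_min,
                                               nmol = nmol))
  rate <- unname(coef(fit)[2])
  if (rate < 0) {
    warning("negative fitted rate clamped to 0")
    rate <- 0
  }
  u_per_ml <- rate * 1e-3 / a$sample_volume
  u_per_mg <- if (is.null(a$protein_conc)) NA_real_ else u_per_ml / a$protein_conc
  list(rate_nmol_min = rate, u_per_ml = u_per_ml, u_per_mg = u_per_mg)
}
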