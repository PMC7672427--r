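# Synthetic-data generators.  Every input the analysis modules consume can be
# generated here with a planted ground truth (stored in the "truth"
# attribute), under a seed, so parameter recovery is testable end to end.
#
# Noise conventions: multiplicative lognormal for fluorescence and cell
# densities (instrument convention), additive normal for CT values,
# absorbances and activities.  Units are fixed package-wide: VCD in cells/mL,
# titer in ug/mL, qP in pg/cell/day.

# lognormal sdlog giving a multiplicative coefficient of variation `cv`
.cv_to_sdlog <- function(cv) sqrt(log(1 + cv^2))

#' Configuration for a simulated flow-cytometry sample
#'
#' Defaults emulate a transient co-transfection readout: 150,000 recorded
#' events, a broad lognormal plasmid-dose distribution on the BFP
#' normalization channel, RFP tied to BFP through a multiplicative
#' translation `dosage` (the planted truth), plus untransfected, debris and
#' doublet subpopulations that the gating chain must remove.  The
#' autofluorescence floor overlaps the BFP gate boundary so gating is
#' nontrivial.
#'
#' @param n_events number of events (>= 1).
#' @param transfected_fraction fraction of intact single cells carrying
#'   plasmid.
#' @param dosage multiplicative translation factor on RFP (>= 0); 1 = the
#'   unregulated control.
#' @param bfp_log_mean,bfp_log_sd log-scale parameters of the transfected BFP
#'   signal (plasmid dose heterogeneity).
#' @param channel_noise_cv multiplicative measurement noise CV applied to the
#'   RFP channel.
#' @param debris_fraction,doublet_fraction event fractions of debris and
#'   cell doublets; together must not exceed 1.
#' @param seed RNG seed.
#' @return A validated config list of class `flow_sim_config`.
#' @export
flow_sim_config <- function(n_events = 150000L, transfected_fraction = 0.55,
                            dosage = 1, bfp_log_mean = log(2e4),
                            bfp_log_sd = 1.0, channel_noise_cv = 0.25,
                            debris_fraction = 0.08, doublet_fraction = 0.05,
                            seed = 1L) {
  .check_scalar(n_events, "n_events", lower = 1)
  .check_scalar(transfected_fraction, "transfected_fraction", 0, 1)
  .check_scalar(dosage, "dosage", lower = 0)
  .check_scalar(channel_noise_cv, "channel_noise_cv", lower = 0)
  .check_scalar(debris_fraction, "debris_fraction", 0, 1)
  .check_scalar(doublet_fraction, "doublet_fraction", 0, 1)
  if (debris_fraction + doublet_fraction > 1)
    stop("debris_fraction + doublet_fraction must not exceed 1")
  structure(as.list(environment()), class = "flow_sim_config")
}

#' Simulate a flow-cytometry event table
#'
#' Generates scatter and two-channel fluorescence per event with truth
#' labels.  Transfected singlets draw a lognormal plasmid dose on BFP and
#' express `RFP = dosage * dose * noise` on top of a small autofluorescence
#' floor; untransfected cells carry autofluorescence only; debris sits at low
#' scatter; doublets have SSC-A near twice SSC-H.  Identical config + seed
#' gives identical tables.
#'
#' @param cfg a [flow_sim_config()].
#' @return `data.frame` of class `cell_event_table` with columns `fsc_a`,
#'   `ssc_a`, `ssc_h`, `bfp`, `rfp`, `truth_label`, and attribute `truth`
#'   (the planted dosage and config).
#' @export
simulate_flow_sample <- function(cfg = flow_sim_config()) {
  stopifnot(inherits(cfg, "flow_sim_config"))
  with_seed(cfg$seed, {
    n <- as.integer(cfg$n_events)
    u <- runif(n)
    label <- rep("untransfected", n)
    label[u < cfg$debris_fraction] <- "debris"
    dd <- cfg$debris_fraction + cfg$doublet_fraction
    label[u >= cfg$debris_fraction & u < dd] <- "doublet"
    cell <- u >= dd
    label[cell][runif(sum(cell)) < cfg$transfected_fraction] <- "transfected"

    fsc <- rlnorm(n, log(1.0e5), 0.22)
    ssc_h <- rlnorm(n, log(5.0e4), 0.28)
    ssc_ratio <- rlnorm(n, 0, 0.03)          # SSC-A/SSC-H band for singlets
    is_debris <- label == "debris"
    is_doublet <- label == "doublet"
    fsc[is_debris] <- rlnorm(sum(is_debris), log(1.2e4), 0.35)
    ssc_h[is_debris] <- rlnorm(sum(is_debris), log(6e3), 0.35)
    fsc[is_doublet] <- fsc[is_doublet] * 1.7
    ssc_a <- ssc_h * ssc_ratio
    ssc_a[is_doublet] <- 2 * ssc_h[is_doublet] * rlnorm(sum(is_doublet), 0, 0.04)

    bfp_auto <- rlnorm(n, log(60), 0.8)
    rfp_auto <- rlnorm(n, log(8), 0.8)
    bfp <- bfp_auto
    rfp <- rfp_auto
    # doublets are cells too: they carry plasmid with the same probability
    expressing <- label == "transfected" |
      (label == "doublet" & runif(n) < cfg$transfected_fraction)
    ne <- sum(expressing)
    dose <- rlnorm(ne, cfg$bfp_log_mean, cfg$bfp_log_sd)
    dose[label[expressing] == "doublet"] <- 2 * dose[label[expressing] == "doublet"]
    sdlog <- .cv_to_sdlog(cfg$channel_noise_cv)
    bfp[expressing] <- bfp_auto[expressing] + dose
    rfp[expressing] <- rfp_auto[expressing] +
      cfg$dosage * dose * rlnorm(ne, 0, sdlog)

    out <- data.frame(fsc_a = fsc, ssc_a = ssc_a, ssc_h = ssc_h,
                      bfp = bfp, rfp = rfp, truth_label = label,
                      stringsAsFactors = FALSE)
    class(out) <- c("cell_event_table", "data.frame")
    attr(out, "truth") <- list(dosage = cfg$dosage, config = cfg)
    out
  })
}

#' Simulate a qPCR CT table
#'
#' Plants per-sample relative expression levels (vs a control sample, exactly
#' the 2^-ddCT scale) for one target gene against a reference gene, with
#' normal replicate noise on CT.  Amplification efficiency is exactly 2, so a
#' planted level `r` shifts the target CT by `-log2(r)` cycles.
#'
#' @param rel_true named numeric vector: planted relative expression of each
#'   non-control sample (control is 1 by definition).
#' @param replicates technical replicates per (sample, gene) (>= 2).
#' @param ct_sd replicate CT standard deviation, cycles (>= 0).
#' @param control_sample name of the control sample.
#' @param target_gene,ref_gene gene labels.
#' @param base_ct_target,base_ct_ref control-sample mean CTs.
#' @param seed RNG seed.
#' @return `data.frame` with columns `sample`, `gene`, `replicate`, `ct` and
#'   a `truth` attribute.
#' @export
simulate_qpcr <- function(rel_true, replicates = 4L, ct_sd = 0.2,
                          control_sample = "CMV", target_gene = "RFP",
                          ref_gene = "ref", base_ct_target = 20,
                          base_ct_ref = 18, seed = 1L) {
  if (is.null(names(rel_true)) || any(!nzchar(names(rel_true))))
    stop("rel_true must be a named vector")
  if (any(rel_true <= 0)) stop("planted relative expressions must be > 0")
  if (replicates < 2L) stop("replicates must be >= 2")
  if (ct_sd < 0) stop("ct_sd must be >= 0")
  samples <- c(control_sample, names(rel_true))
  rel <- c(1, unname(rel_true))
  with_seed(seed, {
    rows <- do.call(rbind, lapply(seq_along(samples), function(i) {
      data.frame(
        sample = samples[i],
        gene = rep(c(target_gene, ref_gene), each = replicates),
        replicate = rep(seq_len(replicates), 2L),
        ct = c(base_ct_target - log2(rel[i]) + rnorm(replicates, 0, ct_sd),
               base_ct_ref + rnorm(replicates, 0, ct_sd)),
        stringsAsFactors = FALSE)
    }))
    attr(rows, "truth") <- list(rel_true = setNames(rel, samples),
                                control_sample = control_sample)
    rows
  })
}

#' Configuration for a simulated expression batch
#'
#' Defaults emulate a transient 8-day batch: logistic growth of the viable
#' cell density, viability declining after the growth peak, and titer
#' accumulating in proportion to the integral of viable cell density with
#' specific productivity `qp_true` (the planted truth).
#'
#' @param days sampling grid, days post transfection.
#' @param vcd0,vcd_max initial and plateau viable cell density, cells/mL
#'   (`vcd0 < vcd_max`).
#' @param growth_rate logistic rate, 1/day; 0 gives the degenerate
#'   constant-VCD mode.
#' @param qp_true planted specific productivity, pg/cell/day (>= 0).
#' @param viability_decline percentage points of viability lost per day after
#'   the growth peak.
#' @param noise_cv multiplicative noise CV on VCD and titer.
#' @param seed RNG seed.
#' @return A config list of class `batch_sim_config`.
#' @export
batch_sim_config <- function(days = 0:8, vcd0 = 5e5, vcd_max = 8e6,
                             growth_rate = 0.9, qp_true = 2,
                             viability_decline = 3, noise_cv = 0.02,
                             seed = 1L) {
  if (length(days) < 2L || any(diff(days) <= 0)) stop("days must be increasing")
  .check_scalar(vcd0, "vcd0", lower = 0)
  .check_scalar(vcd_max, "vcd_max", lower = 0)
  if (growth_rate > 0 && vcd0 >= vcd_max) stop("vcd0 must be < vcd_max")
  .check_scalar(qp_true, "qp_true", lower = 0)
  .check_scalar(noise_cv, "noise_cv", lower = 0)
  structure(as.list(environment()), class = "batch_sim_config")
}

#' Simulate a batch-culture time series
#'
#' @param cfg a [batch_sim_config()].
#' @return `data.frame` of class `batch_series` with columns `day`, `vcd`,
#'   `viability`, `titer` and a `truth` attribute carrying `qp_true` and the
#'   noiseless curves.
#' @export
simulate_batch <- function(cfg = batch_sim_config()) {
  stopifnot(inherits(cfg, "batch_sim_config"))
  t <- cfg$days
  vcd_det <- if (cfg$growth_rate <= 0) rep(cfg$vcd0, length(t)) else
    cfg$vcd_max / (1 + ((cfg$vcd_max - cfg$vcd0) / cfg$vcd0) *
                     exp(-cfg$growth_rate * t))
  # trapezoidal IVCD of the deterministic curve, cell.days/mL
  ivcd <- c(0, cumsum(diff(t) * (head(vcd_det, -1) + tail(vcd_det, -1)) / 2))
  titer_det <- cfg$qp_true * ivcd * 1e-6     # pg/mL -> ug/mL
  t_peak <- if (cfg$growth_rate <= 0) max(t) else
    min(t[vcd_det >= 0.95 * cfg$vcd_max], max(t))
  viability <- pmax(0, pmin(100, 98 - cfg$viability_decline * pmax(0, t - t_peak)))
  with_seed(cfg$seed, {
    sdlog <- .cv_to_sdlog(cfg$noise_cv)
    # VCD carries iid measurement noise; titer noise acts on the daily
    # production increments (day-to-day biological variability), which keeps
    # accumulated titer nondecreasing
    titer_obs <- cumsum(c(titer_det[1],
                          diff(titer_det) * rlnorm(length(t) - 1L, 0, sdlog)))
    out <- data.frame(
      day = t,
      vcd = vcd_det * rlnorm(length(t), 0, sdlog),
      viability = viability,
      titer = titer_obs)
    class(out) <- c("batch_series", "data.frame")
    attr(out, "truth") <- list(qp_true = cfg$qp_true, vcd_det = vcd_det,
                               titer_det = titer_det, ivcd = ivcd, config = cfg)
    out
  })
}

#' Simulate a size-exclusion chromatogram
#'
#' Gaussian mixture on a linear baseline: peak areas are proportional to the
#' planted fractions, in elution order (HMW before the main peak, LMW after).
#'
#' @param fractions planted area percentages (normalized to 100).
#' @param centers peak centers, minutes (strictly increasing).
#' @param widths Gaussian SDs, minutes.
#' @param baseline_drift `c(intercept, slope_per_min)` of the linear baseline.
#' @param noise_sd additive absorbance noise SD.
#' @param total_area total peak area, a.u. * min.
#' @param time sampling grid, minutes.
#' @param seed RNG seed.
#' @return `data.frame` of class `chromatogram` with columns `time_min`,
#'   `a280` and a `truth` attribute.
#' @export
simulate_chromatogram <- function(fractions = c(5, 90, 5),
                                  centers = c(8, 12, 16),
                                  widths = rep(0.35, length(fractions)),
                                  baseline_drift = c(0.5, 0.01),
                                  noise_sd = 0.05, total_area = 100,
                                  time = seq(0, 30, by = 0.02), seed = 1L) {
  if (length(fractions) != length(centers) || length(centers) != length(widths))
    stop("fractions, centers and widths must have equal length")
  if (any(fractions < 0) || sum(fractions) <= 0) stop("invalid fractions")
  if (any(diff(centers) <= 0)) stop("centers must be strictly increasing")
  fr <- 100 * fractions / sum(fractions)
  with_seed(seed, {
    signal <- rowSums(vapply(seq_along(fr), function(i)
      total_area * fr[i] / 100 * dnorm(time, centers[i], widths[i]),
      numeric(length(time))))
    a280 <- signal + baseline_drift[1] + baseline_drift[2] * time +
      rnorm(length(time), 0, noise_sd)
    out <- data.frame(time_min = time, a280 = a280)
    class(out) <- c("chromatogram", "data.frame")
    attr(out, "truth") <- list(fractions = fr, centers = centers,
                               widths = widths)
    out
  })
}

# canonical migration coordinates for gel species (arbitrary lane units)
GEL_SPECIES_POSITIONS <- c(fs = 30, "2HC" = 48, "HC_LC" = 62, "HC" = 72, "LC" = 85)

#' Simulate gel-lane densitometry profiles
#'
#' Each lane is a sum of Gaussian bands at species-specific migration
#' positions over a smooth sloped background; band areas equal the planted
#' amounts.
#'
#' @param band_amounts named list: one named numeric vector of species
#'   amounts per lane, species drawn from
#'   `names(GEL_SPECIES_POSITIONS)`.
#' @param spread band Gaussian SD in migration units.
#' @param background background intensity level.
#' @param noise_sd additive intensity noise SD.
#' @param positions migration grid.
#' @param seed RNG seed.
#' @return List of class `lane_profile_set`: `lanes` (named list of
#'   `data.frame(position, intensity)`), `windows` (species integration
#'   windows) and `truth`.
#' @export
simulate_gel_lanes <- function(band_amounts, spread = 1.5, background = 2,
                               noise_sd = 0.02,
                               positions = seq(0, 100, by = 0.1), seed = 1L) {
  if (!is.list(band_amounts) || is.null(names(band_amounts)))
    stop("band_amounts must be a named list of named vectors")
  with_seed(seed, {
    lanes <- lapply(band_amounts, function(amts) {
      sp <- names(amts)
      bad <- setdiff(sp, names(GEL_SPECIES_POSITIONS))
      if (length(bad)) stop("unknown species: ", paste(bad, collapse = ","))
      sig <- background + 0.004 * positions
      for (s in sp)
        sig <- sig + amts[[s]] * dnorm(positions, GEL_SPECIES_POSITIONS[[s]], spread)
      data.frame(position = positions,
                 intensity = sig + rnorm(length(positions), 0, noise_sd))
    })
    species <- unique(unlist(lapply(band_amounts, names)))
    windows <- lapply(species, function(s)
      GEL_SPECIES_POSITIONS[[s]] + c(-4, 4) * spread)
    names(windows) <- species
    structure(list(lanes = lanes, windows = windows,
                   truth = list(band_amounts = band_amounts)),
              class = "lane_profile_set")
  })
}

#' Configuration for a simulated helper-factor dose response
#'
#' Emulates the saturating specific-activity curve and linearly declining
#' specific productivity observed when titrating a helper factor: activity
#' follows a continuous plateau model with a planted breakpoint, qP declines
#' linearly with helper level.
#'
#' @param sumf1_levels relative helper expression levels (fold of control).
#' @param breakpoint planted plateau onset on the level scale (within the
#'   level range).
#' @param activity_plateau planted plateau specific activity, U/mg (> 0).
#' @param qp_intercept,qp_slope planted qP line, pg/cell/day (per unit level
#'   for the slope).
#' @param noise_sd additive noise SD applied to activity (U/mg) and qP
#'   (pg/cell/day).
#' @param seed RNG seed.
#' @return A config list of class `dose_response_sim_config`.
#' @export
dose_response_sim_config <- function(sumf1_levels = seq(0.05, 1.2, length.out = 10),
                                     breakpoint = 0.4, activity_plateau = 4.5,
                                     qp_intercept = 2.0, qp_slope = 1.2,
                                     noise_sd = 0.15, seed = 1L) {
  if (length(sumf1_levels) < 2L || any(sumf1_levels <= 0))
    stop("sumf1_levels must be positive")
  if (breakpoint < min(sumf1_levels) || breakpoint > max(sumf1_levels))
    stop("breakpoint must lie within the level range")
  .check_scalar(activity_plateau, "activity_plateau", lower = 1e-12)
  .check_scalar(noise_sd, "noise_sd", lower = 0)
  structure(as.list(environment()), class = "dose_response_sim_config")
}

#' Simulate a helper-factor dose-response table
#'
#' @param cfg a [dose_response_sim_config()].
#' @return `data.frame` with columns `level`, `activity`, `qp` and a `truth`
#'   attribute.
#' @export
simulate_sumf1_dose_response <- function(cfg = dose_response_sim_config()) {
  stopifnot(inherits(cfg, "dose_response_sim_config"))
  with_seed(cfg$seed, {
    lv <- cfg$sumf1_levels
    act <- cfg$activity_plateau * pmin(lv / cfg$breakpoint, 1) +
      rnorm(length(lv), 0, cfg$noise_sd)
    qp <- cfg$qp_intercept - cfg$qp_slope * lv +
      rnorm(length(lv), 0, cfg$noise_sd)
    out <- data.frame(level = lv, activity = act, qp = qp)
    attr(out, "truth") <- list(breakpoint = cfg$breakpoint,
                               activity_plateau = cfg$activity_plateau,
                               qp_intercept = cfg$qp_intercept,
                               qp_slope = cfg$qp_slope, config = cfg)
    out
  })
}

#' Simulate a chromogenic sulfatase activity assay
#'
#' The enzyme converts its chromogenic substrate at a constant rate, so
#' product absorbance at 515 nm rises linearly in time.  The planted specific
#' activity (U/mg, U = umol product/min) and the protein concentration set
#' the slope through the product standard curve.
#'
#' @param specific_activity_true planted specific activity, U/mg.
#' @param protein_conc enzyme concentration in the assayed sample, mg/mL.
#' @param std_curve named vector `c(slope=, intercept=)`: A515 per nmol
#'   product, plus blank offset.
#' @param read_times reading times, minutes.
#' @param sample_volume sample volume in the reaction, mL.
#' @param noise_sd additive A515 noise SD (0 = noise-free).
#' @param seed RNG seed.
#' @return Object of class `activity_assay` (see [activity_assay()]) with a
#'   `truth` attribute.
#' @export
simulate_asa_assay <- function(specific_activity_true = 4.5,
                               protein_conc = 0.06,
                               std_curve = c(slope = 0.012, intercept = 0.04),
                               read_times = seq(0, 30, by = 5),
                               sample_volume = 0.1, noise_sd = 0, seed = 1L) {
  .check_scalar(specific_activity_true, "specific_activity_true", lower = 0)
  .check_scalar(protein_conc, "protein_conc", lower = 0)
  if (length(read_times) < 2L) stop("need at least 2 read times")
  with_seed(seed, {
    u_per_ml <- specific_activity_true * protein_conc
    rate_nmol_min <- u_per_ml * sample_volume * 1000   # nmol product / min
    a515 <- std_curve[["intercept"]] +
      std_curve[["slope"]] * rate_nmol_min * read_times +
      rnorm(length(read_times), 0, noise_sd)
    a <- activity_assay(std_curve = std_curve,
                        readings = data.frame(time_min = read_times, a515 = a515),
                        sample_volume = sample_volume,
                        protein_conc = protein_conc)
    attr(a, "truth") <- list(specific_activity = specific_activity_true,
                             u_per_ml = u_per_ml)
    a
  })
}
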