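# End-to-end orchestration of the three experiment templates over synthetic
# (or user-supplied) data:
#   reporter_panel - hairpin panel on a fluorescent reporter: flow FC panel,
#                    mRNA levels, dG regressions, Dunnett chain;
#   igg_hc_tuning  - heavy-chain tuning of an IgG: batches/qP, SEC fractions,
#                    gel band ratios;
#   sumf1_asa      - helper-factor titration: segmented dose response,
#                    sulfatase activity, qP.

REPORT_SCHEMA_VERSION <- "1.0"

# default six-element heavy-chain panel: translation dosages as fraction of
# the unregulated control, with representative stabilities (kcal/mol)
DEFAULT_HC_PANEL <- data.frame(
  name = c("RgE4", "RgE3", "RgE13", "RgE11", "RgE2", "RgE6"),
  dosage = c(0.05, 0.35, 0.50, 0.65, 0.85, 1.10),
  dg = c(-45, -33, -30, -25, -18, -8),
  mrna_fc = c(0.55, 0.90, 0.70, 0.80, 0.90, 1.00),
  stringsAsFactors = FALSE)

#' Experiment configuration
#'
#' @param experiment one of `"reporter_panel"`, `"igg_hc_tuning"`,
#'   `"sumf1_asa"`.
#' @param seed master seed; all stage seeds derive from it.
#' @param outdir optional directory for stage CSVs and the JSON report.
#' @param n_events flow events per simulated sample.
#' @param replicates biological replicates per element.
#' @param elements element table (`name`, `dosage`, `dg`, `mrna_fc`);
#'   defaults to the bundled six-element panel.
#' @param control_name control sample name.
#' @param verbose log stage progress to standard error.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(experiment = c("reporter_panel", "igg_hc_tuning",
                                             "sumf1_asa"),
                              seed = 1L, outdir = NULL, n_events = 20000L,
                              replicates = 3L, elements = DEFAULT_HC_PANEL,
                              control_name = "CMV", verbose = FALSE) {
  experiment <- match.arg(experiment)
  .check_scalar(seed, "seed")
  .check_scalar(n_events, "n_events", lower = 100)
  .check_scalar(replicates, "replicates", lower = 2)
  if (!all(c("name", "dosage", "dg", "mrna_fc") %in% names(elements)))
    stop("elements needs columns name, dosage, dg, mrna_fc")
  structure(list(experiment = experiment, seed = as.integer(seed),
                 outdir = outdir, n_events = as.integer(n_events),
                 replicates = as.integer(replicates), elements = elements,
                 control_name = control_name, verbose = verbose),
            class = "experiment_config")
}

.log_stage <- function(cfg, ...) {
  if (isTRUE(cfg$verbose)) message("[", cfg$experiment, "] ", ...)
}

# small deterministic seed streams derived from the master seed
.derive_seed <- function(seed, k) (as.integer(seed) * 1000L + as.integer(k)) %% .Machine$integer.max

.simulate_gated_fc_samples <- function(cfg) {
  els <- cfg$elements
  g <- gating_config()
  ref <- simulate_flow_sample(flow_sim_config(
    n_events = cfg$n_events, transfected_fraction = 0,
    seed = .derive_seed(cfg$seed, 999L)))
  gate <- function(dosage, k) {
    s <- simulate_flow_sample(flow_sim_config(
      n_events = cfg$n_events, dosage = dosage, seed = .derive_seed(cfg$seed, k)))
    gate_events(s, g, ref)
  }
  samples <- list()
  groups <- character(0)
  k <- 0L
  for (r in seq_len(cfg$replicates)) {
    nm <- sprintf("%s_r%d", cfg$control_name, r)
    samples[[nm]] <- gate(1, k <- k + 1L)
    groups[nm] <- cfg$control_name
  }
  for (i in seq_len(nrow(els))) for (r in seq_len(cfg$replicates)) {
    nm <- sprintf("%s_r%d", els$name[i], r)
    samples[[nm]] <- gate(els$dosage[i], k <- k + 1L)
    groups[nm] <- els$name[i]
  }
  list(samples = samples, groups = groups,
       control = sprintf("%s_r1", cfg$control_name))
}

.run_reporter_panel <- function(cfg) {
  els <- cfg$elements
  .log_stage(cfg, "simulating + gating ", (nrow(els) + 1) * cfg$replicates,
             " flow samples")
  fl <- .simulate_gated_fc_samples(cfg)
  panel <- fc_panel(fl$samples, fl$control, groups = fl$groups)
  gs <- attr(panel, "group_summary")
  mean_fc <- setNames(gs$mean_fc, gs$group)

  .log_stage(cfg, "fitting dG dose-response models")
  fc_el <- unname(mean_fc[els$name])
  lin <- fit_linear(els$dg, fc_el)
  logi <- fit_logistic4(els$dg, fc_el)

  .log_stage(cfg, "simulating qPCR and computing 2^-ddCT")
  rel_true <- setNames(els$mrna_fc, els$name)
  cts_rfp <- simulate_qpcr(rel_true, target_gene = "RFP",
                           control_sample = cfg$control_name,
                           seed = .derive_seed(cfg$seed, 2001L))
  cts_bfp <- simulate_qpcr(setNames(rep(1, nrow(els)), els$name),
                           target_gene = "BFP",
                           control_sample = cfg$control_name,
                           seed = .derive_seed(cfg$seed, 2002L))
  rel_rfp <- delta_delta_ct(cts_rfp, "RFP", "ref", cfg$control_name)
  rel_bfp <- delta_delta_ct(cts_bfp, "BFP", "ref", cfg$control_name)
  mrna <- mrna_ratio_fc(rel_rfp, rel_bfp, cfg$control_name)
  mrna_el <- setNames(mrna$fc_mrna, mrna$sample)[els$name]
  rp_ratio <- rna_protein_ratio(unname(mrna_el), fc_el)

  .log_stage(cfg, "testing chain (Levene/ANOVA/Dunnett)")
  groups_fc <- lapply(split(panel$fc, panel$group), unname)
  stats <- anova_dunnett(groups_fc, stat_config(control_name = cfg$control_name))

  list(panel = panel, group_summary = gs,
       fits = list(linear = lin, logistic4 = logi),
       mrna = mrna, rna_protein_ratio = setNames(rp_ratio, els$name),
       stats = stats,
       headline = list(
         fc = as.list(mean_fc),
         r2_linear = lin$r2, r2_logistic4 = logi$r2,
         fc_mrna = as.list(setNames(as.numeric(mrna_el), els$name)),
         anova_p = stats$anova_p,
         n_significant = sum(stats$comparisons$significant)))
}

# per-element product-quality truths for the IgG template: SEC fractions
# (HMW/main/LMW) and planted full-size:HC-dimer gel ratios
DEFAULT_IGG_QUALITY <- list(
  CMV   = list(sec = c(28, 59, 13), fs_2hc = 1.0, qp = 8),
  RgE4  = list(sec = c(5.5, 91.0, 3.5), fs_2hc = 11.9, qp = 14),
  RgE3  = list(sec = c(4.5, 92.5, 3.0), fs_2hc = 12.4, qp = 20),
  RgE13 = list(sec = c(12, 80, 8), fs_2hc = 4.2, qp = 12))

.run_igg_hc_tuning <- function(cfg) {
  qual <- DEFAULT_IGG_QUALITY
  .log_stage(cfg, "simulating batches")
  batches <- list(); qp <- numeric(0)
  for (i in seq_along(qual)) {
    nm <- names(qual)[i]
    b <- simulate_batch(batch_sim_config(qp_true = qual[[nm]]$qp,
                                         seed = .derive_seed(cfg$seed, 100L + i)))
    batches[[nm]] <- b
    qp[nm] <- specific_productivity(b)
  }
  .log_stage(cfg, "integrating SEC chromatograms")
  sec <- lapply(seq_along(qual), function(i) {
    ch <- simulate_chromatogram(fractions = qual[[i]]$sec,
                                seed = .derive_seed(cfg$seed, 200L + i))
    classify_peaks(integrate_chromatogram(ch))
  })
  names(sec) <- names(qual)
  mab_frac <- vapply(sec, function(p) p$fraction[p$klass == "mAb"], numeric(1))

  .log_stage(cfg, "quantifying gel lanes")
  amounts <- lapply(qual, function(q) c(fs = 10 * q$fs_2hc, "2HC" = 10))
  lanes <- simulate_gel_lanes(amounts, seed = .derive_seed(cfg$seed, 300L))
  ctrl <- lane_band_ratio(lanes$lanes[[cfg$control_name]], lanes$windows)
  band_fc <- vapply(names(qual), function(nm)
    lane_band_ratio(lanes$lanes[[nm]], lanes$windows,
                    control_ratio = ctrl$ratio)$fc, numeric(1))

  list(batches = batches, sec = sec, band_fc = band_fc, qp = qp,
       headline = list(qp = as.list(qp), mab_fraction = as.list(mab_frac),
                       fs_2hc_fc = as.list(band_fc)))
}

.run_sumf1_asa <- function(cfg) {
  .log_stage(cfg, "simulating helper-factor dose response")
  dr <- simulate_sumf1_dose_response(dose_response_sim_config(
    seed = .derive_seed(cfg$seed, 400L)))
  seg_est <- segmented_response(dr$level, dr$activity, mode = "estimate")
  seg_fix <- segmented_response(dr$level, dr$qp, split = 0.4, mode = "fixed")

  .log_stage(cfg, "simulating activity assay and batch")
  assay <- simulate_asa_assay(seed = .derive_seed(cfg$seed, 401L))
  act <- asa_activity(assay)
  batch <- simulate_batch(batch_sim_config(
    days = 0:8, vcd0 = 5e6, vcd_max = 5e6, growth_rate = 0, qp_true = 2,
    seed = .derive_seed(cfg$seed, 402L)))
  qp <- specific_productivity(batch)

  list(dose = dr, segmented = seg_est, fixed_split = seg_fix,
       activity = act, batch = batch, qp = qp,
       headline = list(breakpoint = seg_est$breakpoint,
                       plateau_activity = seg_est$plateau,
                       specific_activity_u_mg = act$u_per_mg,
                       qp_low_r2 = seg_fix$low$r2,
                       qp_asa_only = qp))
}

#' Run an experiment end to end
#'
#' Executes the stage chain for the configured experiment
#' (simulate/design -> quantify -> model -> test), optionally writing stage
#' CSVs and a machine-readable JSON report.  Reruns with the same config are
#' identical.
#'
#' @param cfg an [experiment_config()].
#' @return The report list (invisibly also written to
#'   `file.path(cfg$outdir, "report.json")` when `outdir` is set); element
#'   `headline` holds the scalar summary quantities, `stages` the full
#'   stage outputs.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  stages <- switch(cfg$experiment,
                   reporter_panel = .run_reporter_panel(cfg),
                   igg_hc_tuning = .run_igg_hc_tuning(cfg),
                   sumf1_asa = .run_sumf1_asa(cfg))
  report <- list(schema_version = REPORT_SCHEMA_VERSION,
                 experiment = cfg$experiment, seed = cfg$seed,
                 headline = stages$headline, stages = stages)
  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(schema_version = REPORT_SCHEMA_VERSION, experiment = cfg$experiment,
           seed = cfg$seed, headline = stages$headline),
      file.path(cfg$outdir, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(stages$panel))
      write.csv(stages$panel, file.path(cfg$outdir, "fc_panel.csv"),
                row.names = FALSE)
    if (!is.null(stages$mrna))
      write.csv(stages$mrna, file.path(cfg$outdir, "mrna_fc.csv"),
                row.names = FALSE)
    if (!is.null(stages$sec))
      for (nm in names(stages$sec))
        write.csv(stages$sec[[nm]],
                  file.path(cfg$outdir, paste0("sec_", nm, ".csv")),
                  row.names = FALSE)
    if (!is.null(stages$dose))
      write.csv(stages$dose, file.path(cfg$outdir, "dose_response.csv"),
                row.names = FALSE)
  }
  report
}

#' Write small bundled datasets for every experiment
#'
#' One compact dataset per experiment template, each sized so the full chain
#' runs in well under a minute, with a sidecar JSON carrying the planted
#' truth.
#'
#' @param dir output directory.
#' @param seed master seed.
#' @return Character vector of written files, invisibly.
#' @export
make_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  put <- function(obj, name, truth = NULL) {
    p <- file.path(dir, name)
    write.csv(obj, p, row.names = FALSE)
    written <<- c(written, p)
    if (!is.null(truth)) {
      tp <- file.path(dir, sub("\\.csv$", "_truth.json", name))
      jsonlite::write_json(truth, tp, auto_unbox = TRUE, digits = NA)
      written <<- c(written, tp)
    }
  }
  ev <- simulate_flow_sample(flow_sim_config(n_events = 2000L, dosage = 0.35,
                                             seed = .derive_seed(seed, 1L)))
  put(ev, "flow_events_rge3.csv", attr(ev, "truth")["dosage"])
  ctl <- simulate_flow_sample(flow_sim_config(n_events = 2000L, dosage = 1,
                                              seed = .derive_seed(seed, 2L)))
  put(ctl, "flow_events_cmv.csv", attr(ctl, "truth")["dosage"])
  ref <- simulate_flow_sample(flow_sim_config(n_events = 2000L,
                                              transfected_fraction = 0,
                                              seed = .derive_seed(seed, 3L)))
  put(ref, "flow_events_untransfected.csv")
  cts <- simulate_qpcr(c(RgE3 = 0.9, RgE4 = 0.55),
                       seed = .derive_seed(seed, 4L))
  put(cts, "qpcr_ct.csv", attr(cts, "truth"))
  b <- simulate_batch(batch_sim_config(seed = .derive_seed(seed, 5L)))
  put(b, "batch_series.csv", list(qp_true = attr(b, "truth")$qp_true))
  ch <- simulate_chromatogram(fractions = c(4.5, 92.5, 3.0),
                              time = seq(0, 30, by = 0.05),
                              seed = .derive_seed(seed, 6L))
  put(ch, "sec_chromatogram.csv", list(fractions = attr(ch, "truth")$fractions))
  dr <- simulate_sumf1_dose_response(dose_response_sim_config(
    seed = .derive_seed(seed, 7L)))
  put(dr, "sumf1_dose_response.csv", attr(dr, "truth")[c("breakpoint",
                                                         "activity_plateau")])
  invisible(written)
}
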