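# Ratiometric single-cell quantification: gating chain (scatter -> singlet
# -> BFP-positive), per-cell RFP/BFP ratio, geometric mean, fold change
# versus the unregulated control.

#' Gating configuration
#'
#' Rectangular scatter bounds for intact cells, a singlet band on the
#' SSC-A/SSC-H ratio around its robust median, and a BFP-positivity
#' threshold taken as a high quantile of an untransfected reference.  All
#' gates are overridable; the defaults bracket the populations produced by
#' [simulate_flow_sample()].
#'
#' @param fsc_min,fsc_max,ssc_min,ssc_max scatter bounds (FSC-A, SSC-A).
#' @param singlet_tol maximum relative deviation of `ssc_a/ssc_h` from the
#'   median ratio of scatter-gated events (> 0).
#' @param bfp_positive_quantile quantile of the untransfected reference BFP
#'   used as positivity threshold; must be in (0.5, 1).
#' @return A list of class `gating_config`.
#' @export
gating_config <- function(fsc_min = 2.5e4, fsc_max = 5e5,
                          ssc_min = 1e4, ssc_max = 2.5e5,
                          singlet_tol = 0.15, bfp_positive_quantile = 0.999) {
  .check_scalar(singlet_tol, "singlet_tol", lower = 1e-9)
  if (bfp_positive_quantile <= 0.5 || bfp_positive_quantile >= 1)
    stop("bfp_positive_quantile must be in (0.5, 1)")
  structure(list(fsc_min = fsc_min, fsc_max = fsc_max, ssc_min = ssc_min,
                 ssc_max = ssc_max, singlet_tol = singlet_tol,
                 bfp_positive_quantile = bfp_positive_quantile),
            class = "gating_config")
}

.check_event_table <- function(t, what = "event table") {
  need <- c("fsc_a", "ssc_a", "ssc_h", "bfp", "rfp")
  if (!is.data.frame(t) || !all(need %in% names(t)))
    stop(what, " must have columns ", paste(need, collapse = ", "))
  if (nrow(t) < 1L) stop(what, " is empty")
  if (!all(vapply(t[need], function(col) all(is.finite(col)), logical(1))))
    stop(what, " contains non-finite channel values")
  invisible(t)
}

#' Gate a flow-cytometry event table
#'
#' Applies, in order: the rectangular viability scatter gate, the
#' SSC-A/SSC-H singlet band, and the BFP-positivity threshold derived from
#' an untransfected reference sample.  Event order is preserved.
#'
#' @param t event table (see [simulate_flow_sample()] or [read_events_csv()]).
#' @param g a [gating_config()].
#' @param untransfected_ref untransfected reference event table supplying the
#'   BFP-positivity threshold.
#' @return The retained events, with attribute `gate_counts` giving the
#'   event count after each stage.
#' @export
gate_events <- function(t, g = gating_config(), untransfected_ref) {
  .check_event_table(t, "input")
  .check_event_table(untransfected_ref, "untransfected reference")
  stopifnot(inherits(g, "gating_config"))
  scatter <- t$fsc_a >= g$fsc_min & t$fsc_a <= g$fsc_max &
    t$ssc_a >= g$ssc_min & t$ssc_a <= g$ssc_max
  ratio <- t$ssc_a / t$ssc_h
  m <- median(ratio[scatter])
  singlet <- scatter & abs(ratio - m) <= g$singlet_tol * m
  thr <- quantile(untransfected_ref$bfp, g$bfp_positive_quantile,
                  names = FALSE, type = 7)
  positive <- singlet & t$bfp > thr
  counts <- c(input = nrow(t), scatter = sum(scatter),
              singlet = sum(singlet), bfp_positive = sum(positive))
  if (counts[["bfp_positive"]] == 0L)
    stop("empty gate: events per stage ",
         paste(names(counts), counts, sep = "=", collapse = ", "))
  out <- t[positive, , drop = FALSE]
  attr(out, "gate_counts") <- counts
  attr(out, "bfp_threshold") <- thr
  class(out) <- class(t)
  out
}

#' Ratiometric fold change of a gated sample versus a gated control
#'
#' Computes the per-cell ratio `r_i = rfp_i / bfp_i`, its geometric mean
#' `G = exp(mean(ln r_i))`, and the fold change `fc = G_sample / G_control`.
#' Events with nonpositive ratios are dropped (below-detection RFP), with a
#' warning when more than 5% are lost.
#'
#' @param sample,control gated event tables (the BFP-positivity gate
#'   guarantees `bfp > 0`).
#' @return A list of class `sample_quant`: `n_gated`, `n_dropped`,
#'   `geo_mean_ratio`, `control_geo_mean`, `fc`.
#' @export
ratiometric_fc <- function(sample, control) {
  g <- function(t, what) {
    .check_event_table(t, what)
    r <- t$rfp / t$bfp
    keep <- r > 0
    if (!any(keep)) stop("all per-cell ratios nonpositive in ", what)
    if (mean(!keep) > 0.05)
      warning(sprintf("%.1f%% of %s events dropped (nonpositive ratio)",
                      100 * mean(!keep), what))
    list(G = exp(mean(log(r[keep]))), n = sum(keep), dropped = sum(!keep))
  }
  gs <- g(sample, "sample"); gc <- g(control, "control")
  structure(list(n_gated = gs$n, n_dropped = gs$dropped,
                 geo_mean_ratio = gs$G, control_geo_mean = gc$G,
                 fc = gs$G / gc$G),
            class = "sample_quant")
}

#' @export
print.sample_quant <- function(x, ...) {
  cat(sprintf("<sample_quant> n=%d  geo-mean ratio=%.4g  FC=%.4g\n",
              x$n_gated, x$geo_mean_ratio, x$fc))
  invisible(x)
}

#' Fold-change panel across samples
#'
#' One row per sample with fold change relative to the named control;
#' samples are ordered by decreasing mean fold change (ties broken by name).
#' When a `groups` mapping is supplied (replicates of the same element), the
#' attribute `group_summary` carries per-group mean fold change and SEM.
#'
#' @param samples named list of gated event tables.
#' @param control_name name of the control entry in `samples`.
#' @param groups optional named character vector mapping sample name ->
#'   replicate group.
#' @return `data.frame` with columns `sample`, `n_gated`, `geo_mean_ratio`,
#'   `fc` (plus `group`), ordered by fold change.
#' @export
fc_panel <- function(samples, control_name, groups = NULL) {
  if (!control_name %in% names(samples))
    stop("control sample '", control_name, "' missing from panel")
  control <- samples[[control_name]]
  rows <- lapply(names(samples), function(nm) {
    q <- ratiometric_fc(samples[[nm]], control)
    data.frame(sample = nm, n_gated = q$n_gated,
               geo_mean_ratio = q$geo_mean_ratio, fc = q$fc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(groups)) out$group <- unname(groups[out$sample])
  ord <- order(-out$fc, out$sample)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(groups)) {
    sp <- split(out$fc, out$group)
    gs <- data.frame(group = names(sp),
                     mean_fc = vapply(sp, mean, numeric(1)),
                     sem = vapply(sp, function(x)
                       if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_,
                       numeric(1)),
                     n = vapply(sp, length, integer(1)),
                     stringsAsFactors = FALSE)
    gs <- gs[order(-gs$mean_fc, gs$group), , drop = FALSE]
    rownames(gs) <- NULL
    attr(out, "group_summary") <- gs
  }
  out
}

#' Read a flow-cytometry event table from CSV
#'
#' CSV fallback format with columns `fsc_a`, `ssc_a`, `ssc_h`, `bfp`, `rfp`
#' (and optionally `truth_label`).  FCS binary parsing is out of scope; export
#' tables from the acquisition software instead.
#'
#' @param path CSV file.
#' @return Event table of class `cell_event_table`.
#' @export
read_events_csv <- function(path) {
  t <- read.csv(path, stringsAsFactors = FALSE)
  .check_event_table(t, path)
  class(t) <- c("cell_event_table", "data.frame")
  t
}

#' Write a flow-cytometry event table to CSV
#' @param t event table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(t, path) {
  write.csv(t, path, row.names = FALSE)
  invisible(path)
}
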