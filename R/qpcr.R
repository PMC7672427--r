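# Relative mRNA quantification by the 2^-ddCT method.  Amplification
# efficiency is fixed at exactly 2 (no efficiency correction); replicate CTs
# are averaged arithmetically before differencing.

#' Relative expression by the 2^-ddCT method
#'
#' Replicate CTs are averaged per (sample, gene); `dCT = CT_target -
#' CT_ref`, `ddCT = dCT_sample - dCT_control`, `rel = 2^-ddCT`.  The control
#' sample gets `rel = 1` exactly.
#'
#' @param cts `data.frame` with columns `sample`, `gene`, `replicate`, `ct`
#'   (>= 2 replicates per sample/gene).
#' @param target_gene,ref_gene gene labels present for every sample.
#' @param control_sample the calibrator sample.
#' @return `data.frame` with columns `sample`, `ddct`, `rel`.
#' @examples
#' cts <- simulate_qpcr(c(RgE21 = 0.25), ct_sd = 0)
#' delta_delta_ct(cts, "RFP", "ref", "CMV")
#' @export
delta_delta_ct <- function(cts, target_gene, ref_gene, control_sample) {
  need <- c("sample", "gene", "replicate", "ct")
  if (!is.data.frame(cts) || !all(need %in% names(cts)))
    stop("cts must have columns ", paste(need, collapse = ", "))
  if (any(cts$ct <= 0 | cts$ct >= 45)) stop("CT values must be in (0, 45)")
  for (gn in c(target_gene, ref_gene))
    if (!gn %in% cts$gene) stop("gene not present: ", gn)
  samples <- unique(cts$sample)
  if (!control_sample %in% samples) stop("control sample not present: ", control_sample)
  mean_ct <- function(smp, gn) {
    x <- cts$ct[cts$sample == smp & cts$gene == gn]
    if (length(x) == 0L) stop("no CT values for sample ", smp, ", gene ", gn)
    if (length(x) < 2L) stop("fewer than 2 replicates for sample ", smp, ", gene ", gn)
    if (sd(x) > 0.5)
      warning(sprintf("replicate CT SD %.2f > 0.5 cycles (sample %s, gene %s)",
                      sd(x), smp, gn))
    mean(x)
  }
  dct <- vapply(samples, function(s)
    mean_ct(s, target_gene) - mean_ct(s, ref_gene), numeric(1))
  ddct <- dct - dct[[control_sample]]
  data.frame(sample = samples, ddct = unname(ddct), rel = unname(2^(-ddct)),
             stringsAsFactors = FALSE)
}

#' mRNA ratio fold change (two-reporter normalization)
#'
#' Per sample, the regulated-reporter mRNA level is normalized to the
#' co-expressed reference reporter and related to the control:
#' `fc = (rel_a/rel_b)_sample / (rel_a/rel_b)_control`.
#'
#' @param rel_a,rel_b outputs of [delta_delta_ct()] for the two reporters
#'   (e.g. RFP and BFP), matched by `sample`.
#' @param control_sample the calibrator sample.
#' @return `data.frame` with columns `sample`, `fc_mrna`.
#' @export
mrna_ratio_fc <- function(rel_a, rel_b, control_sample) {
  if (!setequal(rel_a$sample, rel_b$sample))
    stop("sample sets of the two reporters do not match")
  m <- merge(rel_a[c("sample", "rel")], rel_b[c("sample", "rel")],
             by = "sample", suffixes = c("_a", "_b"))
  if (!control_sample %in% m$sample) stop("control sample not present")
  ratio <- m$rel_a / m$rel_b
  fc <- ratio / ratio[m$sample == control_sample]
  data.frame(sample = m$sample, fc_mrna = fc, stringsAsFactors = FALSE)
}

#' RNA-to-protein fold-change ratio
#'
#' Ratio of the mRNA fold change to the protein fold change; values far above
#' 1 indicate that protein output dropped much more than transcript level,
#' i.e. regulation acted at translation.
#'
#' @param fc_mrna,fc_protein positive fold changes.
#' @return `fc_mrna / fc_protein` (vectorized).
#' @export
rna_protein_ratio <- function(fc_mrna, fc_protein) {
  if (any(fc_mrna <= 0) || any(fc_protein <= 0))
    stop("fold changes must be positive")
  fc_mrna / fc_protein
}
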