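# Generators: determinism, planted-truth bookkeeping, moment checks.

test_that("flow simulator is deterministic and labels partition the events", {
  cfg <- flow_sim_config(n_events = 5000, dosage = 0.3, seed = 42)
  a <- simulate_flow_sample(cfg)
  b <- simulate_flow_sample(cfg)
  expect_identical(a, b)
  expect_equal(nrow(a), 5000)
  expect_true(all(a$truth_label %in%
                    c("transfected", "untransfected", "debris", "doublet")))
  expect_true(all(is.finite(as.matrix(a[1:5]))))
  expect_error(flow_sim_config(debris_fraction = 0.7, doublet_fraction = 0.5),
               "exceed 1")
})

test_that("simulated BFP channel matches the configured lognormal moments", {
  cfg <- flow_sim_config(n_events = 40000, bfp_log_mean = log(2e4),
                         bfp_log_sd = 1.0, seed = 5)
  t <- simulate_flow_sample(cfg)
  lb <- log(t$bfp[t$truth_label == "transfected"])
  n <- length(lb)
  expect_gt(n, 1e4)
  # 3 SE band, plus a small allowance for the autofluorescence floor
  expect_lt(abs(mean(lb) - cfg$bfp_log_mean), 3 / sqrt(n) + 0.01)
  expect_lt(abs(sd(lb) - cfg$bfp_log_sd), 3 / sqrt(2 * n) + 0.01)
})

test_that("dosage-1 sample against a same-config control gives FC 1", {
  p <- gated_pair(dosage = 1, n = 20000, seed = 31)
  q <- ratiometric_fc(p$sample, p$control)
  expect_equal(q$fc, 1, tolerance = 0.02)
})

test_that("qPCR simulator plants exact CT offsets at zero noise", {
  cts <- simulate_qpcr(c(S = 0.25), ct_sd = 0, seed = 1)
  rel <- delta_delta_ct(cts, "RFP", "ref", "CMV")
  expect_equal(rel$rel[rel$sample == "S"], 0.25)   # 2-cycle offset exactly
  expect_equal(rel$rel[rel$sample == "CMV"], 1)
  expect_identical(simulate_qpcr(c(S = 0.25), seed = 9),
                   simulate_qpcr(c(S = 0.25), seed = 9))
  expect_error(simulate_qpcr(c(S = 0.25), ct_sd = -1), "ct_sd")
  expect_error(simulate_qpcr(c(0.25)), "named")
})

test_that("planted relative expression is recovered within CI at sd 0.2", {
  hits <- vapply(1:20, function(s) {
    cts <- simulate_qpcr(c(S = 0.25), replicates = 4, ct_sd = 0.2, seed = s)
    rel <- delta_delta_ct(cts, "RFP", "ref", "CMV")
    r <- rel$rel[rel$sample == "S"]
    # ddCT of 4 replicate pairs per gene: sd = 0.2 * 2 / sqrt(4) cycles
    abs(log2(r) - log2(0.25)) < 3 * 0.2 * 2 / sqrt(4)
  }, logical(1))
  expect_gt(mean(hits), 0.9)
})

test_that("batch simulator honors its closed forms", {
  flat <- simulate_batch(batch_sim_config(qp_true = 0, seed = 3))
  expect_true(all(flat$titer == 0))
  const <- simulate_batch(batch_sim_config(days = 0:6, vcd0 = 2e6,
                                           vcd_max = 2e6, growth_rate = 0,
                                           qp_true = 3, noise_cv = 0, seed = 1))
  expect_equal(const$titer, 3 * 2e6 * const$day * 1e-6)   # qp*VCD*t
  expect_identical(simulate_batch(batch_sim_config(seed = 8)),
                   simulate_batch(batch_sim_config(seed = 8)))
})

test_that("qP is recovered within 5% at noise_cv 0.02 across 20 seeds", {
  err <- vapply(1:20, function(s) {
    b <- simulate_batch(batch_sim_config(qp_true = 2, noise_cv = 0.02, seed = s))
    abs(specific_productivity(b) - 2) / 2
  }, numeric(1))
  expect_lt(max(err), 0.05)
})

test_that("chromatogram simulator plants recoverable areas", {
  ch <- simulate_chromatogram(fractions = c(5, 90, 5), seed = 2)
  pt <- integrate_chromatogram(ch)
  expect_equal(pt$fraction, c(5, 90, 5), tolerance = 0.5 / 5)  # 0.5% absolute
  single <- simulate_chromatogram(fractions = 100, centers = 12,
                                  widths = 0.4, seed = 1)
  expect_equal(integrate_chromatogram(single)$fraction, 100)
  expect_identical(simulate_chromatogram(seed = 4), simulate_chromatogram(seed = 4))
  expect_error(simulate_chromatogram(fractions = c(5, 90), centers = c(8, 12, 16)),
               "equal length")
})

test_that("gel-lane simulator plants recoverable band ratios", {
  lanes <- simulate_gel_lanes(list(eq = c(fs = 10, "2HC" = 10),
                                   skew = c(fs = 120, "2HC" = 10)), seed = 6)
  eq <- lane_band_ratio(lanes$lanes$eq, lanes$windows)
  expect_equal(eq$ratio, 1, tolerance = 0.02)
  skew <- lane_band_ratio(lanes$lanes$skew, lanes$windows)
  expect_equal(skew$ratio, 12, tolerance = 0.02)
  expect_identical(simulate_gel_lanes(list(a = c(fs = 1)), seed = 2),
                   simulate_gel_lanes(list(a = c(fs = 1)), seed = 2))
})

test_that("dose-response simulator is exact at zero noise and reproducible", {
  cfg <- dose_response_sim_config(noise_sd = 0, seed = 1)
  dr <- simulate_sumf1_dose_response(cfg)
  expect_equal(dr$activity,
               cfg$activity_plateau * pmin(dr$level / cfg$breakpoint, 1))
  expect_equal(dr$qp, cfg$qp_intercept - cfg$qp_slope * dr$level)
  expect_identical(simulate_sumf1_dose_response(dose_response_sim_config(seed = 3)),
                   simulate_sumf1_dose_response(dose_response_sim_config(seed = 3)))
  expect_error(dose_response_sim_config(breakpoint = 5), "within the level range")
})

test_that("activity assay simulator closes the loop with asa_activity", {
  a0 <- simulate_asa_assay(0, noise_sd = 0)
  expect_equal(asa_activity(a0)$u_per_ml, 0)
  a <- simulate_asa_assay(4.5, protein_conc = 0.06, noise_sd = 0)
  expect_equal(asa_activity(a)$u_per_mg, 4.5, tolerance = 1e-9)
  expect_identical(simulate_asa_assay(2, seed = 5, noise_sd = 0.01),
                   simulate_asa_assay(2, seed = 5, noise_sd = 0.01))
})
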