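# Shared fixture builders.  Everything is generated in code; no data files.

# random valid hairpin over WC + GU pairs, deterministic under the caller's
# RNG state
random_hairpin <- function(stem_len = sample(2:8, 1),
                           loop_len = sample(3:6, 1),
                           pairs = c("AU", "UA", "GC", "CG", "GU", "UG"),
                           name = "rand") {
  pt <- sample(pairs, stem_len, replace = TRUE)
  s5 <- substr(pt, 1, 1)
  s3r <- substr(pt, 2, 2)
  loop <- paste(sample(c("A", "C", "U"), loop_len, replace = TRUE),
                collapse = "")
  hairpin(name, paste(s5, collapse = ""), loop,
          paste(rev(s3r), collapse = ""))
}

# minimal event table with everything inside the default gates
inline_events <- function(bfp, rfp, fsc = 1e5, ssc = 5e4) {
  n <- max(length(bfp), length(rfp))
  structure(data.frame(fsc_a = rep(fsc, n), ssc_a = rep(ssc, n),
                       ssc_h = rep(ssc, n), bfp = bfp, rfp = rfp),
            class = c("cell_event_table", "data.frame"))
}

# gated sample/control pair from the simulator at a given dosage
gated_pair <- function(dosage, n = 30000L, seed = 7L) {
  ref <- simulate_flow_sample(flow_sim_config(
    n_events = n, transfected_fraction = 0, seed = seed + 900L))
  g <- gating_config()
  s <- gate_events(simulate_flow_sample(flow_sim_config(
    n_events = n, dosage = dosage, seed = seed)), g, ref)
  ctl <- gate_events(simulate_flow_sample(flow_sim_config(
    n_events = n, dosage = 1, seed = seed + 1L)), g, ref)
  list(sample = s, control = ctl)
}

# CT table rows for hand-constructed ddCT cases
ct_rows <- function(sample, gene, cts) {
  data.frame(sample = sample, gene = gene, replicate = seq_along(cts),
             ct = cts, stringsAsFactors = FALSE)
}
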