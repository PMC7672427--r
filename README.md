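# rgetune

Design and quantitative analysis of synthetic 5'-UTR RNA hairpins
("regulation elements", RgEs) used to tune protein translation in mammalian
cell factories.

## The problem

A stem-loop placed between the 5'-cap and the start codon attenuates
translation initiation in proportion to its thermodynamic stability, with
the stem GC-content and cap-relative position as secondary dials.  A panel
of such elements spans expression from ~2% to ~110% of an unregulated CMV
control in CHO and HEK293 cells, which makes them a practical tool for two
classic cell-engineering problems: lowering IgG heavy-chain expression to
improve assembly (titer and fewer aggregates/fragments), and titrating a
helper factor (SUMF1, required for active arylsulfatase A) to the minimum
level that saturates product activity.

`rgetune` implements the full workflow for scientists using such elements:

| Layer | Functions |
|---|---|
| Hairpin design | `hairpin()`, `hairpin_mfe()`, `enumerate_mfe()` (brute-force oracle), `design_stem()`, `place_element()` |
| Synthetic data with planted truth | `simulate_flow_sample()`, `simulate_qpcr()`, `simulate_batch()`, `simulate_chromatogram()`, `simulate_gel_lanes()`, `simulate_sumf1_dose_response()`, `simulate_asa_assay()` |
| Flow quantification | `gate_events()`, `ratiometric_fc()`, `fc_panel()` |
| mRNA quantification | `delta_delta_ct()`, `mrna_ratio_fc()`, `rna_protein_ratio()` |
| Product quality | `integrate_chromatogram()`, `classify_peaks()`, `lane_band_ratio()`, `sumf1_relative_level()` |
| Bioprocess | `cumulative_cell_days()`, `specific_productivity()`, `protein_conc_a280()`, `asa_activity()` |
| Models & statistics | `fit_linear()`, `fit_logistic4()`, `segmented_response()`, `gc_pair_differential()`, `anova_dunnett()` |
| Orchestration | `run_experiment()`, `make_fixtures()`, `inst/cli/rgetune-cli.R` |

The core quantities, in the field's notation:

* hairpin free energy (reduced nearest-neighbor model, 37 °C):
  `ΔG = Σ stacks + ΔG_loop(n) + n_AU/GU-ends · 0.45` kcal/mol, clipped at 0;
* per-cell ratiometric fold change:
  `FC = exp(mean ln(RFP_i/BFP_i))_sample / exp(mean ln(RFP_i/BFP_i))_control`;
* relative mRNA level: `rel = 2^−ΔΔCT`;
* specific productivity: `qP = Δtiter · 10^6 / ∫VCD dt` pg/cell/day;
* segmented dose response: `response = c · min(level, τ)/τ` with grid-searched
  breakpoint τ.

## Worked example

Design a strong high-GC stem, verify it against the enumeration oracle, and
recover a planted translation dosage from simulated flow cytometry:

```r
library(rgetune)

h <- design_stem(-33, "high", tol = 0.5, seed = 7, name = "el_strong")
h
#> <hairpin> el_strong  (+15, stem 13 bp, loop 4 nt)
#>   GGGGCCGGGGCCCGAAAGGGCCCCGGCCCC
#>   (((((((((((((....)))))))))))))
hairpin_property_table(list(h))
#>        name dg_kcal_mol gc_fraction gc_class position
#> 1 el_strong      -32.94           1     high       15
```

The designed element folds to −32.94 kcal/mol, within 0.5 kcal/mol of the
−33 target, with an all-GC (class "high") stem at the default +15 position.
For short sequences the exhaustive oracle returns the global minimum over
*all* nested structures, which bounds the designed fold from below.

```r
ref <- simulate_flow_sample(flow_sim_config(n_events = 50000,
                                            transfected_fraction = 0, seed = 99))
g   <- gating_config()
ctl <- gate_events(simulate_flow_sample(flow_sim_config(n_events = 50000,
                                        dosage = 1,    seed = 1)), g, ref)
smp <- gate_events(simulate_flow_sample(flow_sim_config(n_events = 50000,
                                        dosage = 0.35, seed = 2)), g, ref)
ratiometric_fc(smp, ctl)
#> <sample_quant> n=23784  geo-mean ratio=0.348  FC=0.3505
```

The pipeline recovers the planted dosage of 0.35 as FC = 0.3505 (0.1%
relative error) from 23,784 gated transfected singlets: the gating chain
removed debris, doublets and untransfected events, and the per-cell
geometric-mean ratio cancels the ~70-fold cell-to-cell transfection-dose
spread on the BFP normalization channel.

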