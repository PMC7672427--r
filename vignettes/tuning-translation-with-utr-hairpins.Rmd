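---
title: "Tuning translation with 5'-UTR hairpins: models, assumptions and design choices"
author: "rgetune"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tuning translation with 5'-UTR hairpins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Placing a defined RNA stem-loop ("regulation element", RgE) between the
5'-cap and the start codon of an mRNA attenuates translation initiation:
the scanning machinery must unwind the structure, and the residual
translation rate falls with the hairpin's thermodynamic stability.  Three
design properties control the effect — the minimum free energy (MFE,
$\Delta G$ in kcal/mol at 37 °C), the GC-content of the stem, and the
position of the first stem nucleotide relative to the cap (+1).  A panel of
such elements spans roughly two orders of magnitude of expression in CHO and
HEK293 cells, which makes them a practical dial for balancing the subunits
of multimeric products (e.g. IgG heavy chain) or the dose of helper factors
(e.g. SUMF1 for arylsulfatase A).

`rgetune` implements the complete quantitative workflow around these
elements: hairpin design properties with an enumeration oracle, single-cell
ratiometric quantification, relative mRNA levels, product-quality signals,
bioprocess metrics, dose-response models and the hypothesis-testing chain —
plus seeded synthetic-data generators with planted ground truth for every
input, since the original raw data are not deposited.

## The energy model

`hairpin_mfe()` scores a stem-loop with a reduced nearest-neighbor model:

$$\Delta G = \sum_{i} \Delta G^{stack}_{(p_i, p_{i+1})}
  + \Delta G^{loop}(n_{loop}) + n_{AU/GU\ ends} \cdot \Delta G^{end}$$

* **Stacks**: a 6x6 doublet table over pair types (AU, UA, GC, CG, GU, UG),
  embedding a published Watson-Crick set (all $\le 0$) and approximate GU
  wobble values, symmetric under 180° rotation.
* **Hairpin-loop initiation**: tabulated for loop sizes 3–30 nt
  (5.4 kcal/mol at size 3), extended beyond 30 by the Jacobson–Stockmayer
  form $1.75\,RT\ln(n/30)$ with $RT = 0.6163$ kcal/mol at 37 °C.
* **Helix ends**: +0.45 kcal/mol per terminal AU/UA/GU/UG pair, applied at
  the helix base and at the loop-closing pair.
* The unfolded chain is the zero reference, so totals are clipped at 0.

Deliberate exclusions: tetraloop bonuses, dangling ends, coaxial stacking,
and initiation terms for interior/bulge/multibranch loops.  Absolute values
therefore *approximate but do not equal* full-featured folding servers; what
matters for this package is that the model is small, self-contained, and
exactly verifiable.

**The oracle.** `enumerate_mfe()` enumerates *every* nested structure of a
short sequence (cap 25 nt, minimum hairpin loop 3) by brute-force recursion
in C++ and scores each complete structure with the same tables — a code path
independent of the R-side designed-fold walk.  Ties break toward fewer pairs,
then the lexicographically smallest dot-bracket.  Because the reduced model
gives non-hairpin loops no initiation penalty, the enumerated minimum can
only be *lower* than the designed fold's energy, so the oracle bound
`enumerate_mfe ≤ hairpin_mfe` is conservative; equality is asserted whenever
the enumerated argmin *is* the designed fold.  A third route,
`structure_dg()`, scores arbitrary dot-brackets in R and cross-checks the
C++ evaluation.

**Coordinates and placement.** Transcript coordinates are 1-based with the
cap at +1; an element's position is its first stem nucleotide.  The default
cloning site sits at +15; positions beyond it are reached with unstructured
5'-CAA-3' spacer repeats (so offsets must be multiples of 3), positions
before it by truncating the leader.  The bundled 14-nt leader is a
*synthetic stand-in* (AU-rich, structure-free) — the real vector leader is
not distributed with the package.  Cloning overhangs must be trimmed before
scoring; only stem and loop enter the MFE.

**design_stem().** Searches stem lengths in ascending order, sampling
Watson-Crick pair compositions whose GC-pair count keeps the stem GC
fraction strictly inside the requested class band (low < 0.40,
high > 0.75), and returns the first stem within `tol` (default
0.5 kcal/mol) of the target.  The search is seeded and deterministic; GU
pairs are excluded from designed stems so the GC fraction is exact by
construction.  Infeasible targets fail with an explicit error.

## What the synthetic data emulate — and what they do not

Every generator plants its ground truth in a `truth` attribute and is
byte-reproducible under `seed`.  Noise magnitudes are package choices (the
study reports no variance components); all are surfaced as config defaults.

* **Flow cytometry** (`simulate_flow_sample()`): 150,000 events by default.
  Transfected singlets draw a lognormal plasmid dose on the BFP channel
  (log-mean log(2e4), log-sd 1.0 — broad transient-transfection
  heterogeneity); RFP is `dosage × dose` with 25% CV multiplicative
  measurement noise on top of a small autofluorescence floor (log-mean
  log(8)).  Untransfected cells carry autofluorescence only, with the BFP
  floor (log-mean log(60), log-sd 0.8) deliberately overlapping the gate
  boundary so gating is nontrivial.  Debris (8%) sits at low scatter;
  doublets (5%) have SSC-A near twice SSC-H and doubled dose.  *Not*
  emulated: spectral spillover, instrument drift, time gates, FCS metadata.
  A green recovery test therefore establishes correctness of the gating and
  geometric-mean arithmetic under this stated world, not robustness to
  compensation errors.
* **qPCR** (`simulate_qpcr()`): CT values normal around means consistent
  with the planted relative expression at amplification efficiency exactly
  2; replicate SD 0.2 cycles by default.
* **Batch culture** (`simulate_batch()`): logistic VCD (5e5 → 8e6 cells/mL,
  rate 0.9/day), viability declining 3 %-points/day after the growth peak,
  titer accumulating as `qP × IVCD`.  VCD carries iid multiplicative
  measurement noise (CV 2%); titer noise acts on the *daily increments*
  (day-to-day production variability), which keeps accumulated titer
  nondecreasing — iid noise on the cumulative titer would violate that
  invariant near plateau and inflate endpoint-qP error beyond its stated
  recovery band.
* **SEC / gels** (`simulate_chromatogram()`, `simulate_gel_lanes()`):
  Gaussian mixtures with areas equal to the planted fractions on a linear
  baseline (drift 0.01 a.u./min) with additive noise; bands at fixed
  migration coordinates over a gently sloped background.
* **Helper-factor dose response** (`simulate_sumf1_dose_response()`):
  activity follows the continuous plateau model
  `plateau × min(level/breakpoint, 1)` (defaults: plateau 4.5 U/mg,
  breakpoint 0.4), qP declines linearly (2.0 − 1.2 × level pg/cell/day),
  both with additive noise (SD 0.15).
* **Activity assay** (`simulate_asa_assay()`): A515 rises linearly at the
  rate implied by the planted specific activity through the product standard
  curve; noise-free mode closes the loop with `asa_activity()` exactly.

## Quantification conventions

* **Ratiometric FC**: per-cell `r = RFP/BFP` on gated events, geometric mean
  in log space, FC versus the control's geometric mean.  Nonpositive ratios
  are *dropped*, not shifted — the BFP-positivity gate guarantees `BFP > 0`,
  and `RFP ≤ 0` is below detection; >5% drops warn, 100% errors.  Default
  gates: rectangular scatter bounds, SSC-A/SSC-H within 15% of the robust
  median ratio, BFP above the 0.999 quantile of an untransfected reference.
  No spectral compensation (two well-separated channels).
* **2^-ddCT**: replicate CTs averaged arithmetically *before* differencing
  (standard practice; averaging replicate rel values instead differs only in
  second order), efficiency fixed at 2, no efficiency correction.
* **SEC integration**: linear baseline fitted to the flanking 15% of points
  with iterative clipping of high outliers (a peak tail in a flank cannot
  drag the fit; symmetric noise stays in, keeping the fit unbiased); peak
  detection on a lightly smoothed copy above max(2% of max, 5x noise MAD);
  boundaries valley-to-valley — manual-integration practice, robust, no
  Gaussian deconvolution; trapezoidal areas normalized to 100%.
* **Densitometry**: band background by linear interpolation between window
  edges (deterministic and testable, unlike rolling-ball); detection floor
  3x the MAD of the detrended off-band signal; a denominator band below the
  floor reports a *missing* ratio, never infinity.
* **Helper-factor level**: each compartment normalized to the 55 kDa ladder
  band, lysate then to harvest-day VCD, supernatant to cumulative cell days
  (secreted factor accumulates); compartments *summed* by default (the
  original combination rule is ambiguous; `combine = "mean"` is offered and
  gives identical ratios when both samples share the rule).
* **Bioprocess**: IVCD by trapezoid; qP over the full batch window
  (end − start titer), matching a single end-of-batch readout, with a
  per-interval mode as an option; U = µmol/min.

## Models and statistics

* **MFE → FC**: OLS for the headline R²; a 4-parameter logistic in
  $\Delta G$, `d + (a−d)/(1+exp((ΔG−g50)/b))`, for the saturating shape —
  the original nonlinear form is unspecified, and the logistic is the
  field's default for sigmoid dose response; fitted by multistart
  Nelder-Mead + BFGS including a near-linear start, so its SSE never
  exceeds the linear fit's where both converge.
* **Segmented response**: fixed split at 0.4-fold (OLS per group) and an
  estimate mode grid-searching the continuous plateau model over the
  observed levels plus 100 uniform candidates; the plateau height has a
  closed form per candidate.
* **Testing chain**: Levene (mean-centered) → one-way ANOVA → Dunnett
  many-to-one at family-wise α = 0.05, flags n.s. / # (<0.1) / * / ** / ***.
  Adjusted p-values use the multivariate-t formulation (mvtnorm) when
  available; otherwise a seeded Monte-Carlo null of max |t| (1e5 draws,
  memoized per design).  Type-I error is property-tested at ≤ 0.06 over
  2000 null panels.

## Numerical choices and degenerate inputs

Zero-length IVCD intervals return 0 (strictly reversed bounds error); zero
IVCD errors on division; negative fitted assay rates clamp to 0 with a
warning; saturated flat-top chromatogram peaks warn; equal-area main-peak
ties classify to earlier elution with a warning; DNA input is transcribed
(T→U) and uppercased everywhere; all simulators restore the caller's RNG
state.

## Known limitations

FCS binary files are not parsed (CSV event tables only); kissing-hairpin
loop–loop energetics are not modeled — tandem hairpins are representable
only as two independent stems; no pseudoknots, partition functions, or
full-length mRNA folding; no fed-batch feeding models; no image processing
of gel photographs (lane profiles are inputs).  Every empirical number
quoted in the package's documentation is computed by the test suite or the
acceptance script — nothing is asserted that the code does not itself
reproduce.
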