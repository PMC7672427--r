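Package: rgetune
Title: Design and Quantitative Analysis of 5'-UTR Hairpin Translation Tuning
Version: 1.0.0
Authors@R:
    person("Robin", "Geller", email = "rgetune@fastmail.com", role = c("aut", "cre"))
Description: Toolbox for tuning protein translation in mammalian cell factories
    with synthetic stem-loop RNA elements placed in the 5'-UTR. Computes hairpin
    design properties (nearest-neighbor free energy, stem GC-content,
    cap-relative position) with an exhaustive-enumeration folding oracle,
    quantifies expression by ratiometric flow cytometry (gating, per-cell
    RFP/BFP ratio, geometric-mean fold change), relative mRNA levels by the
    2^-ddCt method, product quality from size-exclusion chromatograms and gel
    densitometry, bioprocess metrics (integral viable cell density, specific
    productivity, arylsulfatase activity), and fits dose-response models
    (linear, four-parameter logistic, segmented plateau) with a
    Levene/ANOVA/Dunnett testing chain. Ships seeded synthetic-data generators
    with planted ground truth for every input it consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mvtnorm,
    Biostrings,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
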