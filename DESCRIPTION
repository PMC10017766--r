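Package: ecmscan
Title: Quantification of ECM Remodeling, Cell Behavior and Mechanics on
    Decellularized Muscle Scaffolds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying extracellular-matrix (ECM) remodeling
    experiments on decellularized skeletal-muscle sections (myoscaffolds).
    Implements line-scan segmentation of endomysial fluorescence profiles
    into basement-membrane and interstitial-matrix regions with per-region
    protein abundance and stoichiometry (basal scaling, zero-phase
    Butterworth smoothing, two-peak detection, single/double Gaussian
    fitting with BIC model selection, mean +/- 2 SD segment points,
    trapezoidal area under the curve); the remodeling index comparing
    cell-seeded to control scaffolds; cell motility, adhesion retention and
    myotube fusion efficiency from fixed-interval tracks and nuclei/region
    fields; and Hertz-Sneddon force-curve analysis of atomic force
    microscopy data (contact-point detection, Young's modulus, rupture
    force). A synthetic-data module generates every input class with stored
    ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    signal,
    minpack.lm,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
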