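Package: phaseseed
Title: Seed-Phase Dual-Space Phasing of Centrosymmetric Small-Molecule Crystal Structures
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ab initio phasing toolkit for centrosymmetric (P2(1)/c) small-molecule
    crystal structures. Provides a synthetic ground-truth structure generator,
    structure-factor and normalized-E machinery with Laue 2/m orbit reduction and
    systematic-absence handling, seed-phase providers and quality metrics, a
    direct-methods engine with triplet invariants and a prior-weighted tangent
    formula that folds externally supplied seed phases into the phase estimate,
    dual-space electron-density-modification phase extension, origin-searched
    agreement metrics (mean phase error, map correlation, R factor), and a
    statistical evaluation harness (two-means solvability clustering, silhouettes,
    efficiency with propagated uncertainty, random-forest classification with
    ROC-constrained thresholding, and resolution cut-off benchmarks).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    randomForest,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
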