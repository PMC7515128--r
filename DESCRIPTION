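Package: morfmlp
Title: Per-Residue Prediction of Molecular Recognition Features with
    Ensemble Multi-Layer Perceptrons
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts molecular recognition features (MoRFs) -- short
    segments of intrinsically disordered protein regions that fold upon
    binding -- at per-residue resolution.  Sequences are turned into
    multi-window pooled features from amino-acid property scales and a
    topological-entropy complexity measure, and, when PSI-BLAST ASCII
    PSSM profiles are available, into pooled evolutionary-profile
    features.  Two small ensemble multi-layer perceptrons (one per
    feature branch) are trained with dropout and Adam on balanced
    subsamples, their scores fused by a naive-Bayes posterior rule, and
    performance assessed with ROC curves, AUC and FPR-at-fixed-TPR
    operating points.  A synthetic fixture generator with a planted,
    tunable MoRF signal allows the complete train/predict/evaluate
    pipeline to run without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
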