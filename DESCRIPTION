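Package: CornealKG
Title: Explainable Knowledge-Graph Reasoning for Corneal Topography and
    Early Keratoconus Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for interpretable corneal biometry analysis: a per-eye
    biometric data model with triplicate-scan median aggregation and
    quality-control filters, a seeded synthetic cohort simulator calibrated
    to published IOLMaster-style summary statistics (including rendered
    axial-curvature maps), a symbolic corneal knowledge graph with
    threshold-rule edges, noisy-OR Bayesian inference producing keratoconus
    posteriors and refractive-surgery eligibility decisions with full
    machine-readable reasoning traces, a compact convolutional-transformer
    map encoder with contrastive feature-to-knowledge alignment,
    deterministic bilingual physician and patient report generation, and a
    cross-validated evaluation harness with ROC/AUC, bootstrap confidence
    intervals and Cohen's kappa.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    igraph
Suggests:
    testthat (>= 3.0.0),
    pROC,
    e1071,
    png,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'CornealKG-package.R'
    'biometry.R'
    'map-indices.R'
    'nn.R'
    'encoder.R'
    'knowledge-graph.R'
    'inference.R'
    'evaluation.R'
    'reporting.R'
    'cohort.R'
    'cli.R'
    'utils.R'
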