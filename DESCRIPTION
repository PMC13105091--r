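Package: loraxr
Title: Odorant-Receptor Affinity Prediction with LoRA-Adapted Cross-Attention Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting odorant-receptor binding affinity and for
    benchmarking molecular representations against that task. Provides loaders
    and schemas for odorant-receptor interaction panels (full-factorial
    electrophysiology panels and sparse binary screens), a registry of molecule
    and protein featurizers, angular orthogonal-Procrustes and CCA
    dissimilarity metrics between representation spaces, per-receptor and
    concatenated ridge-regression baselines, a multi-modal cross-attention
    transformer with low-rank (LoRA) adapters on the chemical encoder trained
    in two stages with a weighted gradient-boosted-tree ensemble, evaluation
    utilities (entity-disjoint cross-validation splits, regression and
    classification metrics, statistical model comparison), and synthetic-data
    generators with planted interaction structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    xgboost,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
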