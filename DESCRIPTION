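Package: glycobind
Title: Prediction of Protein-Carbohydrate Binding Residues from Structure,
    Profile and Language-Model Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates carbohydrate-binding residues in protein structures by
    a heavy-atom distance rule, extracts the per-residue feature system used
    for binding-site prediction (a 36-dimensional geometric descriptor,
    PSSM-derived evolutionary features, physicochemical properties,
    residue-window index encodings and ingested protein language-model
    embeddings), performs group-level feature selection, and trains a
    two-branch residual-convolutional / feed-forward neural network under
    five class-imbalance strategies combined into a 2:1:1 weighted ensemble.
    Includes a synthetic-data generator so the full pipeline is testable at
    desk scale, and a standard binary-classification metrics suite
    (sensitivity, specificity, balanced accuracy, MCC, AUC, AUPR).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    Biostrings,
    car,
    e1071,
    glmnet,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
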