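Package: acpkit
Title: Anticancer Peptide Classification with Boundary-Aware Resampling
    and Residue-Level Attribution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A toolkit for anticancer peptide (ACP) classification from
    sequence. Provides FASTA input with validation and length filtering,
    classical peptide feature encoders (amino-acid composition, dipeptide
    composition, pseudo amino-acid composition, CTD), a deterministic
    per-residue embedding backend contract, adaptive neighborhood-based
    sampling (ANBS) and reference ADASYN for class-imbalance correction,
    a soft-voting ensemble of tree learners, a six-metric evaluation
    protocol with ROC/AUC and stratified cross-validation, and SHAP-Res
    residue-level attribution that projects global SHAP weights onto
    per-residue embeddings. Synthetic-data generators make the full
    pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    randomForest,
    stats,
    utils,
    xgboost,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
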