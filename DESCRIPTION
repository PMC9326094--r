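Package: netscope
Title: Quantification of Neutrophil Extracellular Traps in Equine Bronchoalveolar Lavage
Version: 0.1.0
Authors@R:
    person("BALF", "Imaging Group", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify neutrophil extracellular traps (NETs) in
    bronchoalveolar lavage fluid (BALF) of horses. Implements image-based
    NETs-area scoring from three-channel fluorescence cytospin fields
    (DAPI/MPO/Cit-H3 colocalization), PicoGreen cell-free DNA and MPO-DNA
    ELISA quantification with standard-curve calibration, clinical phenotype
    classification of equine asthma (severe/moderate/healthy) from BALF
    differential cytology and physical-exam findings, and the accompanying
    statistics layer (normality-dispatched group comparisons, Spearman
    correlation, empirical ROC/AUC). A synthetic-data module generates
    ground-truthed cytospin-like images and cohort measurement tables so the
    entire pipeline is testable without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
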