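Package: glycosig
Title: Glycan-Signature Analysis of Tumor Cell Subpopulations and Blood Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multiplexed glycan immunofluorescence of
    pancreatic ductal adenocarcinoma (PDAC). Converts per-cell fraction-positive
    measurements for a panel of glycan stains into four-digit binary glycan
    signature codes via classification-tree threshold selection, tests
    signature-histology association with a cluster-adjusted rank-sum test and
    specimen-bootstrap odds ratios, segments tissue into signature-coded
    regions of interest by kernel density overlap, quantifies intratumoral
    heterogeneity with a categorical Gini index and between-cluster dispersion,
    builds stepwise glycan-accumulation lineage graphs, and evaluates a
    hybrid sandwich blood-assay panel combined at a specificity-anchored
    cutoff. Includes a seedable synthetic cohort generator emulating the
    statistical structure of such studies so every stage is testable without
    primary data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    rpart,
    survival,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
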