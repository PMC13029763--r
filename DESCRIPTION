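Package: nutrascreen
Title: Ligand-Based Screening of Food Chemical Space Against a Metabolic Enzyme Target
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, seed-reproducible pipeline for ligand-based virtual
    screening of food-associated small molecules against an enzyme bioactivity
    dataset. Covers curation of concentration-based activity records to pIC50
    labels, structure canonicalization and deduplication, Bemis-Murcko
    scaffold-grouped data splitting, circular-fingerprint classification with
    seeded tuning and out-of-fold evaluation, probability calibration and
    MCC-optimal thresholding, Tanimoto applicability-domain analysis with
    stratified error reporting, feature attribution mapped back to atom-centred
    substructures, R-group series summaries, and ensemble library screening
    with Butina diversity selection. A synthetic-data module with planted
    substituent effects provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    stats,
    utils,
    jsonlite,
    digest,
    ranger,
    glmnet,
    xgboost,
    igraph,
    MASS,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
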