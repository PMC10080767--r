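Package: mhamfd
Title: Health-Insurance Fraud Detection with Hierarchical Graph Attention
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects health-insurance fraud from tabular medical claim
    records by modelling patients, visit dates, departments and medicines
    as an attributed heterogeneous information network, decomposing it
    into patient-patient behavioural-relationship graphs (shared
    department, date and/or medicine within a joint visit), and training
    a semi-supervised three-tier attention network (neighbour-level
    multi-head attention, relation-level attention within each level,
    and level-level attention) whose attention weights make the fitted
    model interpretable. Includes a synthetic claim generator with
    planted fraud rings, stratified node splits, early-stopped Adam
    training with hand-derived gradients, evaluation metrics, and a
    fraud-lift neighbour analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
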