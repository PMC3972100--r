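Package: HSAbind
Title: Structure-Based Prediction of Small-Molecule Binding to Human Serum Albumin
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for predicting the extent of small-molecule binding to human
    serum albumin (HSA) from structure. Implements ensemble docking score
    aggregation over the two major xenobiotic sites (site I, the warfarin site,
    and site II, the indole/benzodiazepine site), a combined linear score over
    the best docking score and an atomic-contribution logP, fraction-bound
    equilibrium algebra, binder/weak-binder classification, site-preference
    assignment from the site II minus site I score difference, and ROC-based
    evaluation of ranked predictions. Docking backends are pluggable: scores can
    be replayed from tables or produced by an external engine. A seeded
    synthetic-data generator emulating the statistical structure of curated
    literature %HSA data makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    ChemmineR
Suggests:
    ChemmineOB,
    pROC,
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
biocViews: Cheminformatics, Pharmacokinetics, Classification
Config/testthat/edition: 3
RoxygenNote: 7.3.3
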