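Package: specEffect
Title: Spectrum-Effect Screening of Herbal Formula Constituents with
    Gray Relational Analysis and Untargeted Metabolomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Screens candidate active constituents of multi-component
    herbal medicines against pharmacodynamic readouts. Implements gray
    relational analysis (GRA) for spectrum-effect correlation with
    configurable normalization and distinguishing coefficient, network
    topology filtering of compound-target graphs (degree, betweenness,
    closeness), homeostasis-model insulin-resistance indices (HOMA-IR,
    HOMA-beta) and trapezoidal glucose-tolerance AUC, NIPALS latent-variable
    models (PCA, PLS-DA, OPLS-DA) with VIP, cross-validated Q2 and p(corr)
    for untargeted metabolomics, a four-criterion differential-metabolite
    screen with Venn intersection and hypergeometric pathway
    over-representation, monoisotopic-mass and negative-mode adduct
    annotation arithmetic, and seeded synthetic-data generators that plant
    recoverable ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
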