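Package: wbmflux
Title: Host-Microbiome Community Flux Modeling and Contribution Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based modeling of host-gut-microbiome co-metabolism.
    Builds abundance-personalized microbial community metabolic models,
    couples them to a compartmentalized host model, predicts maximal
    blood-metabolite fluxes by flux balance analysis, and decomposes the
    predictions into per-species contribution potentials via steady-state
    shadow prices. Includes the downstream statistical layer (influence
    filtering, robust-PCA outlier scoring, confounder-adjusted logistic
    flux-diagnosis regressions with BH-FDR, bootstrap ranking, pruning,
    Spearman flux-microbe correlation and exhaustive microbial cluster
    search) and a seeded synthetic-data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
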