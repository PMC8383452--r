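Package: sirbym
Title: Small-Area Disease Mapping with Standardized Incidence Ratios,
    Spatial Cluster Detection and Besag-York-Mollie Models
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for areal (small-area) epidemiology of case counts:
    indirectly standardized incidence ratios (SIRs) per geographic area,
    distance-band spatial weight matrices, Global and Local Moran's I with
    permutation inference and LISA cluster classification, Kulldorff's
    purely spatial Poisson scan statistic with Monte-Carlo p-values,
    and a from-scratch Metropolis-within-Gibbs sampler for the
    Besag-York-Mollie (BYM) model with an intrinsic CAR structured effect,
    an exchangeable unstructured effect and optional ecological covariates.
    Includes MCMC convergence diagnostics (Gelman-Rubin PSRF, Geweke,
    Heidelberger-Welch, Raftery-Lewis), a synthetic areal-data generator
    with CAR-structured risk surfaces for end-to-end testing, and a
    pipeline that orchestrates the full SIR -> clustering -> disease
    mapping -> ecological regression workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0), SummarizedExperiment
Imports: methods, stats, utils, Matrix, S4Vectors, jsonlite, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), coda, rjags, withr
Config/testthat/edition: 3
biocViews: Epidemiology, Spatial, Bayesian, Clustering
RoxygenNote: 7.3.3
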