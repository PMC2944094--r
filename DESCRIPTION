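Package: areaepi
Title: Small-Area Environmental Epidemiology: Standardized Rates,
    Point-Source Risk Analysis and Disease Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analytical engine for small-area ecological environmental
    epidemiology. Computes directly standardized rates and indirectly
    standardized incidence/mortality ratios (SIR/SMR) with age, sex and
    area-level covariate adjustment (including a Carstairs-style
    deprivation index); performs point-source risk analysis in
    user-defined distance bands with homogeneity and linear-trend tests;
    and maps disease risk with empirical-Bayes Poisson-gamma shrinkage
    toward the global mean, a fully Bayesian Besag-York-Mollie spatial
    model fitted by Markov chain Monte Carlo, posterior exceedance
    probabilities and an elevated/lowered/uncertain classification.
    Includes planar geography handling (GeoJSON polygons, centroids,
    queen/rook contiguity, distance bands around point, line or polygon
    sources) and a synthetic-data generator for stratified Poisson counts
    over polygonal geographies with known relative-risk surfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
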