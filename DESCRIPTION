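Package: facetshift
Title: Multi-Facet Diversity Redistribution Under Climate Change
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for projecting how climate change
    redistributes the taxonomic, functional and phylogenetic diversity of a
    species assemblage. Per-species presence-background distribution models
    (generalised additive, regularized log-linear and boosted-tree learners
    plus their ensemble) are fitted inside buffered accessible areas, scored
    with AUC and the continuous Boyce index, thresholded at maximum
    sensitivity plus specificity, and projected to current and future
    climates. Binary range maps are stacked into cell-by-species communities
    from which tree-based alpha diversity and temporal beta diversity
    (decomposed into replacement and richness components) are mapped for each
    facet. Per-species range shifts (area ratio, altitudinal and centroid
    displacement) are analysed with phylogenetic comparative methods: Pagel's
    lambda, Blomberg's K, ancestral state reconstruction and phylogenetic
    generalised least squares with lambda, kappa and delta branch
    transformations. A synthetic-data module generates spatially
    autocorrelated climates, species with known logistic suitability,
    birth-death phylogenies and Brownian traits so that every stage has a
    known recovery target.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    geosphere,
    glmnet,
    jsonlite,
    mgcv,
    stats,
    tools,
    utils,
    grDevices,
    xgboost
Suggests:
    nlme,
    optparse,
    phytools,
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
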