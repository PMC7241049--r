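Package: streamMOX
Title: Methane Oxidation Kinetics and Methanotroph Community Landscapes in
    Stream Sediments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools linking stream-sediment methane oxidation (MOX) kinetics to
    methanotroph (MOB) community structure. Simulates closed-chamber sediment
    incubations with discrete withdrawal/replacement sampling and recovers
    Michaelis-Menten parameters (Vmax, Ks) by trajectory or pointwise nonlinear
    least squares, with blank and dilution corrections, putative in-situ rate
    and methane-derived carbon-fixation estimates. Converts headspace
    equilibration gas measurements to dissolved concentrations via a
    temperature-dependent Henry's-law model. Builds enterotype-style community
    landscapes from OTU tables: Bray-Curtis non-metric multidimensional
    scaling, kernel-density landscapes of species scores with peak calling,
    k-means clustering of methanotrophic OTUs, convex-hull co-occurrence and
    taxonomic overrepresentation. Includes a synthetic-data generator with
    known ground truth (site gradients, depth profiles, OTU tables with
    planted MOB co-occurrence clusters, pmoA counts, incubation series) so
    every stage has a recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    mgcv,
    stats,
    graphics,
    grDevices,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
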