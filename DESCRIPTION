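Package: reefplume
Title: River-Plume Exposure Modelling and Microbial Community Statistics
    for Coastal Lagoon Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying riverine influence on coastal lagoon
    waters and its imprint on planktonic microbial communities. Simulates
    conservative river tracers on a two-dimensional depth-averaged coastal
    grid (first-order upwind advection plus explicit diffusion), converts
    tracer concentration series into a cumulative river-exposure index
    (concentration-days above a threshold) with capped exposure maps and a
    distance-based riverine/plume/marine site classifier, and implements
    the downstream 16S rRNA community statistics used in lagoon monitoring:
    rarefaction (expected and subsampled), gene copy-number correction,
    alpha diversity (richness, Shannon-Wiener, evenness, Chao1), one-sided
    Mann-Whitney tests, Hellinger ordination (PCoA), PERMANOVA, indicator
    species analysis, partial redundancy analysis with AIC model selection,
    Pearson correlation screening, and exploratory factor analysis with
    parallel analysis. A seeded synthetic-data generator emulates the
    riverine-to-marine community gradient and a four-factor environmental
    covariate structure so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    biomformat,
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
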