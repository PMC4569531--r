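Package: tallstand
Title: Baseline Analysis of Permanent Tall Eucalypt Forest Plot Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the baseline analysis of continental-scale permanent
    forest-plot networks in tall eucalypt forest: a stem-census data model with
    CSV readers and protocol validation, community importance values (relative
    frequency, density and dominance) at species and guild level, allometric
    aboveground biomass and carbon accounting with diameter-class partitioning
    and plot-level exclusions, stand-structure summaries (basal area, stocking,
    diameter distributions, diameter-height curves), canopy-cover estimation
    from hemispherical photographs by intensity thresholding, climate
    derivations with AIC-based model selection of carbon-climate relationships,
    and a synthetic census generator that emulates the statistical structure of
    a mature tall-forest network for testing every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
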