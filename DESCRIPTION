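Package: redsnow
Title: Bio-Albedo Modelling and Community Statistics for Arctic Red-Snow Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements an integrated bio-albedo change model for snow surfaces
    colonized by red-pigmented snow algae (square-root-of-time albedo decay
    fitted to anchor albedo values, closed-form seasonal integration, scenario
    differencing and sensitivity analysis), together with the field-measurement
    computations (radiometer albedo with quality control, spherical cell
    biovolume, biomass-albedo correlation) and amplicon OTU-table statistics
    (singleton exclusion, rarefaction, Shannon diversity, rank aggregation,
    principal component ordination, one-way ANOVA across locations,
    taxon-geochemistry correlations) used in Arctic red-snow microbiome
    surveys. A synthetic-study generator emulating a 40-site, four-location
    Arctic sampling design makes every analysis stage testable without
    sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    vegan,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
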