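Package: pestniche
Title: Climate Niche Modelling and Risk Mapping for Forest Insects and Diseases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for modelling the climate niches of forest
    insect and disease species from presence-only occurrence records and
    projecting them under climate change. Provides occurrence-record screening
    (metadata filters, landmass restriction, equal-area 10-km spatial thinning,
    minimum-record gating), rectilinear Bioclim-style climate envelopes with a
    percentile suitability score, a from-scratch L1-regularized presence-
    background maximum-entropy model (linear, quadratic, product, hinge and
    threshold features; raw, cumulative and logistic outputs; AUC and
    permutation variable importance), delta-method downscaling of GCM anomalies
    onto a baseline climate with multi-GCM composites, host-volume-at-risk
    accounting, and stacked-envelope species richness maps. Includes a
    self-contained synthetic-world generator (spatially autocorrelated climate
    surfaces, species with known Gaussian niches, deliberately dirty occurrence
    files, GCM anomaly fields, host volume surfaces) so the whole pipeline runs
    and is testable without any external data, plus single-band GeoTIFF reading
    and writing for all gridded inputs and outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
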