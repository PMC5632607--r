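Package: admodel
Title: Presence-Only Distribution Models, Habitat Masking and Field Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for turning presence-only species occurrence records and
    multi-layer environmental rasters into thresholded potential distribution
    models (PDMs), habitat-masked actual distribution models (ADMs),
    field-validated prediction-success statistics and stacked co-occurrence
    richness maps. Implements Ecological Niche Factor Analysis (marginality,
    specialization and tolerance), two auxiliary suitability engines
    (percentile envelope and Mahalanobis distance) with an adapter for
    externally produced suitability rasters, cross-engine pseudoabsence
    sampling, Kappa- and ROC-based threshold selection, subcell land-cover
    masking, site- and buffer-based validation against field surveys, and a
    seeded synthetic-landscape generator (spatially autocorrelated
    climate-like layers, virtual species with planted Gaussian niches,
    museum-style and point-count field sampling) so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    mgcv
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'geometry.R'
    'io.R'
    'synthetic.R'
    'enfa.R'
    'engines.R'
    'evaluation.R'
    'adm.R'
    'validation.R'
    'cooccurrence.R'
    'studyTables.R'
    'pipeline.R'
    'cli.R'
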