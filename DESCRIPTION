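Package: specfuse
Title: Multi-Block Fusion Chemometrics for LIBS and Raman Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised classification of biological samples (marine
    zooplankton taxa) from fused laser-induced breakdown (LIBS) and Raman
    spectra. Provides a seeded synthetic spectra generator with taxon-specific
    line and band inventories, spot-level preprocessing (iterative Grubbs
    outlier filtering on integrated peak intensities, spot averaging,
    total-intensity normalisation, resonance-line masking, colour chaining and
    Frobenius-norm block fusion), matrix decompositions (PCA, multi-restart
    non-negative matrix factorisation, JADE independent component analysis and
    ComDim/CCSWA common components with per-block saliences), oblique score
    coordinates, spider-diagram loading signatures, and an all-outside-points
    silhouette statistic scanned over component planes and subspaces, plus a
    config-driven pipeline that runs the full method-by-dataset comparison
    grid.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
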