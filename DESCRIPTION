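Package: depthfd
Title: Taxonomic and Functional Diversity of Demersal Fish Assemblages
    Across Depth
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing stereo-video transect surveys of demersal
    fish communities along bathymetric gradients: length correction and
    length-weight biomass conversion, abundance and biomass density
    matrices, rank-based and permutational community statistics (Bray-Curtis,
    PCoA, PERMANOVA, PERMDISP), construction of a categorical trait space
    (Gower distance, PCoA, mean-absolute-deviation dimensionality
    selection, iterative random-forest imputation), functional-entity
    redundancy metrics, convex-hull and distance-based functional
    diversity indices, and the FUSE (functionally unique, specialized, and
    endangered) conservation-priority index. Includes a synthetic survey
    generator that emulates a multi-atoll, multi-depth-band transect
    design so the whole pipeline can be exercised without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    randomForest,
    stats,
    utils
Suggests:
    ape,
    cluster,
    jsonlite,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
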