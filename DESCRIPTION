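Package: atlasquant
Title: Regional Quantification of Segmented Objects in Atlas-Registered
    Brain Sections
Version: 0.1.0
Authors@R:
    person("Atlasquant", "Developers", email = "atlasquant@example.org",
           role = c("aut", "cre"))
Description: Quantifies labelled objects (e.g. immunohistochemically
    stained amyloid plaques) in serial brain-section images that have been
    segmented into unique RGB colour codes and registered to a 3D
    reference atlas.  Extracts connected-component objects from colour
    segmentations, assigns them to atlas regions via section-matched
    label maps, computes per-region counts, areas and loads, exports
    3D atlas-space point clouds using planar anchoring vectors (o, u, v),
    renders overlay images, and provides image-series pre-processing
    (resize, rotate, mirror, rename), a point-grid stereological
    area-fraction estimator, and a fully synthetic fixture generator with
    closed-form ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    xml2,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
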