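Package: holodsn
Title: Adaptive 3D Descattering for Inline Holographic Particle Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulator-trained adaptive removal of multiple-scattering
    artifacts from inline holographic reconstructions of dense 3D particle
    suspensions. Provides a split-step beam-propagation forward model for
    simulating holograms of synthetic particle fields, angular-spectrum
    holographic backpropagation into depth-sliced complex volumes, a
    mixture-of-experts dynamic synthesis network (expert V-net
    encoder/decoders blended per input by a gating network fed with the
    hologram) trained to descatter the backpropagated volume, and an
    assignment-based 3D particle-localization scoring protocol (Otsu
    binarization, cluster filtering, centroid matching within an elliptical
    proximity gate, depth-binned Jaccard indices).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    jsonlite,
    yaml,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
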