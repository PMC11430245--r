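Package: retinaKMP
Title: Parallel Retinal Coding with K, M and P Opponent Pathways
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Models the primate retina's three parallel ganglion-to-LGN
    coding pathways from RGB images: the koniocellular blue-yellow channel,
    the foveal midget red-green channel and the peripheral homochromatic
    parvocellular channel, built from center-surround difference-of-Gaussian
    receptive fields over L/M/S cone planes. Also provides an algorithm-level
    emulation of a streaming hardware datapath for the same computation:
    raster-scan line-buffer convolution, shift-quantized fixed-point weights,
    parallel multiply/adder-tree critical-path accounting and a LUT-equivalent
    resource-sharing model, together with fovea/eccentricity viewing geometry.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, tools, png, yaml, jsonlite
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'cone-layer.R'
    'receptive-field.R'
    'datapath.R'
    'geometry.R'
    'image-io.R'
    'opponent-channels.R'
    'pipeline.R'
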