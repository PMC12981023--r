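Package: curvmech
Title: Curvature Mechanosensing of Stem Cells on Ultrasoft Hydrogel Topographies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative toolkit for studying how multiaxial surface
    curvature directs stem-cell mechanosensing on ultrasoft hydrogels.
    Provides differential geometry of height-field substrates and
    triangulated microgel meshes (principal, mean and Gaussian curvature,
    normal sections), synthetic wrinkle/groove/microgel topography
    generators emulating solvent-induced curvature engineering, curvature
    statistics and uniaxial/multiaxial region classification, a two-layer
    stress-fiber energy-minimization model (Euler-Bernoulli bending, active
    contractility, focal-adhesion binding, nuclear compression) with
    orientation energy landscapes and cytoskeletal drug perturbations, and
    structure-tensor orientation analysis of fiber images including polar
    histograms and the curvature polarization index.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    pracma,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
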