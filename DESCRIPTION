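Package: nestcamo
Title: Camouflage Scoring and Egg-Heating Analysis for Ground-Nesting Bird Nests
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies egg and nest camouflage in calibrated nest-scene
    photographs and the thermal behaviour of nest materials. Camouflage is
    scored by a multi-scale texture analysis: each CIE L*a*b* channel is passed
    through a bank of oriented Gaussian-derivative and rotation-invariant
    filters, per-pixel features are clustered with K-means, and per-region
    texture signatures are compared with a chi-squared histogram distance
    (background/pattern matching) or intersected with egg outlines (disruptive
    camouflage). Also provides a grid-based nest-material coverage metric,
    Newtonian heating-curve fitting (characteristic heating time), and a
    seeded synthetic-scene and heating-curve generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    minpack.lm,
    grDevices,
    stats,
    utils,
    png,
    tiff,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
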