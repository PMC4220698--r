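Package: synmorph
Title: Synaptic Ultrastructure and Axonal Bouton Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantification of axon-collateral boutons and symmetric
    synapse ultrastructure from microscopy images. Implements a
    standardized synaptic-cleft-width estimator based on averaged
    electron-density line profiles and a 10 percent peak-to-valley drop
    rule, active-zone and docked-vesicle geometric classification,
    confocal bouton detection by the twice-axonal-diameter rule with
    fluorescent-voxel volumetry, superimposed-arbor bouton density
    mapping, and the accompanying statistical procedures (pooled t,
    two-sample Kolmogorov-Smirnov, Hartley F-max homoscedasticity test
    with embedded critical values). Every measurement stage is paired
    with a synthetic-data generator producing inputs with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    EBImage,
    tiff,
    ggplot2,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    yaml
Config/testthat/edition: 3
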