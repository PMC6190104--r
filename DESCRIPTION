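Package: EmbryoServo
Title: Adaptive Visual Servoing for Automated Zebrafish Embryo Microinjection
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hardware-free implementation of the visual-servoing image pipeline
    used in robot-assisted zebrafish embryo microinjection: microscope autofocus
    (Brenner, Tenengrad and normalized-variance focus criteria with a two-phase
    coarse/fine search), adaptive local-mean threshold segmentation with a
    (b, param1) parameter circulation and least-squares ellipse fitting for
    embryo detection under uneven illumination, normalized template matching
    with tip-offset templates for pipette-tip localization, and the pixel
    displacement computation that drives the injection move. A seeded synthetic
    micrograph generator (elliptical embryo, tapered pipette, defocus stacks,
    illumination gradients, sensor noise) provides ground-truthed scenes so the
    whole pipeline is testable end-to-end without microscope hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, EBImage, jsonlite
Suggests: testthat (>= 3.0.0), optparse
biocViews: Software, CellBiology, Visualization
Config/testthat/edition: 3
RoxygenNote: 7.3.3
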