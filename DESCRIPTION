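Package: nucmorph
Title: Nuclear Shape Dynamics, Migration Kinematics and Mechanics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies nuclear shape dynamics of migrating cells from
    time-lapse fluorescence microscopy and nuclear mechanics from atomic
    force spectroscopy. Segments labelled nuclei per frame (Otsu or fixed
    thresholding), traces sub-pixel outlines, and computes the nuclear
    irregularity index (NII) with its four shape components, frame-to-frame
    shape change (delta NII), and a rotational maximum-overlap fluctuation
    statistic. Converts centroid trajectories into step speeds, mean path
    speed and beeline speed, detects recoil ("phase IV") events that combine
    a speed peak with nuclear rounding, aligns events into population
    mean +/- s.e.m. ensembles, and partitions time points into recoil versus
    remaining steps with nonparametric group comparisons. Analyses AFM
    force-distance curves: contact point, penetration at a force setpoint,
    Hertz sphere-fit elastic modulus, and approach/retraction dissipation
    energies with adhesion exclusion. Includes seeded generators for
    synthetic migration movies and force curves with ground truth, and an
    end-to-end pipeline with a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    polyclip,
    yaml,
    jsonlite,
    ggplot2,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
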