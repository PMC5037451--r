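Package: stretchplate
Title: High-Content Analysis of In Vitro Neuronal Stretch Injury in 96-Well Plates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for 96-well in vitro neuronal stretch-injury
    experiments on silicone-membrane plates. Computes per-well equibiaxial
    Green-Lagrange strain from fiducial-dot deformation measurements and
    summarizes strain fields across plates; segments two-channel live-cell
    fluorescence images (Hoechst nuclear + calcein AM viability) into viable
    cells, dead cells and neurites, and derives nine injury metrics including
    neurite length, process and branch counts; quantifies synaptophysin
    density in cell, soma and neurite compartments using background and
    maximum-correlation thresholding with morphological compartment splitting;
    and fits a four-parameter generalized logistic dose-response model of each
    injury metric against strain by Levenberg-Marquardt, with asymptotic
    confidence intervals and R-squared. A synthetic-data module generates
    fiducial-dot measurements, well-metric tables and rendered fluorescence
    channels with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
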