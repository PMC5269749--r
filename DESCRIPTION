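Package: auglam
Title: Augmented Laminography: Simulation and Fourier-Domain Fusion of CL
    and CT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis toolkit for computed laminography (CL)
    of flat, laterally extended specimens. Generates layered synthetic
    attenuation phantoms, forward-projects them in a parallel-beam model
    with an arbitrarily tilted rotation axis, reconstructs CT and CL
    volumes by filtered backprojection, and implements augmented
    laminography: filling the unsampled double cones in the Fourier space
    of a CL reconstruction with coefficients from a co-registered,
    lower-resolution CT reconstruction. Includes missing-cone geometry
    analysis, data-driven and analytic Fourier masks, image-quality
    metrics, MetaImage/TIFF volume input and output, and a command-line
    pipeline.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    withr,
    optparse,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    png
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
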