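Package: myxopix
Title: Quantification of Myxococcus xanthus Aggregation and Rippling from
    Time-Lapse Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the self-organizing behaviors of Myxococcus
    xanthus swarms from grayscale time-lapse microscopy. Implements the image
    preprocessing pipeline (Lanczos rescaling, contrast-limited adaptive
    histogram equalization, global histogram equalization), aggregate
    segmentation by bandpass filtering with Otsu thresholding and
    morphological refinement, aggregate matching with pixel-level
    precision/recall evaluation, global mean-squared-error and structural
    similarity metrics calibrated into equivalent spatial shifts and
    equivalent Gaussian noise levels, ripple wavelength estimation by
    radially binned two-dimensional Fourier spectra, and a compact
    conditional generative adversarial network (pix2pixHD-HE style: a shared
    generator trunk branching into a normalized-fluorescence head and a
    histogram-equalized head, each with its own multi-scale patch
    discriminator) that translates phase-contrast images into synthesized
    fluorescence images. A synthetic scene generator with known ground truth
    makes the whole stack testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
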