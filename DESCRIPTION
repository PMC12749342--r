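Package: clxmreg
Title: Lipid-Droplet Landmark Registration for Correlative Cryo-Fluorescence
    and Soft X-Ray Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fiducial-free co-registration of cryo-epifluorescence images with
    soft X-ray tomography projections using endogenous lipid droplets as
    landmarks. Implements the full pipeline: Gaussian/CLAHE preprocessing and
    global Otsu droplet segmentation in both modalities, phase cross-correlation
    coarse alignment, cost-driven iterative affine refinement with anisotropic
    scaling and rotation, thin-plate-spline non-rigid correction, and a
    leave-one-out landmark protocol for registration accuracy. Also provides
    Fourier ring correlation resolution estimation (0.25-threshold, full-pitch
    convention), frame-splitting for noise-independent half-datasets, FWHM line
    profiles, tilt-series planning, Beer-Lambert absorbance conversion, a
    ground-truth synthetic correlative scene generator, and TIFF/MRC/CSV/JSON
    input and output with physical pixel-size metadata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
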