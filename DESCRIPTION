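Package: congealsqi
Title: Least-Squares Groupwise Image Alignment with Self Quotient Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Groupwise (joint) alignment of image ensembles by alternating
    least squares: the evolving mean image is re-estimated from the currently
    warped ensemble and each image's affine warp is refined by a Gauss-Newton
    (Lucas-Kanade) update against that mean, giving a cost linear in the
    number of images. Self Quotient Image preprocessing with hard thresholding
    makes the same least-squares core applicable to photometrically distorted,
    partially occluded and multimodal (e.g. T1/T2/PD MRI) ensembles.
    Includes mPSNR/mSSIM quality metrics, a synthetic-distortion generator
    with ground-truth warps, and readers/writers for PNG, TIFF and NIfTI
    slices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    png,
    tiff,
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
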