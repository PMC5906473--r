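Package: breastskin
Title: Automated Breast Skin Segmentation for DCE-MRI by Active Contours
    and Skin-Thickness Continuity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments and removes the surface skin from stacks of breast
    dynamic contrast-enhanced MRI slices so that vessels, glands and tumors
    become visible in maximum intensity projections. The pipeline combines
    classical pre-processing (median filtering, Otsu binarization,
    morphological repair, parabolic removal of chest-wall organs), an open
    active-contour (snake) model seeded at the skin's upper boundary, and a
    skin-thickness continuity analysis along boundary normals that excludes
    vessels and mammary glands adherent to the skin's inner surface.
    Includes a synthetic phantom generator with ground-truth label maps,
    evaluation utilities (Dice coefficient, gray-level co-occurrence matrix
    texture features, paired t-tests) and readers/writers for DICOM series,
    NIfTI volumes and PNG/TIFF slices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    RNifti,
    png,
    tiff,
    jsonlite,
    yaml,
    stats,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
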