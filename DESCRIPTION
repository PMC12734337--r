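Package: fetalvm
Title: Automated Fetal Ventriculomegaly Assessment from Brain MRI Segmentations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures fetal lateral-ventricle width and volume from
    multi-class brain MRI tissue segmentations and assigns clinical
    ventriculomegaly severity grades. Provides NIfTI and PNG label I/O,
    mask simplification and intensity normalization, selection of the
    axial measurement plane by maximal deep-gray-matter cross-section,
    adaptive left/right ventricle partitioning, minimum-area bounding
    rectangle width estimation, threshold-based severity labeling,
    structured clinical report templates, segmentation and classification
    evaluation metrics, and a synthetic phantom generator with analytic
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    png,
    yaml,
    jsonlite,
    tibble,
    generics,
    ggplot2,
    rlang,
    grDevices,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    withr
Config/testthat/edition: 3
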