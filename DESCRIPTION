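Package: neurotrackr
Title: Longitudinal Tracking and Response Assessment of Brain Metastases from Segmentation Masks
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for lesion-level longitudinal analysis of brain metastases
    from co-registered 3D segmentation masks. Reads NIfTI-1 label volumes,
    decomposes them into anatomically distinct lesions by 3D connected
    components, measures RECIST-style maximum orthogonal diameters in the
    axial plane, matches lesions across up to eight follow-up studies by
    optimal assignment, classifies per-lesion treatment response under
    modified RANO-BM rules, and exports lesion tool cards as CSV. Includes
    lesion-wise detection metrics (precision, sensitivity, F1) with size
    stratification, patient-wise Dice overlap, inter-rater agreement
    statistics (ICC, Spearman, Bland-Altman), and a synthetic longitudinal
    phantom generator with simulated readers and a degraded segmenter for
    fully self-contained validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
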