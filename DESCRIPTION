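Package: radsaliva
Title: Slice-Aware CT Texture Radiomics and Toxicity Models for Salivary Glands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Artifact-aware extraction of grey-level run-length and
    co-occurrence texture features (Short Run Emphasis, inverse difference
    moment, maximum CT intensity) from salivary-gland regions of planning CT
    scans, with per-slice 2D computation that excludes dental-implant slices
    and a reference 3D mode; nested logistic models of moderate-to-severe
    xerostomia and sticky saliva at 12 months with likelihood-ratio tests and
    rank-based AUC; subgroup analyses; and a fully parameterised synthetic
    cohort generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    lmtest
Config/testthat/edition: 3
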