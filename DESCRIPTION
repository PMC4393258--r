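Package: prmap
Title: Parametric Response Maps for Serial Quantitative Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Voxel-wise parametric response mapping (PRM) of longitudinal
    quantitative imaging. Derives apparent diffusion coefficient (ADC) maps
    from two-b-value diffusion-weighted MRI and Hounsfield-calibrated maps
    from raw CT, co-registers follow-up volumes onto a baseline grid (rigid
    mutual-information alignment or landmark thin-plate-spline warping),
    classifies each voxel's change against a test-retest-calibrated 95%
    no-change threshold, and summarizes increased/decreased/unchanged volume
    fractions per lesion. Includes PSA-based clinical response calls, tumor
    growth-delay metrics, group comparisons, and a synthetic phantom
    generator with planted ground-truth change for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    png,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
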