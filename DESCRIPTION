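Package: cswater
Title: Three-Pool T2 Relaxometry for Brain Water-Fraction Mapping
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Multi-compartment T2 relaxometry of multi-echo brain MRI.
    Separates each voxel's water signal into short-T2 myelin water,
    intermediate-T2 intra/extra-cellular water and long-T2 CSF-like water by
    box-constrained three-pool non-linear least squares with an optional
    Laplacian spatial smoothness penalty, after correcting the non-central
    chi noise bias of sum-of-squares coil-combined magnitude data with a
    moment-based lookup table. Includes a digital phantom and cohort
    simulator, anisotropic CSF-distance region-of-interest erosion, regional
    water-fraction summaries, and linear-versus-quadratic age-association
    modelling with nested-model ANOVA selection and false discovery rate
    adjustment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, tools, RNifti, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'phantom.R'
    'noise.R'
    'relaxometry.R'
    'distance.R'
    'masks.R'
    'stats.R'
    'io.R'
    'pipeline.R'
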