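Package: mpMRIquant
Title: Multiparametric MRI Quantification of Tumor Therapy Response
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantification pipeline for multiparametric MRI of tumor
    therapy response in preclinical liver-tumor studies. Fits per-voxel
    apparent diffusion coefficients (ADC) from multi-b diffusion-weighted
    imaging, Tofts-model Ktrans and ve from dynamic contrast-enhanced MRI,
    and deconvolution-based relative blood volume and flow from dynamic
    susceptibility contrast MRI; computes morphometric response indexes
    (tumor volume change, relative viable rim, relative necrosis volume);
    and runs per-timepoint nonparametric group comparisons with
    Bonferroni-corrected post-hoc tests plus stepwise linear regression
    for predictor selection. A digital-phantom and longitudinal cohort
    simulator with known ground truth makes every stage testable
    end-to-end without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    jsonlite,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'adc.R'
    'kinetics.R'
    'dsc.R'
    'io.R'
    'morphometry.R'
    'phantom-geometry.R'
    'phantom-cohort.R'
    'phantom-simulate.R'
    'stats.R'
    'tofts.R'
    'pipeline.R'
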