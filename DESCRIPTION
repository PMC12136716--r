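Package: zsustain
Title: Subtype and Stage Inference for Z-Scored Regional Neuroimaging
    Biomarkers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Data-driven disease-progression modelling for cross-sectional
    regional neuroimaging biomarkers (e.g., ALFF from resting-state fMRI).
    Implements the z-score event-based subtype-and-stage inference model:
    multisite ComBat harmonization, control-referenced covariate
    residualization and z-scoring, region-wise feature selection, maximum
    likelihood event-sequence fitting with EM-based mixture subtyping, MCMC
    posterior sampling over event orderings, cross-validated model selection
    (CVIC), per-patient subtype and stage assignment with stage binning,
    between-subtype clinical statistics, and spatial term-map decoding of
    stage-wise abnormality profiles. A synthetic cohort generator with planted
    ground truth supports end-to-end testing and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    sva
Config/testthat/edition: 3
RoxygenNote: 7.3.3
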