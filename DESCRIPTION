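Package: voxconn
Title: Voxel-Wise Connectomic Predictors and Mechanisms of Symptom Change
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Longitudinal voxel-wise resting-state connectomics for
    brain-behavior analyses. Builds voxel-by-voxel functional connectivity
    matrices from 4D time series, computes weighted-degree, between-network
    integration and within-network segregation maps against a seven-network
    parcellation, fits mass-univariate covariate-adjusted general linear
    models linking connectivity (or its longitudinal change) to symptom
    change scores, and controls family-wise error with Monte-Carlo
    cluster-extent correction at matched spatial smoothness. Includes
    seed-based post-hoc characterization of significant integration voxels,
    clinical cohort statistics (paired nonparametric tests, CGI-I
    summaries, FDR, extreme-responder stratification, healthy-control
    contextualization), and a synthetic longitudinal cohort generator with
    configurable planted brain-behavior effects for calibration and
    parameter-recovery studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
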