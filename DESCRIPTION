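Package: r1connectome
Title: Myelin-Weighted Structural Connectome Analysis with Partial Least
    Squares and Epicenter Ring Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds R1-weighted (longitudinal relaxation rate, a
    myelin-sensitive quantitative MRI metric) structural connectomes from
    scalar volumes, tractography streamlines and a parcellation; pools
    subject connectomes into consensus group connectomes; tests group
    differences and brain-behavior relationships with mean-centering and
    behavioral partial least squares (permutation significance and
    bootstrap-ratio edge reliability); performs epicenter ring analysis
    with covariate-adjusted group comparison and false-discovery-rate
    correction; and computes cohort demographic statistics. Ships a
    synthetic cohort generator that emulates the statistical structure of
    a Parkinson's disease case-control study, including a toy labeled
    phantom volume with streamlines, so the full pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    RNifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
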