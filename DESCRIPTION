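Package: curisc
Title: Intersubject Correlation and Curiosity-Motivated Memory Encoding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end pipeline for analysing incidental memory
    encoding under curiosity and monetary incentives, combining a
    behavioural arm (generalised linear mixed models of subsequent memory,
    confidence-cutoff sweeps, inverse-variance fixed-effect meta-analysis)
    with a naturalistic-fMRI intersubject arm (volume selection and
    reordering, hemodynamic-lag selection by intersubject pattern
    correlation, pairwise intersubject correlation maps, intersubject
    representational similarity analysis with residualised and
    Anna-Karenina behavioural similarity, voxelwise linear mixed models
    with crossed random intercepts for subject pairs, and cluster-extent
    and ROI false-discovery-rate inference). Includes synthetic-data
    generators with known ground truth so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    igraph,
    jsonlite,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
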