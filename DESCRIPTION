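Package: mvdecode
Title: Multivoxel Pattern Decoding of Current and Prospective Task Relevance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and inference tools for region-of-interest fMRI
    multivariate pattern analysis of trial-structured designs in which a
    remembered object category is currently relevant, prospectively relevant,
    or irrelevant. Provides a synthetic generator of per-trial, per-TR voxel
    t-value patterns with controllable category signal, relevance-dependent
    gain and representational sign inversion (including a BOLD/GLM path with
    a double-gamma haemodynamic response); one-vs-rest logistic-regression
    category decoding with leave-one-run-out and balanced cross-validation;
    within- and cross-relevance decoding schemes; cross-temporal
    generalization with two-dimensional cluster-based sign-flip permutation
    testing; representational dissimilarity analysis (Spearman-based RDMs,
    rank transform, classical multidimensional scaling, same- versus
    different-category contrasts); and group-level statistics (paired t with
    Cohen's d, one-way repeated-measures ANOVA with partial eta squared and
    Greenhouse-Geisser correction, within-subject standard errors).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
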