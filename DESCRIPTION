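Package: fibrosign
Title: Transcriptomic Stricture Signatures in Fibrostenotic Crohn's Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for matched-site bulk transcriptomics of
    fibrostenotic Crohn's disease resections. Provides a synthetic cohort
    generator emulating the nine-patient, three-site (stricture, proximal
    margin, distal margin) design with multivariate log-normal expression and
    injected differential-expression truth; TPM log-transformation and
    low-count/low-variance gene filtering; empirical-Bayes moderated-t
    differential expression with Benjamini-Hochberg control, fold-change
    gating and sign-consistent overlap across pairwise site contrasts;
    NIPALS PLS-DA with VIP-score gene selection and cross-validated R2/Q2;
    random-forest biomarker-panel AUC with bootstrap confidence intervals;
    a simulation-based power and sample-size estimator under a multivariate
    log-normal model with Cohen's d effect injection; and qPCR relative
    quantification by the 2^-ddCt method with Kruskal-Wallis comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    randomForest,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
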