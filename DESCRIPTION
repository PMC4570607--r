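Package: splicemix
Title: Model-Based Clustering of Tissues by Splice-Variant Composition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage model-based clustering of tissues by the relative
    abundance of co-expressed splice-variant mRNAs quantified by real-time
    PCR. Provides comparative-CT preprocessing into compositional ratios with
    a PAN-consistency check, kernel density exploration with four bandwidth
    selectors, a finite mixture of bivariate Gaussians over pooled technical
    replicates (EM with CEM initialization, eigenvalue-decomposed covariance
    families, BIC selection, MAP allocation and entropy), and a finite
    mixture of linear mixed models that accounts for within-tissue replicate
    dependence through tissue-level random effects. A synthetic-data module
    generates panels with the exact generative structure the models assume.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    MASS,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
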