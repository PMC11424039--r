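Package: micoconn
Title: Microstructure-Informed Structural Connectomes and Developmental
    Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds microstructure-informed structural connectomes from
    multi-shell diffusion MRI and analyses their development. Provides a
    synthetic crossing-fibre phantom generator with known per-streamline
    intra-axonal signal fractions, a miniature COMMIT-style deconvolution
    stage (stick-zeppelin-ball forward kernels, a streamline-segment
    linear operator, deterministic non-negative least squares, and
    implausible-streamline filtering), bundle-weighted connectome
    construction with a data-driven atlas-merging rule, weighted graph
    measures (Newman spectral modularity, global and local efficiency,
    Onnela clustering, strength), a cohort simulator with programmed age,
    sex and network effects, and the corresponding statistical pipeline
    (mixed models with AIC selection, per-network linear models, and
    elastic-net feature importance for local efficiency).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    lme4,
    glmnet,
    RNifti,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
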