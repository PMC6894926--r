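Package: actionrsa
Title: Representational Similarity Analysis of Observed Actions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A behavioral-to-neural representational similarity analysis (RSA)
    pipeline for observed actions. Estimates semantic and component
    dissimilarity structures from multi-arrangement (inverse MDS) behavior,
    builds model representational dissimilarity matrices (arrangement-derived,
    rating-derived, binary, and HMAX-C1 image features), runs surface
    searchlight standard and multiple-regression RSA with cluster-based
    Monte-Carlo permutation inference, and characterizes the recovered
    representational geometry via classical MDS, PCA, k-means with silhouette
    model selection, and hierarchical clustering. A synthetic-data module
    generates arrangement sessions, toy cortical meshes with planted
    representational structure, fMRI-like time series, trial sequences, and
    parametric stimulus images, so the full pipeline can be exercised and
    validated without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    cluster,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
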