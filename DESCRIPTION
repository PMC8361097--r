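Package: nichemap
Title: Signature Derivation, Ligand-Receptor Scoring and Cellular-Niche
    Detection for Single-Nucleus, Spatial and Multiplexed-Imaging Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for integrated tumor-microenvironment
    analysis across single-nucleus RNA-seq, spot-based spatial transcriptomics
    on hexagonal arrays, and multiplexed antibody imaging. Implements hashtag
    demultiplexing recovery and QC filters; one-vs-all Wilcoxon
    differential-expression scoring with disjoint top-N subtype signatures;
    co-expression module detection; binned-background and single-sample
    (ssGSEA-style) gene-set scoring; latent-time transfer from normal
    epithelium by L1 nearest-neighbor matching with interval signatures;
    receptor-activity scoring with ligand-receptor interaction calling and a
    spatial co-expression filter; hexagonal ring-neighborhood expression
    profiles and Fisher concurrence tests; and multi-phase kNN cell typing
    with cellular-niche detection, Shannon-entropy diversity, enrichment and
    proximity statistics. Ships seeded synthetic-data generators that emulate
    every input so the full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    methods,
    stats,
    utils,
    FNN,
    glmnet,
    cluster,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
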