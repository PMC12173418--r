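Package: pathMoE
Title: Interpretable Multimodal Integration of Histopathology Regions and
    Pathway-Structured Multi-Omics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint modelling of whole-slide-image patch features and multi-omics
    profiles for classification and survival prediction in oncology cohorts.
    Patch bags are summarised into spatial region embeddings through kernel-based
    patch merging, K-means region assignment and an attention-weighted hypergraph
    convolutional encoder; multi-omics sources are partitioned by gene set and
    embedded with per-pathway multi-source variational autoencoders. Region and
    pathway embeddings are fused by factorized bilinear pooling and reduced with a
    two-phase hierarchical mixture-of-experts whose gating weights yield pathway
    enrichment scores, region-by-pathway multimodal interaction scores and
    SHAP-style gene attributions. Training supports categorical cross-entropy and
    Cox partial-likelihood objectives, multiphase optimisation and modality
    dropout for robustness to missing modalities. Includes a synthetic-cohort
    generator with planted region-by-pathway signals for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    survival,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Collate: 
    'AllClasses.R'
    'accessors.R'
    'fusion.R'
    'interpret.R'
    'io.R'
    'metrics.R'
    'nn.R'
    'omics.R'
    'pathMoE-package.R'
    'pipeline.R'
    'synthetic.R'
    'tape.R'
    'train.R'
    'wsi.R'
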