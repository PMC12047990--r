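Package: stclip
Title: Contrastive Image-Transcriptomics Toolkit for Spatial Omics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for integrating histology image patches with spot-level
    spatial transcriptomics through a shared embedding space. Expression
    profiles are encoded as rank-ordered gene sentences and embedded with a
    pluggable dual encoder (a deterministic hash encoder and a small
    trainable contrastive dual encoder are provided). On top of the
    embeddings the package implements non-rigid slide alignment via an
    embedding-augmented coherent point drift, zero-shot tissue annotation
    against bulk or marker-gene references, probabilistic cell-type
    decomposition of spots or patches, cross-modal retrieval with Recall at K,
    and similarity-weighted spot expression prediction with cross-validation,
    together with the evaluation metrics used to benchmark these tasks and a
    synthetic paired-data generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    png,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
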