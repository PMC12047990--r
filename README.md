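# stclip

Contrastive image–transcriptomics integration for spot-based spatial
transcriptomics, in R.

Spot-based ST platforms (10x Visium and its relatives) measure a
gene-count vector at each ~55 µm capture spot *and* pair every spot with a
patch of the H&E histology image. `stclip` treats the two modalities as
two views of one tissue state and connects them through a shared
unit-norm embedding space, then builds the standard downstream analyses
on top of that space. It is written for computational biologists who want
a self-contained, fully testable implementation of this analysis stack —
including a deterministic stand-in encoder and a synthetic paired-data
generator — without multi-GB pretrained weights or GPU training.

## What it does

**Representation.** An expression profile becomes a *gene sentence*: its
genes ranked by decreasing expression (housekeeping genes removed, ties
broken alphabetically), truncated to the top 50 symbols. A pluggable dual
encoder maps sentences and image patches to unit vectors in R^d
(d = 768 default). Two backends ship: a deterministic hash encoder
(training-free, reproducible bit-for-bit), and a small trainable dual
encoder optimized with the symmetric contrastive loss

    L = -(1/N) [ Σ_i log softmax_i(x_iᵀy_i/σ) + Σ_i log softmax_i(y_iᵀx_i/σ) ]

over matched (image, sentence) pairs in a batch (temperature σ = 0.07,
batch size 64).

**Algorithms on embeddings.**

| task | function | method |
|---|---|---|
| slide alignment | `align_slides()` | coherent point drift in `[x, y, γ·PC1, γ·PC2]` space, coordinate-only updates, rigid (Procrustes) distortion screen |
| tissue annotation | `annotate_with_reference()`, `zero_shot_classify()`, `fuse_scores()` | cosine similarity to bulk-RNA-seq or marker-gene reference sentences; min-max-normalized score fusion |
| cell-type decomposition | `decompose_slide()` | row-stochastic cell→spot mapping minimizing per-dimension cosine distance (Tangram-style), NMS refinement |
| retrieval | `retrieve()`, `recall_at_k()` | cosine ranking with conservative (worst-rank) tie handling, Recall@K quantile |
| expression prediction | `predict_expression()`, `crossval_predex()` | similarity-weighted reference average, 10-fold CV with per-fold fine-tuning |
| metrics | `calinski_harabasz()`, `kendall_tau()`, `js_divergence()` (log2), `ssim_global()`, `weighted_f1()`, `impact_scores()`, `mse_per_gene()` | the exact printed forms used to benchmark these tasks |

**Data layer.** `read_slide()`/`write_slide()` for MatrixMarket +
features/barcodes/positions (+ per-spot PNGs), gene-sentence TSVs,
embedding TSVs, QC filtering (> 200 expressed genes), log normalization,
pseudo-spot binning of single-cell-resolution data onto Visium geometry,
and patch extraction from a slide image. `make_slide()` generates
synthetic paired slides with known domain structure, cell-type fractions,
and a single-cell reference; `perturb_alignment()`, `downsample_depth()`,
and `add_image_noise()` reproduce the standard robustness manipulations.

## Worked example

```r
library(stclip)

## a 200-spot synthetic slide with 4 spatial domains and paired patches
ms <- make_slide(synth_config(n_spots = 200, seed = 1))
ms$slide
#> spot_slide: 200 spots x 120 genes
#>   spot diameter 55 um, pitch 100 um
#>   patches: 16x16

slide_sentences(ms$slide)[[1]]
#> gene_sentence [spot_0001] (50 tokens): GENE0012 GENE0019 GENE0004 ...

## rotate + jitter a copy, then register it back
pert <- perturb_alignment(ms$slide, coord_noise_sd = 5,
                          rotation_deg = 10, seed = 2)
res <- align_slides(pert$slide, ms$slide, hash_encoder(d = 64),
                    mode = "st_to_st")
post <- mean(sqrt(rowSums((res$final_coords - pert$true_coords)^2)))
#> pre-alignment error:  89.4 um
#> post-alignment error:  6.1 um   (6.8% of pre)

ev <- evaluate_alignment(res$final_coords,
                         normalize_counts(pert$slide)$lognorm,
                         normalize_counts(ms$slide), n_hvg = 50)
ev$median_pcc
#> [1] 1.000   # median per-gene PCC over 200 matched spots
```

The mean spot displacement introduced by the 10° rotation (89.4 µm,
roughly one spot pitch) is reduced to 6.1 µm by the registration — the
aligned spots land on their true positions to within a medium-depth
sequencing error — and the expression of the 50 most variable genes
agrees perfectly at matched locations.

A command-line front end over the same functions is installed at
`system.file("cli", "stclip.R", package = "stclip")`:

```sh
Rscript stclip.R simulate --n-spots 200 --seed 1 --out slide/
Rscript stclip.R sentences --matrix slide/matrix.mtx --features slide/features.tsv \
    --barcodes slide/barcodes.tsv --positions slide/positions.csv --out sentences.tsv
Rscript stclip.R embed --modality text --backend hash --in sentences.tsv --out emb.tsv
```

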