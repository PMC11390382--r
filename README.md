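# natmil — neighborhood-attention multiple instance learning for whole-slide images

Pathology diagnoses attach to a whole slide, not to pixels. Weakly
supervised WSI classification therefore treats the slide as a *bag* of
256×256 tiles with a single label, and learns which tiles matter. Classical
attention-based MIL scores tiles independently, ignoring that tumor tissue
is spatially coherent. `natmil` re-scores each tile with a **neighborhood
attention** (NA) transformer over the slide's tile grid — self-attention
restricted, per query, to its `k` nearest grid neighbors, with learned
relative positional biases and neighborhoods that shift inward at slide
edges — then pools tiles with **gated attention** into a slide embedding
and classifies it.

The package is aimed at method developers: it is a complete, tested,
pure-R desk-scale implementation (all forward *and* backward passes are
hand-written) with a seeded synthetic-slide and feature-bag generator, so
every stage is exercisable without any clinical data or GPU.

## The model in brief

For tile embeddings `X ∈ R^{n×d}` on an `h×w` grid with projections
`Q, K, V` and per-offset biases `B`, query `i` attends over its `k` nearest
valid neighbors `ρ_1(i) … ρ_k(i)` (Chebyshev distance, ties by Euclidean
then raster order):

    A_i = [ Q_i K_{ρ_j(i)}^T + B(i, ρ_j(i)) ]_{j=1..k}
    NA_k(i) = softmax(A_i / √d_head) · V_i^k

Stacked in pre-norm transformer blocks with LayerScale, this
contextualizes every tile; gated attention pooling

    a_i = softmax_i( w^T ( tanh(V t_i) ⊙ sigm(U t_i) ) ),
    g = Σ_i a_i (g_i + t_i),   y = W_c g^T

aggregates contextual (`g_i`) plus raw (`t_i`) embeddings into the slide
prediction. As `k → n`, NA provably equals global self-attention (tested);
at `k = 1` the model degenerates to gated AB-MIL. Tile features can be
learned with a two-view contrastive objective (NT-Xent at τ = 0.5).

Modules: synthetic data (`generate_slide`, `generate_feature_bags`),
preprocessing (`segment_tissue`, `tile_slide`), contrastive features
(`augment`, `nt_xent_loss`, `train_encoder`, `extract_features`), the NA
operator with a brute-force oracle (`build_neighborhood_index`,
`neighborhood_attention`, `oracle_masked_attention`), the hierarchical NAT
backbone (`nat_config`, `forward_backbone`), the MIL head
(`gated_attention`, `aggregate_bag`, `classify`, `baseline_pool`), and the
experiment layer (`train_natmil`, `train_mil_baseline`, `k_sweep`,
`ablation_attention_type`, `compute_metrics`) plus a CLI
(`inst/cli/natmil`).

## Worked example

Sparse clustered tumor (5–8% of tiles) with slide-level stain variation is
the regime where global pooling fails and neighborhood context pays off:

```r
library(natmil)

spec <- bag_spec(n_bags = 120, grid_height = 12, grid_width = 12, d = 32,
                 tumor_fraction = 0.08, cluster = TRUE, class_separation = 4,
                 seed = 42)
bags <- generate_feature_bags(spec)

cfg <- natmil_config(d = 32, n_blocks = 1, heads = 2, k = 9, gate_hidden = 16)
fit <- train_natmil(bags, cfg, seed = 7,
                    settings = train_settings(epochs = 30, lr = 3e-3,
                                              batch_size = 8, patience = 5,
                                              min_epochs = 15,
                                              weight_decay = 0.1))
print(fit$metrics)
#> metric_report: n=18  AUC=1.0000  ACC=0.9444  macro-F1=0.9443

mp <- train_mil_baseline(bags, "mean", cfg, seed = 7,
                         settings = train_settings(epochs = 30, lr = 3e-3),
                         split = fit$split)
print(mp$metrics)
#> metric_report: n=18  AUC=0.3333  ACC=0.3889  macro-F1=0.3714

pos <- bags[[fit$split$test[[1]]]] # a held-out positive slide
pr <- predict_bag(fit$model, pos)
#> slide bag_010 (label 1): P(tumor) = 0.994
#> attention mass on the 12 tumor tiles of 144: 0.85 (uniform would give 0.08)
```

Read: on 18 held-out slides NATMIL ranks every positive above every
negative (AUC 1.0) while mean pooling is at chance — the per-bag stain
shift drowns the 8% tumor signal in the average, but per-tile gated
attention, sharpened by neighborhood context, concentrates 85% of its
weight on the 8% of tiles that are actually tumor.

The image path works the same way end to end:

```r
sl   <- generate_slide(slide_spec(32, 32, tile_px = 8, tumor_fraction = 0.05,
                                  blob_count = 2, seed = 7))
mask <- segment_tissue(sl$image, downsample_factor = 4)
man  <- tile_slide(sl$image, mask, tile_px = 8, min_tissue_fraction = 0.5)
```

## Formats

Rasters are Netpbm PPM (P3/P6), feature bags TSV + JSON sidecars, manifests
and metric tables CSV, checkpoints and configs JSON — all plain text,
readable without external imaging/HDF5 libraries.
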