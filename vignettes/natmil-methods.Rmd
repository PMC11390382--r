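---
title: "Neighborhood-attention MIL for whole-slide images: models, choices, and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neighborhood-attention MIL for whole-slide images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

A whole-slide image (WSI) is a gigapixel scan of a stained tissue section.
Diagnoses attach to the slide, not to pixels, so supervised learning happens
in the multiple-instance setting: the slide is cut into fixed-size tiles (the
instances), the set of tiles forms a bag, and only the bag carries a label.
Classical attention-based MIL (AB-MIL and its descendants) scores each tile
independently, which ignores that tumor tissue is spatially coherent: a tile's
malignancy risk is informed by its neighbors. This package implements a MIL
classifier in which tile scores are recalibrated by a *neighborhood attention*
(NA) transformer over the slide's tile grid before gated attention pooling
aggregates the bag.

## The model

**Neighborhood attention.** For tile grid embeddings $X \in \mathbb{R}^{n
\times d}$ with query/key/value projections $Q, K, V$, the attention logits of
query $i$ over its $k$ nearest grid neighbors $\rho_1(i), \dots, \rho_k(i)$
are $Q_i K_{\rho_j(i)}^T + B_{i,\rho_j(i)}$, where $B$ is a learned relative
positional bias indexed by the grid offset. The output is
$\mathrm{softmax}(A_i^k / \sqrt{d_h})\, V_i^k$ per head ($d_h$ = head width),
heads concatenated and output-projected. Two properties matter and are
asserted by tests: as $k \to n$ the operator equals global self-attention,
and because neighborhoods slide with the query (instead of partitioning the
grid into blocks) the operator is translationally equivariant in the grid
interior.

**"Nearest" and edges.** The source formulation leaves the metric and edge
behavior open. This implementation sorts candidates by Chebyshev distance,
breaking ties by Euclidean distance and then raster order. For $k = m^2$ (odd
$m$) this reproduces the centered $m \times m$ sliding window; at grid edges
the neighbor set shifts inward so every query keeps exactly $\min(k,
n_\text{valid})$ neighbors — a uniform attention span with no zero-padding
dilution. The rule is deterministic for every $k$, including non-square values
such as $k \in \{2, 3, 8\}$. The bias table covers offsets up to radius
$\lceil\sqrt{k}\rceil - 1$; rarer offsets reachable after edge shifting are
clamped to the nearest tabulated entry.

**NAT backbone.** The hierarchical backbone follows the four-stage design:
an overlapping tokenizer (two 3×3 stride-2 convolutions, GELU between)
embedding to a quarter of the input resolution; stages of pre-norm transformer
blocks $X + \gamma_1 \mathrm{NA}(\mathrm{LN}(X))$,
$X + \gamma_2 \mathrm{MLP}(\mathrm{LN}(X))$ with per-channel LayerScale
$\gamma$ initialized at $10^{-5}$; and 3×3 stride-2 convolutions between
stages that halve space and double channels. The reference configuration is
depths (3, 4, 18, 5), 2 heads, MLP ratio 3. The printed stage-size table in
the source is internally inconsistent (it lists $h/16$ twice while stating
that every downsampler halves space); this implementation takes stage 4 at
$h/32$, the only reading consistent with the halving rule.

**MIL head.** Gated attention pooling scores tile $i$ as $w^T(\tanh(V t_i)
\odot \sigma(U t_i))$, softmax-normalized over the bag; the slide embedding
is $g = \sum_i a_i (g_i + t_i)$ where $g_i$ is the NA-contextualized embedding
and $t_i$ the raw one; classification is $y = W_c g^T$ with softmax and
cross-entropy. Two readings left open by the source are exposed as
configuration: `residual_raw` (drop the raw $t_i$ term) and `gate_input`
(gate on contextualized — the default, matching the idea of *re-adjusted*
attention coefficients — or raw embeddings).

**Resolution of the MIL/backbone tension.** Pooling needs one contextualized
embedding per tile, but the hierarchical backbone divides the grid by 32. The
MIL model therefore contextualizes the tile grid with NAT blocks at full grid
resolution (a 1×1 linear embedding instead of the stride-4 tokenizer, no
downsamplers, channels fixed at $d$); the full hierarchical backbone exists
alongside for image-mode use and is tested against its own shape laws. This
is the package's resolution of an unstated design point, not a claim about
the source.

**Contrastive features.** Tile embeddings can be learned with a two-view
contrastive objective: each tile is augmented twice (random resized crop,
horizontal/vertical flips, color jitter, Gaussian blur), encoded by a residual
CNN, projected by a two-hidden-layer MLP, L2-normalized, and scored with the
NT-Xent loss at temperature $\tau$ (default 0.5, the SimCLR convention). The
printed loss equation in the source is garbled (its $q_s, q_t$ are never
defined); the canonical symmetric NT-Xent is used. The desk-scale encoder is
a small residual CNN (He-initialized convolutions; the 0.02
truncated-normal convention used for transformer weights starves a conv
stack, which is visible as NT-Xent frozen at $\log(2N-1)$); the reference
1024-d ResNet-50 setting is a configuration point, not something this
package can train.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `k` | 9 | neighbors | 3×3 sliding window; the sweep harness covers {1, 2, 3, 4, 8} |
| `heads` | 2 | – | reference configuration |
| `mlp_ratio` | 3 | – | reference configuration |
| `layer_scale_init` | 1e-5 | – | deep-transformer stabilization convention |
| `tau` | 0.5 | – | SimCLR convention; unstated in the source |
| `tile_px` | 256 | pixels | stated tiling size |
| `min_tissue_fraction` | 0.5 | – | common default; unstated in the source |
| gating hidden width | 256 | – | AB-MIL convention (tests use 16 at d = 32) |
| optimizer | AdamW, cosine + 10% warmup | – | stated training-configuration style |
| learning rate | 1e-3 | – | desk-scale default; the full-scale value (1e-4) cannot converge at toy widths within test budgets |
| `min_epochs` | 15 | epochs | attention-MIL has a flat phase before the gate sharpens; stopping inside it truncates learning |

## The synthetic world

`generate_slide()` paints a connected tissue region (~60% of the grid) on a
near-white background, grows `blob_count` tumor blobs by random-walk region
growing until exactly `floor(tumor_fraction * n)` tiles are tumor, renders
normal tissue pink and tumor purple with a sinusoidal luminance motif of
period `motif_period` (default 8) tiles, and adds Gaussian pixel noise. The
two regimes of interest are sparse clustered tumor (fraction ≈ 0.05, the
lymph-node metastasis regime) and dominant tumor (≈ 0.8, the resection
regime).

`generate_feature_bags()` skips images: normal tiles are $N(b, I_d)$, tumor
tiles $N(b + s\mu, I_d)$ with one shared random unit direction $\mu$ and
separation $s$. The per-bag shift $b$ is a **rank-3 stain model**: $b =
\texttt{stain\_sd}\,(z_1 \mu + z_2 v_1 + z_3 v_2)$, $z \sim N(0,1)$. Two
deliberate properties follow. First, because the nuisance has sd
`stain_sd` *along* $\mu$, mean pooling cannot linearly project it away — its
signal is $f \cdot s \approx 0.2$ against nuisance 1 in the sparse regime, so
global pooling stays near chance, which is exactly the clinical motivation
for attention MIL. Second, because the nuisance is only rank 3, a model
cannot memorize training bags from high-dimensional stain fingerprints; an
earlier isotropic version of this generator allowed precisely that
memorization shortcut and was replaced. Stain variation in H&E being
low-dimensional and co-varying with stain density (the axis separating tumor
from normal) is the realistic reading.

What a green test does **not** establish: the generator has no morphology,
no stain texture, no label noise, no scanner artifacts, and its tumor/normal
separation is linear by construction. Synthetic discrimination results
demonstrate that the implementation can exploit spatial clustering and
per-tile signal; they say nothing about histopathology performance.

## Numerical choices

- Softmax with max subtraction everywhere; attention rows sum to 1 within
  1e-6; NA-vs-oracle tolerance 1e-5 (comfortably met in double precision).
- $\sqrt{d}$ in the attention scaling is read as $\sqrt{d_\text{head}}$.
- Masked grid positions are excluded as keys/values and forced to zero in
  every block output; LayerNorm never sees masked rows.
- GELU uses the tanh approximation, with the backward pass differentiating
  the approximation itself (gradients are finite-difference-verified to
  ~1e-6 relative error across all four mixer variants).
- All randomness flows through one derived-seed helper; no function touches
  global RNG state. Identical config + seed reproduces results bit-for-bit.
- The ablation mixers (blocked-window, global, depthwise-conv) share the
  block parameterization; window and global attention keep the relative
  positional bias so variant swaps isolate the attention span. This makes
  the $k = n$ limit equivalence exact up to float summation order.

## Scaling of test workloads

Training-based checks run at reduced size on 1 CPU: the sparse-tumor
discrimination experiment uses the stated world (200 bags, 24×24 grids,
tumor fraction 0.05, separation 4, d = 32, 3 seeds) with a one-block
contextualizer; the k-sweep and limit-equivalence runs use 16×16/12×12 grids
and 50–60 bags. Contrastive tests use 12-px tiles and a 6-channel encoder.
The file formats differ from the full-scale design where the environment
lacks offline readers: rasters are Netpbm PPM, feature bags are TSV + JSON
sidecars, configuration files are JSON.

## Known limitations

- No GPU/framework backend: everything is base-R numerics; throughput limits
  experiments to toy dimensions.
- No stochastic depth, dropout, or mixed precision; regularization is weight
  decay + early stopping only.
- The hierarchical backbone is forward-only (unit-tested against shape and
  equivalence laws); end-to-end training happens in the full-resolution MIL
  contextualizer.
- Tissue segmentation parameters (saturation floor, area floor) are
  pragmatic defaults; the source delegates to an external toolkit and prints
  none.
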