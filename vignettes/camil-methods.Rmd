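---
title: "Channel-attention multiple-instance learning: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Channel-attention multiple-instance learning: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Whole-slide images are far too large to classify directly: a slide is
tessellated into thousands of small patches, each patch is embedded by an
external encoder into a feature vector, and only the *slide-level* label is
known. This is multiple-instance learning (MIL): a slide is a **bag** of
instance vectors `X ∈ R^{N×D}`, and a binary bag label obeys

> `Y = 1` if at least one instance is a *witness* of the positive class,
> `Y = 0` otherwise.

The aggregator studied here combines three ideas on top of the standard
attention-MIL recipe:

1. **Linear-complexity self-attention** over the instances (a Nyström
   approximation of softmax attention), so spatial context between patches
   is modelled even for very large bags;
2. a **multi-scale channel attention block (MCAB)** interleaved with the
   transformer layers, which reshapes the instance sequence onto its 2-D
   slide grid and applies depth-wise separable convolutions at two kernel
   sizes, re-weighted channel-wise by a shared-MLP gate;
3. **gated attention pooling**, which turns the contextualized instance
   tokens into one slide representation and, as a by-product, per-instance
   attention scores that can be rendered as an interpretability heatmap.

## Architecture

For a bag `X ∈ R^{N×D}` (default `D = 1024`):

```
tokens:   H0 = ReLU(X W + b)                          D -> d_model (512)
layer l:  Z^ = MHA(LayerNorm(H_{l-1})) + H_{l-1}       pre-norm residual
          H_l = MCAB(Z^)                               channel attention
pooling:  a_k = softmax_k( w' (tanh(V z_k) ⊙ σ(U z_k)) )
          h   = Σ_k a_k z_k
head:     binary: one sigmoid logit; C > 2: softmax
loss:     cross-entropy with probabilities clipped to [1e-7, 1 − 1e-7]
```

There is no feed-forward sublayer in the transformer block; spatial mixing
(attention) simply alternates with channel mixing (MCAB).

### Nyström attention

Exact softmax attention costs `O(N²)`. Per head, the approximation replaces
the `N×N` softmax matrix by

```
S ≈ softmax(Q K̃'/√d_q) · pinv(softmax(Q̃ K̃'/√d_q)) · softmax(Q̃ K'/√d_q)
```

where `Q̃, K̃` are `m` landmark rows formed as means of `m` contiguous token
segments. With `m = N` the landmarks are the tokens themselves and the
formula collapses to exact attention (the middle factor is the inverse of a
full-rank square matrix); this is the oracle identity the test suite checks
to `< 1e-4`.

The pseudo-inverse is computed on the differentiation tape with the
third-order Newton–Schulz iteration

```
V <- V (13 I − A V (15 I − A V (7 I − A V))) / 4,   V0 = A' / (‖A‖₁ ‖A‖∞)
```

whose initial scaling guarantees convergence. **Iteration count.** The
package default is `pinv_iterations = 20`. Small softmax kernel matrices
produced by random projections are surprisingly ill-conditioned (condition
numbers up to ~1e3 were measured at `m ≤ 16`), and at 6 iterations the
residual deviation from exact attention is still ~1e-2; 20 iterations bring
it to ~1e-6 while costing only `O(m³)` per step, negligible against the
attention itself. Users who need speed over fidelity at large `m` can lower
it.

The model's routing policy (`method = "auto"`) uses exact attention
whenever `N ≤ n_landmarks` (default 128): below that size the approximation
saves nothing.

### The channel block (MCAB) and token order

The `N` tokens are reshaped to the smallest `M×M` raster grid
(`M = ⌈√N⌉`), zero-padding the tail. Two branches apply depth-wise
convolutions (one `k×k` spatial filter per channel; defaults `3×3` and
`5×5`) followed by ReLU and a point-wise `1×1` convolution. The branch
outputs `Z1, Z2` and the identity path `Ẑ` are fused channel-wise:

```
F  = Z1 + Z2 + Ẑ
L  = MLP(maxpool(F)) + MLP(avgpool(F))      shared MLP, d -> d/r -> 3d
Z  = σ_τ(L1) ⊗ Z1 + σ_τ(L2) ⊗ Ẑ + σ_τ(L3) ⊗ Z2
```

with `σ_τ(x) = 1/(1 + exp(−τx))`. With all-zero MLP weights every gate is
exactly ½ and the block reduces to `(Z1 + Ẑ + Z2)/2` — a closed form the
tests verify bit-for-bit.

Because convolution reads grid neighbours, MCAB is the **only**
order-sensitive component: the attention layers and the pooling are
permutation-equivariant. The block therefore doubles as an implicit
positional encoding, and the `token_order` ablation (`ordered` vs
per-epoch shuffling) measures exactly this effect. A class token, when the
`class_token` pooling mode is chosen, bypasses the MCAB (it has no grid
position).

Numerical conventions worth stating explicitly:

* pooling in the channel gate runs over **all** `M²` grid positions,
  including the zero padding (padding is part of the block's definition,
  and keeping it makes the closed-form limit exact);
* branch outputs are not re-zeroed at padded positions between the
  convolution and the gate — padding tokens are dropped only when the grid
  is flattened back to the sequence;
* `max.col`-style arguments break ties towards the first index everywhere,
  keeping runs bit-reproducible.

## Training

Adam with decoupled weight decay (defaults `lr 1e-4`, `wd 1e-5`), one bag
per optimization step (variable bag sizes make larger batches pointless),
early stopping on validation loss with configurable patience, and the
best-validation parameters returned. All randomness — initialization,
epoch-level bag shuffling, the token-order ablation's shuffles — derives
from `config$seed`, so a run record is exactly reproducible.

The forward and backward passes are implemented on a small reverse-mode
automatic-differentiation tape written in base R over BLAS matrix
operations; gradient correctness is checked against central finite
differences in the test suite (worst relative error ~1e-7 at default
tolerances).

## The synthetic generator

Real benchmarks for this architecture require hundreds of gigabytes of
scanned slides and an external patch encoder. The package instead ships a
feature-space generator that reproduces the *statistical* structure of MIL:

* background instances `~ N(0, σ²I)`;
* witness instances `~ N(δ·u_c, σ²I)` along orthogonalized random unit
  directions `u_c` (one per positive class), so separability is controlled
  by `δ/σ` alone, independent of the feature dimension;
* positive bags contain `⌈witness_rate · N⌉` witnesses at random
  positions; negative bags contain none — the MIL semantics hold by
  construction, and the generator returns the witness masks so attention
  maps can be scored against ground truth;
* instances carry raster-grid coordinates, and bags can be grouped into
  patients for leakage-safe splitting (`split_bags` stratifies by label and
  never places one patient on two sides of a split).

**Limitations.** The generator is deliberately minimal: instances are
i.i.d. given their type, so there is no spatial correlation between
neighbouring patches, no encoder artefacts, no stain or scanner variation,
and witness difficulty does not vary within a bag. It validates the
machinery (recovery, enrichment, splits) — it does not emulate histology.

## A worked run

```{r}
library(camil)

spec <- synthetic_spec(n_bags = 200, bag_size_range = c(32, 128),
                       witness_rate = 0.3, feature_dim = 64,
                       separation = 3, noise_sd = 1, seed = 1)
ds <- generate_bags(spec)
sp <- split_bags(ds$bags, ratio = c(3, 1, 1), seed = 1)

config <- camil_config(input_dim = 64, max_epochs = 2, seed = 1)
fit <- camil(sp$train, val_bags = sp$val, config = config, verbose = TRUE)

ev <- evaluate_bags(fit, sp$test)
print(ev$report)

att <- export_attention(fit, sp$test[[1]])
head(att)
```

On a single CPU this trains in a few minutes and reaches AUC 1.0 on the
held-out patients; the attention scores of witness instances exceed the
background mean. The same flow is scriptable through the command-line
wrapper (`inst/cli/camil.R`) whose `simulate`, `train`, `evaluate`,
`export-attention` and `ablate` subcommands call exactly these functions.

## Design rationale, briefly

* **One fitting function, classic S3.** `camil()` returns an object with
  `print`, `summary`, `coef`, `predict` and `plot` methods; everything else
  (evaluation, ablation, attention export) is a plain function over that
  object. No frameworks, no non-base dependencies beyond `yaml` and
  `jsonlite` for serialization.
* **Text bag container.** Bags round-trip through a sectioned plain-text
  format with 17 significant digits (bit-exact for doubles). A text format
  keeps fixtures diffable and the reader trivially portable.
* **Oracles over snapshots.** Wherever a component has an independent
  mathematical description (exact attention, sliding-window convolution,
  Mann–Whitney AUC, the ½-gate closed form), the tests implement that
  description separately — usually as slow double loops — and compare.
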