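# camil

Channel-attention multiple-instance learning (MIL) for whole-slide image
classification, implemented as a classic R modelling package: one fitting
function, `camil()`, returning an S3 object with `print`, `summary`,
`coef`, `predict` and `plot` methods.

## The science

A gigapixel whole-slide image cannot be classified directly. It is
tessellated into thousands of patches, each embedded by an external
encoder into a feature vector, and only the slide-level label is known.
Formally a slide is a *bag* `X ∈ R^{N×D}` of instance vectors with the
standard MIL assumption: the bag is positive if and only if it contains at
least one *witness* instance of the positive class.

The aggregator implemented here stacks, per layer, a **pre-norm
multi-head self-attention block** (no feed-forward sublayer) with a
**multi-scale channel attention block (MCAB)**. Attention uses a Nyström
approximation — landmark means of contiguous token segments, with the
middle pseudo-inverse factor computed by a third-order Newton–Schulz
iteration on the differentiation tape — so a bag of `N` instances costs
`O(N)` rather than `O(N²)`. The MCAB reshapes the token sequence onto its
2-D slide raster, runs two depth-wise separable convolution branches
(default kernels 3×3 and 5×5), and fuses branch and identity paths with a
channel-wise sigmoid gate driven by a shared MLP over max- and
average-pooled descriptors. Because convolution reads grid neighbours,
MCAB is the model's only order-sensitive component and doubles as an
implicit positional encoding. A **gated attention pooler** then collapses
the contextualized tokens into one slide representation, yielding
per-instance attention scores that can be exported as an
interpretability heatmap; a sigmoid (or softmax) head produces the
prediction, trained with clipped cross-entropy under Adam with decoupled
weight decay.

Everything — forward pass, reverse-mode automatic differentiation,
optimizer — is written in base R over BLAS matrix operations. The only
runtime dependencies are `yaml` and `jsonlite` (serialization).

See the methods vignette (`vignettes/camil-methods.Rmd`) for the full
architecture, numerical conventions, and design rationale.

## Worked example

Real slides need hundreds of gigabytes plus an external patch encoder, so
the package ships a synthetic feature-space generator with known witness
structure: background instances `N(0, σ²I)`, witnesses displaced by `δ`
along orthogonalized random unit directions, positive bags containing
`⌈witness_rate·N⌉` witnesses, and ground-truth witness masks returned for
scoring attention maps.

```r
library(camil)

spec <- synthetic_spec(n_bags = 200, bag_size_range = c(32, 128),
                       witness_rate = 0.3, feature_dim = 64,
                       separation = 3, noise_sd = 1, seed = 1)
ds <- generate_bags(spec)
sp <- split_bags(ds$bags, ratio = c(3, 1, 1), seed = 1)   # patient-safe

fit <- camil(sp$train, val_bags = sp$val,
             config = camil_config(input_dim = 64, max_epochs = 2, seed = 1))
print(fit)

ev <- evaluate_bags(fit, sp$test)
print(ev$report)

att <- export_attention(fit, sp$test[[1]])
head(att, 3)
```

Output of this exact script on one CPU (about five minutes end to end):

```
CAMIL model: 4 x (transformer + MCAB), d_model 512, pooling attention, 2 classes
  trained 2 epoch(s) on 120 bags; best val loss 0.0004 at epoch 2
MIL metrics over 40 slides (2 classes)
  accuracy 1.0000 | F1 1.0000 | AUC 1.0000
  TP 20 TN 20 FP 0 FN 0 (P = 20, N = 20)
   slide_id instance_index x y attention_score
1 slide_004              1 0 0     0.012864509
2 slide_004              2 1 0     0.011418577
3 slide_004              3 2 0     0.008762768
```

The attention scores land preferentially on the true witnesses: pooling
over all positive test bags, the mean witness attention exceeds the mean
background attention (enrichment ratio 1.0075 on this run at seed 1,
1.0082 and 1.0222 at seeds 2 and 3; the ratio grows with longer training
as the pooler sharpens — e.g. 1.027 → 1.077 from 2 to 10 epochs at
`d_model = 64`).

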