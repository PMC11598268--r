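---
title: "Sparse low-rank pruning of fall-detection networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse low-rank pruning of fall-detection networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(slrprune)
```

## The problem

Vision-based fall detection classifies short video clips of a person into
fall types and activities of daily living (ADLs). The networks that do this
well are dominated, parameter-wise, by their first fully-connected (FC)
layers, which makes them awkward to deploy on the resource-constrained
devices where an immediate, local response matters. `slrprune` implements
the sparse low-rank (SLR) compression of those layers, two reference
backbones to compress, a synthetic data generator so the whole pipeline
runs with no external download, and the training/evaluation harness that
ties them together.

## The SLR method

A fully-connected layer with `m` input and `n` output neurons computes
`a = g(W'X + b)` with `W ∈ R^{m×n}`. SLR compresses `W` in three steps:

1. **SVD.** `W = U diag(S) V'`, singular values non-increasing.
2. **Rank truncation.** Only the `k` leading singular components are kept
   (`k` is the *reduction rank*). By the Eckart–Young theorem the
   reconstruction `U_k diag(S_k) V_k'` is the best rank-`k` approximation
   of `W` in Frobenius norm, and its error is the root-sum-square of the
   discarded singular values — an identity the test suite checks against an
   independent eigen-decomposition oracle.
3. **Intra-vector sparsification.** Within each kept column of `U` and row
   of `V'`, only the `ceiling(density · length)` entries of largest
   absolute value are stored (*density*, default 0.5); the rest become
   structural zeros. Ties are broken toward the lowest index so results are
   deterministic. The singular values and the bias stay dense.

Inference never materialises the reconstructed matrix: the forward pass is
three small products, `((X U_k) * S_k) V_k' + b`.

Only FC6 and FC7 are pruned. The final softmax classifier (FC8) is left
untouched and the configuration validator rejects it, as it rejects
convolutional and recurrent layers: pruning FC layers gives most of the
size reduction at the least accuracy cost, and the conv stack carries the
feature extraction.

### Component selection

One published description of the row/column selection is magnitude-based
("rows and columns whose absolute values are highest"). Because the SVD
already orders components so the dominant ones come first, keeping the `k`
*leading* singular components is consistent with both that description and
with standard truncated SVD, and is what `truncate_components()` does; the
absolute-magnitude criterion governs the intra-vector sparsification. The
orientation convention (components are columns of `U` and rows of `V'`) is
recorded in the container manifest.

## Parameter accounting

Two storage conventions are computed everywhere and printed side by side:

* **values** — counts stored numeric values only: a pruned layer stores
  `k·⌈density·m⌉ + k + k·⌈density·n⌉ + n`; a dense layer `m·n + n`.
* **values+indices** — additionally counts two integer coordinates per
  structurally stored sparse entry, which is what a coordinate-format
  sparse container actually writes. This is the headline convention used by
  the acceptance script, because a sparse factor without its indices cannot
  be decoded.

Reductions can be reported over the whole model (default) or over the
pruned layers only (`basis = "fc"`). Sizes in MB assume 4 bytes per stored
value (single precision), stated in every printout. Index/pointer overhead
beyond the two coordinates (e.g. container framing) is never counted.
`ceiling()` is used for `density · length` so that "half of the elements"
of an odd-length vector keeps at least half.

## The backbones

`build_cnn2d()` stacks `T` RGB frames along the channel axis (default 36
frames of 32×32×3, i.e. a 32×32×108 input) and applies three valid,
stride-1 3×3 convolution stages with 8, 32 and 128 feature maps, the first
two followed by 2×2 max pooling and batch normalization, then dense layers
of 1200 (FC6), 600 (FC7) and `num_classes` (FC8, softmax) units with
dropout (default 0.3) after FC6/FC7.

`build_cnn_lstm()` flattens each frame to one step of a feature sequence
(default 192 steps of 3072 features) and applies two 1D convolution stages
(8 and 32 maps, kernel 3) with window-2/stride-2 pooling and batch
normalization, an LSTM with 32 units returning the full sequence, then the
same dense head.

Conventions worth stating explicitly, since nominal architecture tables in
this literature are not always self-consistent:

* **Pooling** is window 2, stride 2, floor division. This is the only
  choice that reproduces the nominal 1D output sizes (190→95, 93→46) and
  the flatten width 46·32 = 1472.
* **Flatten width of the 2D-CNN.** With the stacked-channel input the
  propagated flatten width is 2048, while the nominal table value is 1472
  (the value the 1D/LSTM branch produces). Executable models always use the
  propagated width; `flatten = "table"` builds an accounting-only spec with
  the nominal width so that both backbones carry the identical dense head
  when comparing stored-parameter arithmetic. `init_network()` refuses to
  instantiate a spec whose nominal width disagrees with propagation.
* **LSTM gates** use the standard sigmoid/tanh parameterisation with
  forget-gate bias initialised to 1 and the usual 4-gate parameter count
  `4(u(u+f)+u)`; batch normalization counts `4·channels` values (scale,
  shift and the two running moments).

## Training engine

No deep-learning framework is available to R in this package's dependency
footprint, so a compact engine implements exactly what the backbones need:
im2col-based valid convolutions (so the inner products run through BLAS),
max pooling with deterministic earliest-element tie-breaking,
batch normalization, backpropagation-through-time for the LSTM, dropout,
and Adadelta. Defaults follow the reference protocol: learning rate 0.98,
categorical cross-entropy, batch size 32, 50 epochs; Adadelta uses
ρ = 0.95 and ε = 1e-7. Weights are initialised with uniform fan-based
(Glorot) draws; all randomness — initialisation, shuffling, dropout,
fold assignment — derives from explicit integer seeds, and retraining with
the same seed is bit-reproducible.

Two numerical details matter at the short training lengths this package
targets:

* **Batch-norm running moments** are exponential moving averages with
  momentum 0.99 *and bias correction* (division by `1 − 0.99^t`). Without
  the correction the inference statistics are still dominated by their
  initialisation after a few hundred updates and held-out accuracy
  collapses even when training-mode accuracy is high.
* **Loss guards**: a non-finite loss aborts with a "training diverged"
  error; softmax and the cross-entropy clamp probabilities at 1e-12.

Gradient correctness is verified in the test suite by central-difference
numerical differentiation through every layer type.

## Evaluation

`confusion_metrics()` reports accuracy plus micro- and macro-averaged
precision and recall. For single-label data micro precision, micro recall
and accuracy coincide exactly (an algebraic identity the suite asserts);
macro averages are the unweighted per-class means, excluding classes absent
from the truth, with never-predicted classes contributing precision 0.
Both averaging families are always computed because published tables in
this area sometimes label unequal accuracy/precision/recall triples
"micro", which is impossible for single-label micro averaging; the
rank-sweep tables show macro rows first. `kfold_cv()` uses stratified folds
(10 by default), a recorded fold seed, a fresh initialisation per fold, and
tests every sample exactly once; per-fold rows export to CSV and the
mean/sd summary to JSON. Whether to read per-fold means or pooled metrics
is left to the consumer — both are derivable from the per-fold export.

## The synthetic generator

`make_dataset()` renders a bright ellipsoidal figure on a constant grey
background (level 0.25) with additive Gaussian pixel noise (σ = 0.05 by
default), 36 frames of 32×32×3 per sequence, matching the 2D backbone's
default input and reshaped automatically for the CNN-LSTM. The default
catalogue mirrors the benchmark class structure: five fall classes
(forward onto hands, forward onto knees, backward, lateral, collapse while
sitting) with accelerating late descents ending in a horizontal posture,
each with a distinct direction and timing; and six ADLs (walk, stand, sit,
pick up, jump, lie down slowly) with level or slow, non-accelerating
motion. Per-sequence jitter (start position, ±10% speed, walk direction)
comes from a per-sequence seed derived from the master seed, so datasets
are bit-reproducible and datasets with different master seeds share no
tensor.

The trajectory equations are artifact choices: the generator emulates the
*class structure and motion statistics* that make fall detection learnable
(including the designed near-confusion between fast falls and slow
lying-down), not the appearance of real video — no camera geometry,
occlusion, lighting variation, multiple people, or background clutter.
Passing tests therefore demonstrate that the pruning pipeline preserves a
learnable signal end-to-end; they say nothing about accuracy on real
recordings. A minimal linear classifier on per-frame centroid features
separates fall from non-fall on held-out sequences, which is the designed
guarantee that the harness has signal for pruning to preserve.

## What pruning preserves at desk scale

The end-to-end acceptance run (11 classes, 40 sequences per class, 10
epochs, fixed seed) trains the CNN-LSTM, prunes FC6/FC7 at rank 8 and
density 0.5, and verifies that unpruned held-out accuracy exceeds 0.8 with
a pruned-vs-unpruned gap under 15 percentage points.

The choice of backbone for that run is substantive, not cosmetic. A weight
matrix trained briefly from a random initialisation is the sum of a
full-spectrum random matrix and a comparatively small learned update, so a
rank-8 truncation of a very wide FC6 (2048×1200 in the 2D-CNN) keeps
essentially arbitrary initialisation directions and discards the learned
component; the 2D-CNN therefore needs substantially higher ranks to stay
within the gap at this training scale. The CNN-LSTM's FC6 is far narrower
(its input is the LSTM feature sequence), rank 8 is a meaningful fraction
of its spectrum, and it retains accuracy — consistent with rank-8 pruning
being reported as most favourable for the CNN-LSTM variant in this
literature. Compressing heavily over-parameterised layers trained to
convergence on large datasets is exactly the regime SLR is designed for;
a desk-scale harness sits at the opposite end of that regime.

## Problem sizes and runtime choices

The test suite keeps its own problem sizes small as a design choice:
gradient checks use 18×18 inputs and four samples; cross-validation and
container tests use a two-layer perceptron on a separable toy problem; the
synthetic-experiment smoke test uses 2 sequences per class, 12 frames of
18×18, 2 folds and 1 epoch; the single full-size end-to-end run uses the
defaults above. Bit-exact report reproducibility is demonstrated by double
runs at the reduced size. The acceptance script is purely structural
(parameter arithmetic over the declared architectures) and runs in
seconds.

## Known limitations

* The engine is CPU-only, single-threaded R; it is meant for desk-scale
  verification, not large-scale training.
* Pruned models are inference-only; there is no fine-tuning after pruning
  (backpropagation through the sparse factors is deliberately not
  implemented, matching the prune-then-evaluate protocol).
* Convolutional and recurrent layers are never pruned, by policy.
* Stored-size figures are conventions (4 bytes/value, optional 2-integer
  coordinates per sparse entry), not measurements of any particular
  serialisation format.
* The PNG frame exchange format quantises pixels to 8 bits; re-imported
  datasets are equal only to within half a grey level.
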