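# slrprune

Sparse low-rank (SLR) pruning of the fully-connected layers of vision-based
fall-detection networks, with everything needed to exercise the method
end-to-end on one CPU: two reference backbones (a 2D-CNN over stacked video
frames and a CNN-LSTM over frame sequences), a deterministic synthetic
fall/ADL sequence generator, a small pure-R training engine, stratified
k-fold evaluation, and parameter-accounting/rank-sweep reports.

## Who this is for

Researchers and engineers who need fall-detection (or similar
frame-sequence classification) models small enough for embedded
deployment, and who want a reproducible, dependency-light harness for
studying how much accuracy SVD-based compression of the dense head costs.

## The method

A fully-connected layer with `m` inputs and `n` outputs computes
`a = g(WᵀX + b)`. SLR replaces `W ∈ R^{m×n}` by sparse low-rank factors:

1. SVD: `W = U diag(S) Vᵀ`;
2. keep the `k` leading singular components (*reduction rank*); by
   Eckart–Young this is the best rank-`k` approximation, with Frobenius
   error `sqrt(Σ_{i>k} Sᵢ²)`;
3. within each kept singular vector, store only the `⌈density·length⌉`
   entries of largest absolute value (*density*, default 0.5).

The pruned layer stores `k⌈density·m⌉ + k + k⌈density·n⌉ + n` values
instead of `mn + n`, and computes `((X U_k) ∗ S_k) Vₖᵀ + b` without ever
rebuilding the dense matrix. Only the first two dense layers (FC6, FC7) are
pruned; the softmax classifier is untouched by policy.

## Worked example

Prune an FC6-sized dense layer (1472 → 1200) at rank 8, density 0.5:

```r
library(slrprune)
set.seed(1)
lyr <- dense_layer(matrix(rnorm(1472 * 1200), 1472, 1200), name = "FC6")
slr <- slr_prune(lyr, k = 8, density = 0.5)
slr
#> SLR factors of 'FC6': rank 8, density 0.50, 1472 -> 1200
#>   stored values: 11,896 (dense layer: 1,767,600)
reduction_percent(stored_param_count(lyr), stored_param_count(slr))
#> [1] 99.32704
```

The 11,896 stored values are 8 sparsified columns of `U` (736 entries
each), 8 singular values, 8 sparsified rows of `Vᵀ` (600 entries each) and
the 1200 dense biases — a 99.3 % reduction for this single layer.

Sweep reduction ranks over a whole backbone (structural accounting, no
training needed):

```r
slr_sweep("cnn_lstm", ranks = c(8, 12, 16))
#> SLR rank sweep | model cnn_lstm | density 0.50 | FC6/FC7
#>                              rank_8 rank_12 rank_16 no_reduction
#> param_reduction_values        95.76   95.41   95.06            0
#> param_reduction_with_indices  94.37   93.33   92.29            0
#> model parameters: 2,577,827 (10.31 MB at 4 bytes/value)
```

Two storage conventions are always shown: counting stored numeric values
only, and counting each sparse entry's value plus its two integer
coordinates (what a coordinate-format container writes). Reductions shrink
as the rank grows, in both conventions.

End-to-end on synthetic data — generate sequences, train, prune, compare:

```r
ds  <- make_dataset(n_per_class = 40, seed = 11)
dat <- dataset_to_sequence(ds)
cmp <- prune_and_compare(build_cnn_lstm(11, input_shape = c(36, 1024, 3)),
                         dat$x, dat$y,
                         prune_config(c(FC6 = 8, FC7 = 8), density = 0.5),
                         hp = hyper_params(epochs = 10, seed = 11))
cmp$original; cmp$pruned
```

A shell front end with `build`, `size`, `sweep`, `run-synthetic`, `prune`
and `evaluate` subcommands ships at `inst/cli/slrprune.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "slrprune.R", package = "slrprune"))')" \
  sweep --model cnn2d --ranks 8,12,16
```

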