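# gatformer

Spatiotemporal seizure detection from multi-channel scalp EEG, combining a
**graph attention network** over per-window functional-connectivity graphs
with a **Transformer encoder** over sequences of window encodings.

## Who this is for

Researchers working on automated seizure detection who want a complete,
inspectable reference implementation of the correlation-graph + GAT +
Transformer detector family: EDF/RDS readers, bipolar-montage channel
selection, zero-phase bandpass filtering, sliding-window segmentation and
labelling, 1:1 class balancing, focal-loss training, stratified ten-fold
cross-validation, and an ablation harness — plus an annotated synthetic EEG
generator so the whole pipeline runs and is tested without access to
clinical corpora.

## The model

Each 1-s window of an M-channel recording becomes a graph: nodes are
channels, node features are the raw samples, and an edge joins channels
*i, j* when their Pearson correlation satisfies |r_ij| ≥ τ (default
τ = 0.3; self-loops always present). A two-layer, 8-head graph-attention
encoder aggregates spatially:

    e_ij = LeakyReLU( aᵀ [W k_i ‖ W k_j] ),  j ∈ V_i
    α_ij = softmax_j(e_ij)                    (over the neighborhood of i)
    k′_i = σ( (1/Q) Σ_q Σ_{j∈V_i} α_ij^q W_q k_j )

Sequences of N = 8 consecutive window encodings are flattened, linearly
projected to dimension D, prepended with a class token, given sinusoidal
positional embeddings, and passed through L = 4 pre-norm Transformer
blocks:

    H′ = MSA(LN(H)) + H
    H  = MLP(LN(H′)) + H′

The class token's final state feeds a softmax head. Training minimises the
focal loss FL(p, y=1) = −α(1−p)^γ log p (α = 0.25, γ = 2) with Adam
(lr 0.001, batch 64), and evaluation reports accuracy, sensitivity,
specificity, F1 and AUC over stratified ten-fold cross-validation.

See `vignette("seizure-detection-methods")` for assumptions, parameter
rationale, and design decisions.

## Worked example

A miniature subject (8 channels, 4 minutes at 64 Hz, ~108 s of seizure
activity) and a reduced model, end to end:

```r
library(gatformer)

rec <- make_subject(sim_config(n_channels = 8, duration_s = 240, fs = 64,
                               seizure_rate = 12, seizure_len_s = c(8, 12),
                               seed = 42))
rec
#> <eeg_record> subject 'sim042': 8 channels x 15360 samples @ 64 Hz (240.0 s)
#>   11 seizure interval(s), 108.2 s total

ws <- segment_windows(bandpass(rec, 0.5, 28), window_s = 1, overlap = 0.5)
ws
#> <window_set> 479 windows of 8 channels x 64 samples @ 64 Hz
#>   labels: 217 seizure / 262 non-seizure

build_graph(get_window(ws, 10)$data, tau = 0.3)
#> <channel_graph> 8 nodes, 6 edges (tau = 0.3), 64 features/node

cfg <- gatformer_config(n_seq = 4, gat_hidden = 8, gat_out = 8, gat_heads = 8,
                        D = 32, t_heads = 4, mlp_hidden = 64, L = 4,
                        epochs = 30, n_folds = 5, seed = 7)
fit <- gatformer(ws, cfg)
fit
#> <gatformer> combined model, 8 channels x 64 samples/window, n_seq 4
#>   trained on 496 samples, 30 epochs; focal loss 0.1994 -> 0.0027

gatformer_cv(ws, cfg)
#> <gatformer_cv> combined model, 5-fold CV on 476 samples (0: 248, 1: 228)
#> <eval_report> 5 folds (values in %, mean +/- sd)
#>   accuracy      93.07 +/- 1.07
#>   sensitivity   85.51 +/- 2.35
#>   specificity  100.00 +/- 0.00
#>   f1            92.17 +/- 1.36
#>   auc           99.40 +/- 1.04
```

Reading the output: 479 one-second windows (50% overlap) are cut from the
240-s record and labelled by majority overlap with the annotated seizure
intervals; sequences of 4 windows are the classification samples. The
training focal loss falls from 0.20 to 0.003 over 30 epochs, and held-out
folds of the 5-fold cross-validation classify ~93% of samples correctly
with perfect specificity — on this easy synthetic task the detector's
errors are a few missed windows near seizure boundaries (sensitivity
85.5%), while the near-unit AUC shows the ranking is almost perfect. At the
full protocol scale (3,000-s subject, 16 channels, ten folds) the detector
reaches ~99% mean accuracy; `scripts/acceptance.R` reproduces that run.

Every model accepts `mode = "gat_only"` or `"transformer_only"` in its
configuration for ablation comparisons, and `predict()` scores new window
sets with the stored normalization and graph threshold.

There is also a command-line surface:

```sh
Rscript inst/cli/gatformer.R simulate   --out subject.edf --seed 1
Rscript inst/cli/gatformer.R preprocess --input subject.edf --out windows.rds
Rscript inst/cli/gatformer.R crossval   --input windows.rds --out report/
```

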