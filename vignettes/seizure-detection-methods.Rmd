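---
title: "Spatiotemporal seizure detection: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatiotemporal seizure detection: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Scalp EEG seizure detection is a binary classification task over short
segments of a multi-channel recording: label each 1-second window (or short
sequence of windows) ictal or interictal. Two kinds of structure carry
signal. *Spatial*: during seizures, the statistical coupling between
channels strengthens and reorganises; *temporal*: ictal activity is rhythmic
and evolves over seconds. `gatformer` couples a graph-attention encoder over
a per-window functional-connectivity graph (spatial) with a Transformer
encoder over a sequence of consecutive window encodings (temporal), trained
end-to-end under focal loss.

# The model

## Window graphs

Each 1-s window of the bipolar-montage recording is mapped to a graph whose
nodes are channels. The edge rule is Pearson correlation thresholding: for
channels $i, j$ with window samples $x_i, x_j \in \mathbb{R}^F$,

$$r_{ij} = \frac{C(x_i, x_j)}{S(x_i)\,S(x_j)}, \qquad
  A_{ij} = \mathbb{1}\{|r_{ij}| \ge \tau\},$$

with self-loops forced on the diagonal. Node features are the raw window
samples (per-channel z-scored with statistics from the training folds only).
Three conventions are deliberate:

* **Absolute value.** Correlation strength matters as it approaches either
  $+1$ or $-1$; strong anticorrelation also creates an edge.
* **Self-loops.** Aggregation runs over first-order neighborhoods; a node
  with no strong partner would otherwise have an empty neighborhood and an
  undefined attention softmax. Including $i \in V_i$ is also standard
  graph-attention practice.
* **Boundary.** $|r| = \tau$ counts as an edge (values *below* the threshold
  are dropped).
* **Degenerate channels.** A zero-variance channel gets correlation 0 to
  every other channel and keeps only its self-loop; `pearson_r()` returns 0
  rather than NaN in that case.

The default $\tau = 0.3$ is a design choice the literature leaves open:
$|r| < 0.2$ is conventionally "very weak or no correlation", so 0.3 discards
weak edges while keeping synthetic-subject graphs connected. It is
configurable (`tau`).

## Spatial encoder (graph attention)

Per head $q$ with shared linear map $W_q$ and attention vector
$a = [a_1; a_2]$, attention scores over neighborhoods are

$$e_{ij} = \mathrm{LeakyReLU}\!\left(a_1^\top W_q k_i + a_2^\top W_q k_j\right),
\qquad
\alpha_{ij} = \frac{\exp e_{ij}}{\sum_{r \in V_i} \exp e_{ir}},$$

computed with the usual per-row max subtraction for numerical stability.
The layer output averages heads rather than concatenating them:

$$k_i' = \sigma\!\Big(\tfrac{1}{Q}\sum_{q=1}^{Q}\sum_{j \in V_i}
  \alpha_{ij}^q W_q k_j\Big).$$

Averaging is applied in *both* layers. Standard GAT implementations
concatenate heads in hidden layers and average only at the output; we follow
the averaged form throughout because that is the form the architecture is
specified in, and note the deviation from common practice here. Two layers
with $Q = 8$ heads each are the default. The output nonlinearity $\sigma$ is
ELU (configurable to ReLU or identity), the LeakyReLU slope is 0.2 — both
standard choices where the architecture leaves them open. Dropout (rate 0.5)
is applied to each layer's output during training, not to the attention
coefficients.

## Temporal encoder (Transformer)

A classification sample is $N$ consecutive windows (default $N = 8$, stride
one window step). Each window passes the spatial encoder with shared
weights; its $M \times F'$ output is flattened column-major and projected by
a linear map $E$ to dimension $D$. A learned class token is prepended at
position 0 and a *fixed* sinusoidal positional table is added:

$$H_0 = [\,k'_{\mathrm{class}},\, E v_1, \dots, E v_N\,] + E_{pos},
\qquad
E_{pos}[p, 2i] = \sin\frac{p}{10000^{2i/D}},\;
E_{pos}[p, 2i{+}1] = \cos\frac{p}{10000^{2i/D}}.$$

$L = 4$ pre-norm encoder blocks follow, with LayerNorm *inside* each
residual branch, taken literally from the stated recurrences:

$$H'_l = \mathrm{MSA}(\mathrm{LN}(H_{l-1})) + H_{l-1}, \qquad
  H_l = \mathrm{MLP}(\mathrm{LN}(H'_l)) + H'_l.$$

MSA is standard scaled dot-product multi-head self-attention (default 4
heads); the MLP is $D \to 4D \to D$ with GELU. The class token's final state
passes a LayerNorm and a linear map to two logits, then softmax. With all
MSA/MLP weights zero each block is an exact identity — a property the test
suite asserts at every depth.

The sequence construction is an interpretation: the architecture is
specified for one window's feature map yet describes a sequence of 1-s
slices and a decision that uses "the states before and after the current
moment". Treating $N$ consecutive windows as the token sequence (sample
label = majority of window labels, ties counting as seizure) preserves both
statements; `n_seq` is configurable.

## Loss

Focal loss with $\alpha = 0.25$, $\gamma = 2$:

$$\mathrm{FL}(p, y) = \begin{cases}
 -\alpha (1-p)^\gamma \log p & y = 1\\
 -(1-\alpha)\, p^\gamma \log(1-p) & y = 0,
\end{cases}$$

with $p$ clamped to $[10^{-7}, 1-10^{-7}]$. Note that at $\gamma = 0$ this
is the *α-weighted* cross-entropy; it equals plain cross-entropy only at
$\alpha = 0.5$ and then up to the factor $\tfrac12$. The implementation is
verbatim; the test suite pins the $\gamma = 0,\ \alpha = 0.5$ identity at
$10^{-12}$.

# Training and evaluation protocol

* **Windowing**: 1-s windows, overlap 0.5, trailing remainder dropped;
  $K = \lfloor (T - w)/(w(1-\mathrm{overlap})) \rfloor + 1$ windows (a 60-s
  record gives 119).
* **Labels**: a window is seizure if at least 50% of its span lies inside an
  annotated interval; exact ties label 1 (sensitivity-favouring). The
  threshold is configurable.
* **Balance**: 1:1 by oversampling the minority class with replacement
  (whole-sample duplicates, no jitter); applied to *training* folds only,
  after the fold split, so no duplicate straddles train/test.
* **Normalization**: per-channel mean/sd fitted on the training folds'
  windows, applied everywhere; sd floored at $10^{-8}$.
* **Optimization**: Adam at learning rate 0.001, batch size 64, 100 epochs
  (defaults), dropout 0.5, seeded shuffling; single-threaded and
  deterministic given the seed.
* **Cross-validation**: stratified ten-fold at the sequence-sample level.
  The default fold assignment (`fold_method = "block"`) keeps each class's
  samples time-contiguous per fold, because 50%-overlapping windows shared
  between neighbouring sequences would otherwise leak across folds; purely
  random stratification is available (`"random"`) as the more literal
  reading of the protocol.
* **Metrics**: accuracy, sensitivity, specificity, F1 (harmonic mean of
  precision and recall) and AUC per fold; aggregate mean with *population*
  (divide-by-$k$) standard deviation. Zero-denominator metrics report 0 with
  a warning, never NaN. The printed F1 formula in the source material is
  garbled; the harmonic-mean form its text describes is implemented. AUC is
  the rank-based (Mann-Whitney) statistic with midrank tie handling, which
  equals the trapezoidal area under the empirical ROC; it is cross-checked
  against `pROC` in the tests.

The ablation harness trains the same protocol in three modes: `combined`
(full pipeline), `gat_only` (spatial encoder, mean-pool over nodes and
windows, linear head) and `transformer_only` (raw flattened window slices
tokenized directly).

# The synthetic-data generator

Clinical corpora with annotated seizures cannot ship with a package, so
every stage is exercised on synthetic subjects whose statistical structure
matches what the method exploits:

* **Background**: channels mix one shared band-limited (0.5–30 Hz) latent
  source with independent noise, $x_i = \sqrt{c}\,\ell + \sqrt{1-c}\,n_i$
  with $c$ = `base_coupling`, giving expected pairwise correlation exactly
  $c$ (both components are variance-normalised). Amplitudes are scaled to
  ~30 µV.
* **Seizures**: interval count is Poisson(`seizure_rate`), lengths uniform
  in `seizure_len_s`, placed disjointly with exchangeable gaps. Within an
  interval the generator adds a coherent rhythm at `osc_freq_hz` (10%
  frequency jitter per seizure, one harmonic at $2f$) plus independent
  band-limited noise, with the two amplitudes solved so that within-seizure
  standard deviation is `seizure_amp_gain` times background *and* pairwise
  correlation reaches `seizure_coupling`. Activity ramps on/off over 1 s.
* **Defaults** emulate the single-subject protocol the detector targets:
  3,000 s at 256 Hz, 16 channels, ~25 seizures of 40–80 s so that seizure
  and normal time are roughly 1:1 (the protocol balances 1,500 s of each),
  gain 3, coupling 0.2 → 0.7, 4 Hz rhythm. With these settings a plain
  variance threshold on 1-s windows already separates the classes with
  ≥ 90% accuracy — the generator *guarantees a solvable task*, which is
  what makes the end-to-end learning test meaningful.

What the generator does **not** emulate: artifacts (blinks, electrode pops,
muscle), 1/f spectral shape, nonstationary background, realistic spike-wave
morphology, or patient-to-patient variability. Green tests therefore
demonstrate that the pipeline is implemented correctly and can learn a
separable spatiotemporal signature — not that clinical performance figures
transfer to real EEG.

# Numerical and engineering choices

* **Bandpass**: zero-phase Butterworth (`signal::filtfilt`), default band
  0.5–48 Hz — the standard scalp-EEG band excluding mains frequency, left
  open by the protocol. The default design order is 6: at 256 Hz a
  forward-backward order-4 design attenuates a 60 Hz tone only to ~28% RMS,
  while order 6 reaches ~3%, meeting the package's own stop-band target of
  < 5%; orders much beyond 6 are numerically unstable in transfer-function
  form at these sampling rates.
* **Rounding**: window starts are computed in seconds and rounded to the
  nearest sample, so fractional-sample steps (e.g. 0.5-s hops at odd rates)
  stay aligned with the count formula.
* **Initialization**: Xavier-uniform for all linear maps and attention
  vectors, LayerNorm gains 1 / biases 0, class token $\mathcal{N}(0,
  0.02^2)$; one integer seed drives initialization, folds, balancing,
  shuffling and dropout through private RNG streams that never disturb the
  caller's RNG.
* **Two implementations, one model**: every operation (attention, GAT
  layer, tokenizer, encoder block, classifier head) exists as readable
  plain-R reference code, and the training engine re-implements the batched
  forward/backward in RcppArmadillo for speed. The suite pins the two paths
  together at $10^{-12}$ on random instances and checks every analytic
  gradient against central finite differences.
* **EDF**: a minimal 16-bit EDF writer/reader (one data record per second,
  symmetric integer physical ranges, CSV annotation sidecar) covers the
  interchange format; the lossless R-native bundle is RDS.

# Problem sizes in the shipped checks

The test suite and `scripts/acceptance.R` run the full protocol on one
synthetic subject (3,000 s, 16 channels, ten folds) at a reduced model
scale chosen for desk hardware: $D = 32$, 8-dimensional GAT heads
(`gat_hidden = gat_out = 8`), MLP width 128, 4-window sequences
(`n_seq = 4`) and 10 epochs. On this task the
scaled model is already heavily over-parameterised — training focal loss
falls below $10^{-2}$ within two epochs and held-out fold accuracy exceeds
99% — so the reduction does not weaken the check. Unit tests use smaller
subjects (60–240 s, 8 channels at 64 Hz) and miniature models.

# Known limitations

* Metrics are window/sequence-level; event-level measures (onset latency,
  false alarms per hour) are out of scope.
* Single-subject evaluation only; no cross-patient generalisation.
* All records must share one sampling rate; no resampling or artifact
  rejection is performed.
* The statistical test behind per-patient significance values in the
  surrounding literature is unspecified and is not implemented.
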