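---
title: "Decoding single-trial decisions from ERP epochs with t-SNE features and an LSTM"
author: "erpdecode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding single-trial decisions from ERP epochs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`erpdecode` decodes a binary behavioral decision (accept / reject) from a
single unaveraged EEG epoch. The pipeline has two learned stages wrapped
in a fixed preprocessing and evaluation harness.

**Feature stage (t-SNE).** Every (trial, channel) time series is treated
as one high-dimensional datapoint. Similarities in the input space are
Gaussian conditional probabilities

$$p_{j|i} = \frac{\exp(-\|D_i - D_j\|^2 / 2\sigma_i^2)}
                 {\sum_{k \ne i} \exp(-\|D_i - D_k\|^2 / 2\sigma_i^2)},$$

with $p_{i|i} = 0$ and each bandwidth $\sigma_i$ found by bisection so
that the row's Shannon perplexity $2^{H(P_i)}$ equals a target (default
30, clamped to $(n-1)/3$ for small $n$, never below 2). The symmetric
joint form $p_{ij} = (p_{j|i} + p_{i|j})/2n$ is paired with Student-t
similarities in the embedding,
$q_{ij} \propto (1 + \|d_i - d_j\|^2)^{-1}$, and the Kullback–Leibler
cost $C = \sum_{ij} p_{ij} \log(p_{ij}/q_{ij})$ is minimized by momentum
gradient descent using

$$\frac{\partial C}{\partial d_i} =
  4 \sum_j (p_{ij} - q_{ij}) (d_i - d_j) (1 + \|d_i - d_j\|^2)^{-1}.$$

A note on formulation: the per-point (conditional) normalization of the
Student-t similarities and the prefactor-4 gradient belong to two
different members of the SNE family. The gradient above is exact for the
symmetric joint objective, which is the package default (`mode =
"joint"`); a literal conditional mode is kept behind a flag, with its own
analytic gradient
$2\sum_j (p_{j|i} + p_{i|j} - q_{j|i} - q_{i|j}) w_{ij} (d_i - d_j)$.
Either way the binding correctness contract — enforced in the test suite
— is agreement of the implemented gradient with central finite
differences of the implemented cost.

**Classifier stage (LSTM).** The embedded features are ordered into one
sequence per trial, one step per channel in montage order, five features
per step (the alternative transposed orientation is available). The
recurrent cell follows the standard gated equations: with
$z_t = [h_{t-1}, I_t]$,

$$f_t = \sigma(W_f z_t + b_f),\quad
  U_t = \sigma(W_U z_t + b_U),\quad
  O_t = \sigma(W_o z_t + b_o),$$
$$\bar c_t = \tanh(W_c z_t + b_c),\quad
  C_t = f_t \odot C_{t-1} + U_t \odot \bar c_t,\quad
  h_t = O_t \odot \tanh(C_t),$$

with $h_0 = C_0 = 0$. In sequence-to-label mode the final hidden state
feeds dropout (rate 0.2, inverted scaling, identity at evaluation), a
2-unit dense layer and softmax; the loss is mean categorical
cross-entropy. Training is stochastic gradient descent with momentum:
`velocity = momentum * velocity - lr * gradient; params += velocity`,
learning rate 0.001, batch size 100, exactly
`epochs * ceiling(n / batch)` iterations over per-epoch shuffles, stopped
at 20 epochs. The gradients come from hand-derived backpropagation
through time and must match central finite differences within $10^{-4}$
relative on small networks — the same binding contract as for t-SNE.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `perplexity` | 30 | affinity calibration target (dimensionless); clamped to $(n-1)/3$, never below 2 |
| `dims` | 5 | embedding dimensionality per (trial, channel) |
| `iterations` | 1000 (`run_tsne`), 250 in the pipeline default | gradient-descent steps |
| `learning_rate` (t-SNE) | 100 | step size of the embedding descent |
| momentum (t-SNE) | 0.5 → 0.8 after iteration 250 | velocity coefficients |
| early exaggeration | ×4 for 50 iterations | affinity inflation to form clusters early |
| `lstm_hidden` | 80 | LSTM hidden units |
| `dropout` | 0.2 | dropout rate after the LSTM |
| `learning_rate` (SGDM) | 0.001 | classifier step size |
| SGDM momentum | 0.9 | velocity coefficient (a standard toolchain default; not dictated by the problem) |
| `epochs` / `batch_size` | 20 / 100 | training run length |
| low-pass | 30 Hz, order 2 forward–backward | 24 dB/octave net roll-off, zero phase |
| rejection | ±80 μV window | `"range"` mode (max − min) available |
| sweep gate | > 30 per condition | strict inequality |

Weight initialization is Glorot-uniform with zero biases under the run
seed; the t-SNE embedding starts from $\mathcal N(0, 10^{-4})$ draws.

## Evaluation scheme

The harness reserves a fresh 20% test set in each of $k = 10$ rounds and
splits the remainder 9:1 into training and validation. Those numbers are
mutually inconsistent with *disjoint* k-fold partitioning (ten disjoint
folds cannot each hold 20%), so the default scheme is repeated random
sub-sampling (Monte-Carlo) validation; classical disjoint k-fold and
whole-subject holdout are first-class options. Rounding is deterministic:
`test = floor(0.2 n)`, `train = floor(0.9 * remaining)`, remainder to
validation (for n = 220: 44 / 158 / 18). Test draws are stratified by
label when labels are present. Summary accuracy is the mean over rounds
with the population (divide-by-k) standard deviation.

The feature stage is unsupervised, so the default embeds all trials
jointly (transductive) — no label information can leak. For strict
generalization measurement an inductive mode embeds only training rows
and places held-out rows by a Gaussian-kernel weighted average of
training embeddings (bandwidth defaulting to the median training-pair
distance); the interface enforces that held-out rows never enter the
embedding fit. SVM and BP baselines receive the channel-mean of the
per-channel embeddings as a per-trial 5-vector, keeping their input
five-dimensional; this discards channel structure, which is precisely
why the sequence classifier is expected to beat them.

## The synthetic generator

`generate_epochs()` emulates two-condition single-trial ERP data: every
trial is 1/f-shaped background noise (white spectrum shaped by
$1/\sqrt{f}$, DC zeroed; default 3 μV RMS), a 10 Hz oscillation with
random phase (1.5 μV), and broadband white noise (1 μV). Trials of the
"accept" class additionally carry a Gaussian-windowed late positivity
(default 8 μV peak, center 500 ms, FWHM 200 ms) scaled per channel by a
topography that places the effect on eight centro-parietal channels.
Ocular-like artifacts — slow ±120 μV frontal deflections — are injected
at rate 0.05, deliberately above the ±80 μV rejection window so the
generator and the rejection stage exercise each other.

What it does *not* emulate: volume-conducted dipole topographies,
inter-subject variability, latency jitter, realistic EOG morphology, or
the heavier noise floor of real single-trial EEG (a real 8 μV component
rides on substantially more background than these defaults). Passing
recovery tests on this generator therefore demonstrates that the
pipeline's machinery is correct and sensitive, not that any particular
accuracy will transfer to recorded data.

For the channel-subset experiment the effect is instead spread laterally
(C3/C4/P3/P4 at full weight, Cz/Pz/T7/T8 at 0.6) so that the 4-electrode
midline preset genuinely under-covers it; with the default midline-heavy
topography a 4-channel montage contains the strongest channels and the
montage comparison would not probe coverage at all.

## Numerical choices

- Bisection on $\log$ perplexity to tolerance $10^{-7}$, 200 steps max;
  degenerate rows (all-equal distances) fall back to uniform affinities
  rather than overflowing.
- $q$ entries are floored at $10^{-12}$ inside logarithms; the KL cost
  uses the convention $0 \log 0 = 0$.
- Forward–backward filtering pads with odd reflection (up to 300
  samples) so start-up transients decay below double precision before
  the retained segment; DC signals pass bit-near-exactly.
- The t-SNE inner loops (bandwidth bisection, Student-t weights,
  gradient + cost) are compiled (RcppArmadillo) with cache-conscious
  column-major passes; $\sum p \log p$ is cached across iterations.
- Ties in argmax predictions resolve to the first class; PCA and ICA
  fix signs deterministically (largest-magnitude loading positive), and
  ICA uses symmetric orthogonalization with a seeded orthogonal start.
- The printed BP architecture ends in a 1-unit output followed by
  softmax, which is degenerate (softmax of one logit is constant 1); the
  default realizes it as a 2-unit softmax head, with the literal 1-unit
  logistic variant behind `output = "sigmoid1"`.
- The ±80 μV criterion is read as a symmetric amplitude window (any
  sample outside ±80 μV rejects the trial, on any channel); the
  max−min reading is available as `mode = "range"`.

## Problem sizes used by the tests and the acceptance script

The statistical checks run at a reduced scale chosen by this package:
synthetic recovery uses 100 trials/class (80 for null controls) at 16
channels, 2 evaluation rounds per seed, 3 seeds (2 for the montage
comparison), and 250 t-SNE iterations. At this scale the full recovery
battery completes in minutes while the margin stays wide: mean test
accuracy ≈ 0.91 against the 0.85 recovery threshold the test suite
asserts, with chance-level nulls. Trial counts, noise levels and
thresholds are the conditions stated above — they are never adjusted
per run.

## Known limitations

- Exact electrode memberships of the 4/16/32/60 presets follow standard
  10-20/10-10 symmetric coverage and are user-overridable; they are a
  convention, not a reconstruction of any particular cap.
- t-SNE here is exact ($O(n^2)$); no Barnes–Hut or interpolation
  acceleration, and no parametric embedding network.
- The EDF reader handles plain EDF (uniform sampling rate across
  selected signals, int16 records); EDF+ annotations are not parsed —
  events come from a table.
- The CNN baseline has no pooling layer (none is specified for it), so
  its dense layer is large; scalogram images should be decimated in time
  (`time_downsample`) for realistic runtimes.
- Subject-level pooling is the caller's choice: the pipeline operates on
  whatever `epoch_set` it is given, and the plan object decides whether
  holdout is by trial or by whole subjects.
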