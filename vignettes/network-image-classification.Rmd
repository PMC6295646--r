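---
title: "Classifying functional brain networks as node-embedding images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying functional brain networks as node-embedding images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netimage)
```

## The problem

Functional brain networks — graphs whose nodes are sensors or regions and
whose edges quantify statistical coupling between their signals — are
non-Euclidean objects. A convolutional neural network (CNN) expects a
regular grid, so it cannot consume an adjacency matrix directly: the row
and column order of an adjacency matrix is arbitrary, while convolution
assumes spatial neighborhood structure. `netimage` implements one bridge
across that gap: embed the graph's nodes in a low-dimensional vector space,
align the embedding axes by variance, and summarize the node cloud as a
small multi-channel 2D histogram. The histogram *is* a regular grid, so an
ordinary small CNN can classify it. The intended use is two-class
discrimination of subject-level sensor networks (e.g. patients vs.
controls in magnetoencephalography montages of a few hundred channels),
with one network, hence one image, per subject.

## Stage 1 — phase-lag-index connectivity

Edges are the phase-lag index (PLI) between channel pairs:

$$\mathrm{PLI}_{ij} \;=\; \bigl|\,\langle\, \mathrm{sign}\,
\Delta\phi_{ij}(t_k) \,\rangle\,\bigr| \in [0, 1],$$

the absolute time-average of the sign of the wrapped instantaneous phase
difference. PLI is 1 when one channel consistently leads the other, and 0
when the lead/lag direction is inconsistent — including the zero-lag case,
which makes the index robust to volume conduction (a common source
projecting instantaneously into two sensors produces $\Delta\phi = 0$ and
contributes nothing).

Three conventions are fixed here because the index is undefined without
them:

* **Phase extraction** is the analytic-signal (Hilbert) phase of the —
  optionally band-passed — channel, the standard practice for PLI. The
  band-pass (`band_filter()`) is a zero-phase Butterworth (`filtfilt`), so
  filtering cannot itself introduce lags. No default band is imposed: the
  analyzed rhythm is a study-level choice, and the pipeline runs unfiltered
  if none is given.
* **Wrapping**: $\Delta\phi$ is mapped into $(-\pi, \pi]$ before the
  signum (via `atan2`), so a difference of $+3\pi/2$ counts as $-\pi/2$.
* **`sign(0) = 0`** (the mathematical signum): identical signals score
  PLI 0, matching the "no consistent lag" reading.

By default one PLI matrix is computed per recording (one network per
subject); `epoch_length` switches to per-epoch PLI matrices that are then
averaged. The node count is data-driven — nothing in the package assumes a
particular montage size — and the dense weighted graph is passed downstream
without thresholding: sparsification, where wanted, is an embedding-stage
option (`top_k`), not an edit of the network itself.

## Stage 2 — node embedding by random walks and skip-gram

`node2vec()` learns a matrix $\Phi \in \mathbb{R}^{|V| \times d}$
($d \ll |V|$) such that nodes with similar graph neighborhoods receive
nearby vectors. Walk "sentences" are generated first: in each of $I$
sweeps every node roots one walk of length $l$, and each step samples the
next node among the current node's positive-weight neighbors. On a dense
PLI graph a *uniform* neighbor choice would ignore all structure — every
node neighbors every other — so the default transition law is
weight-proportional, with `mode = "uniform"` and top-k sparsification
available as switches.

A skip-gram model is then trained on the walks: for every focus position
$j$, the nodes at positions $j - w \ldots j + w$ (window $w$, clipped at
walk ends) are positive contexts, and the model maximizes their softmax
co-occurrence probability. With one-hot node inputs this is exactly two
shared weight matrices — the $|V| \times d$ input matrix (read out as
$\Phi$) and a $d \times |V|$ output matrix. Since the vocabulary is only a
few hundred nodes, the exact softmax is cheap and is the default;
negative sampling (`negative > 0`) is provided for large graphs.
Optimization is stochastic gradient descent over shuffled focus–context
pairs with a linearly decaying learning rate; pairs are processed in small
batches whose gradients are *summed*, so each pair contributes the same
step it would take under per-pair updates.

Unstated-by-convention hyperparameters were fixed once at word2vec-style
values and are all configurable: $I = 10$ walks per node, $l = 40$,
$w = 5$, 5 epochs, initial learning rate 0.025, batch 256. The
embedding dimension defaults to $d = 20$; configurations with
$d \ge |V|$ are rejected.

## Stage 3 — the graph as an image

`graph_to_image()` turns $\Phi$ into an $r \times r \times d_{PCA}/2$
count image:

1. **PCA alignment** (`pca_features()`): project the $d$-dimensional node
   vectors onto their top $d_{PCA}$ principal components, ordering features
   by explained variance. Because eigenvectors are sign-ambiguous, each
   loading vector is flipped so its largest-magnitude entry is positive —
   without this, reruns could mirror the image axes.
2. **Pairing** (`feature_pair()`): features (1, 2) form channel 1,
   features (3, 4) channel 2, and so on.
3. **Binning** (`histogram_channel()`): each feature is divided into $r$
   equal-width bins spanning its per-graph min–max range (the maximum is
   closed into the top bin so no node is dropped); cell $(x, y)$ counts
   the nodes whose binned feature pair is $(x, y)$. The first feature of a
   pair indexes rows, the second columns.

Every node lands in exactly one cell, so each channel's pixel values sum
to $|V|$ — a mass-conservation invariant asserted throughout the tests. A
zero-range feature (all nodes identical on that axis) maps everything to
bin 1 with a warning. Defaults are $d_{PCA} = 4$ and $r = 10$: two
10 × 10 channels per subject. Bin edges are per-graph because the
transform is defined per graph; note this makes pixel positions relative
to each subject's own feature range, a deliberate trade-off that removes
scale differences between subjects.

## Stage 4 — the CNN classifier

The network is deliberately small, sized for 10 × 10 inputs and cohorts of
tens of subjects:

| layer | shape (10 × 10 × 2 input) |
|---|---|
| conv 3×3, 32 maps, ReLU, valid | 8 × 8 × 32 |
| conv 3×3, 128 maps, ReLU, valid | 6 × 6 × 128 |
| max-pool 2×2 | 3 × 3 × 128 |
| flatten | 1152 |
| FC 32, ReLU | 32 |
| FC 16, ReLU | 16 |
| FC 2, softmax | 2 |

Convolutions are unpadded ("valid"); the 1152-unit flatten is asserted at
build time. The model holds 74,848 weights (75,058 scalars counting
biases) — `count_parameters()` reports both, since published totals often
omit biases. Training minimizes categorical cross-entropy with Adam
(learning rate 0.001) plus an L2 penalty of 5 × 10⁻⁴ on all weight
matrices; dropout 0.25 is applied after both convolutions and the first
FC layer, during training only. Up to 1000 epochs are allowed, with early
stopping on validation loss (patience 50, min-delta 0) and best-weight
restoration. A `momentum = 0.1` field is recorded in the configuration for
provenance but unused: Adam has no plain momentum term. Training is
full-batch by default — deterministic and fast at these cohort sizes — and
raw histogram counts are fed to the network (`input_scaling = "per_node"`
optionally divides by $|V|$).

`cross_validate()` repeats, per iteration, a fresh random partition into
$k$ near-equal folds; each fold is held out once while a freshly
initialized model (new seed from the master stream, preventing leakage
across folds) trains on the rest. By default the held-out fold also drives
early stopping, which slightly optimistically couples stopping to the test
fold; `inner_val = TRUE` carves a stratified validation split out of the
training folds instead. The summary statistic is the plain mean of all
fold accuracies.

## The synthetic cohort generator

Because clinical recordings cannot ship with the package, every stage is
exercised on synthetic data whose discriminative signal flows through the
same path real data would use:

* `simulate_coupled_signals()` partitions channels into blocks; each block
  shares one sinusoidal oscillator (random phase per realization, 10 Hz
  default at 250 Hz sampling) and channel $i$ mixes it, shifted by a
  channel-specific lag, with independent Gaussian noise:
  $x_i = c\,\sin(2\pi f_b t + \theta_b + \ell_i) + (1 - c)\,\varepsilon_i$.
  Within-block lags are spread over $(0, \pi/2]$ so coupled pairs have
  consistently non-zero $\Delta\phi$. Each block's frequency is jittered
  uniformly (±1 Hz default) per realization: two *uncoupled* oscillators
  at one exact frequency would hold a constant phase offset and be
  indistinguishable from coupling by any phase metric, so distinct
  frequencies are what makes between-block relative phase drift and
  between-block PLI fall to chance level.
* `simulate_modular_graph()` plants block structure directly at the graph
  level (weights ≈ `w_in` within, `w_out` between, bounded jitter) for
  embedding-stage tests.
* `simulate_two_class_cohort()` draws balanced labeled cohorts; the default
  classes differ in community count (2 vs 4 blocks at coupling 0.9) —
  class structure lives in the phase geometry, never in amplitude, because
  PLI is amplitude-blind.

What passing on this generator shows — and what it does not: the synthetic
oscillators are narrowband, stationary, and noise is white and
channel-independent; real sensor data have 1/f spectra, artifacts,
nonstationarity, correlated noise, and far subtler class differences.
End-to-end accuracy on the generator therefore validates the *mechanics*
(each stage transmits planted structure to the next) and says nothing
about clinical effect sizes.

## Reproducibility and numerics

One master seed feeds named streams (`derive_seed(seed, "walks-s001")`,
…) so each stage, subject, and fold is independently reproducible; a
pipeline rerun under the same master seed reproduces all text artifacts
byte for byte, which the tests assert literally. All interchange formats
are self-describing tab-separated text with period decimals. Numeric
corner cases are pinned down explicitly: PLI wrapping and `sign(0)`,
histogram top-bin closure and zero-range features, PCA sign convention,
max-pool ties broken to the first window position, and near-equal fold
sizes when $N$ is not divisible by $k$.

Problem sizes used in the shipped tests were chosen to keep the suite
quick while still covering the full montage scale where shape contracts
matter: 273-node graphs verify image-mass and shape invariants, while
walk-law, separation, and end-to-end checks use 12–40 channel cohorts of
40 subjects — sizes at which every stage's statistical behavior is already
visible.

## Known limitations

* First-order walks only: there are no return/in-out bias parameters, by
  design.
* The exact-softmax skip-gram scales linearly in $|V|$ per pair; beyond a
  few thousand nodes, switch to `negative` sampling.
* The CNN engine is a compact pure-R implementation sized for small
  images and cohorts; it is not a general deep-learning framework.
* Per-graph PCA and binning mean image axes are subject-relative; a
  cohort-level variant (shared bin edges) is a natural extension point.
* Raw-recording preprocessing (artifact rejection, segmentation) is out of
  scope; inputs are assumed cleaned.
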