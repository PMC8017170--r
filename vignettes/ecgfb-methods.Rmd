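---
title: "Frame-blocking preprocessing and residual attention networks for multi-label ECG classification"
author: "ecgfb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frame-blocking preprocessing and residual attention networks for multi-label ECG classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgfb)
```

## The problem

Clinical 12-lead electrocardiograms come with two properties that
complicate automatic arrhythmia detection. First, records are
*multi-labeled*: one recording may show, say, atrial fibrillation together
with right bundle branch block, so classification cannot be a single
9-way choice. Second, records have *variable length* (6–60 s in the
public challenge corpora this package is modeled on, sampled at 500 Hz),
while convolutional networks want fixed-shape inputs. `ecgfb` implements a
complete pipeline around two ideas: a frame-blocking length unification
borrowed from speech processing, and one independent binary classifier
per abnormality (binary relevance), each a per-frame residual CNN whose
frame embeddings are read by an attention-pooled bidirectional LSTM.

## Frame blocking

A record of $S_l$ samples per lead is cut into $F_n$ frames of $F_l$
samples. Consecutive frames start $F_s$ samples apart, and the part two
neighbours share is the overlap $f_o$, with

$$F_l = F_s + f_o, \qquad F_s = \frac{S_l - F_l}{F_n - 1}.$$

The first frame is anchored at the record start and the last at the
record end, so the whole record contributes signal regardless of its
length; short records yield strongly overlapping frames rather than
zero padding. The defaults $F_l = 2000$ and $F_n = 10$ turn any 500 Hz
record into a $(10, 2000, \mathrm{leads})$ block; a 40-s record (20000
samples) is the clean special case where $F_s = F_l$ and the frames tile
the record contiguously with $f_o = 0$.

Numerical choices, all exposed in `frame_config()` / `frame_block()`:

* **Integer offsets.** $F_s$ is fractional for most $S_l$. Offsets are
  `round(i * F_s)` for $i = 0, \dots, F_n - 1$, which pins the first
  offset to 0 and the last frame end exactly to $S_l$ with at most half a
  sample of deviation from the ideal grid. Flooring instead would lose
  the record tail, defeating the point of the method.
* **Records shorter than one frame** ($S_l < F_l$, where $F_s$ would be
  negative) are right-padded with `pad_value` to $F_l$ and emit $F_n$
  identical frames. The corpora the defaults target have a 6-s minimum
  (3000 samples), so this regime is out-of-distribution, but it must not
  crash.
* **Records longer than $F_n \cdot F_l$** give $F_s > F_l$: frames then
  sample the record uniformly with gaps. The framing equation imposes no
  cap, so this is allowed as-is.

The conventional baseline, `pad_or_truncate()`, cuts every lead to the
first 20000 samples or zero-pads up to that length (40 s at 500 Hz).
`compare_preprocessing()` runs both arms on identical balanced splits.
With the default frame configuration, a padded-to-20000 record
frame-blocks into exactly the contiguous tiling, so the identical network
consumes both representations.

## Denoising

Diagnostic ECG content lies roughly between 0.1 and 35 Hz. Each lead is
filtered with an 8th-order Butterworth lowpass at 35 Hz
(`filter_spec()`), which suppresses 50/60 Hz powerline interference and
high-frequency muscle noise. By default the filter is applied
forward–backward (`zero_phase = TRUE`): ECG morphology (ST segments,
P-wave timing) is phase-sensitive, and zero-phase application avoids
distorting it at the price of squaring the magnitude response; the
causal option is retained. An optional 0.1 Hz highpass (default off)
additionally removes baseline wander that the lowpass leaves untouched.
Whether the original design applied its filter causally or zero-phase is
not something the package takes a position on — both are options, the
default is the morphology-preserving one.

## Balancing and splitting

Each abnormality becomes an independent binary task (`binarize()`): a
record is positive for a class iff the class is in its label set, so
multi-label records are positive for each of their classes. Because
class prevalences are heavily skewed, each task is balanced by random
under-sampling (`undersample()`) to a 2:1 majority:minority ratio —
every minority record is kept, `floor(2 * minority)` majority records
are drawn without replacement.

Partitioning (`split_task()`) uses 64/16/20 train/validation/test
fractions with largest-remainder rounding (total preserved, minimal
deviation from the ideal sizes). Two choices are deliberate defaults the
protocol source leaves open:

* **Stratification** (default on): with rare classes, an unstratified
  20% test draw can easily contain no positives at all, making F1
  undefined; stratified splitting keeps the 2:1 ratio in every partition
  to within one record.
* **Record-level splitting**: all frames of a record stay in one
  partition, since frames of one record are heavily correlated and
  frame-level splitting would leak test information into training.
* **Balance once, then fold**: `kfold()` (default $k = 5$) folds the
  already-balanced task rather than re-balancing per fold, so folds stay
  disjoint and reproducible.

## The classifier

Every class gets its own binary network (`model_config()`,
`build_model()`, `train_model()`):

1. **Per-frame trunk**, shared across frames: Conv1D (32 filters, kernel
   16, stride 2) → batch norm → ReLU → max-pool of 3 → residual block
   with identity shortcut (two Conv1D(32, 7) + BN, shortcut added before
   the second ReLU) → residual block with projection shortcut
   (Conv1D(64, 5, stride 2) path, Conv1D(1×1, stride 2) + BN on the
   shortcut to match channels and stride) → global average pooling to a
   64-vector per frame. Counting convolutions, batch norms and the max
   pool — the convention `layer_census()` documents — the trunk has 13
   layers.
2. **Sequence head**: the $F_n$ frame embeddings, in record order, feed
   a bidirectional LSTM (64 units per direction). Additive attention
   (`attention_pool()`) — a learned query scoring $\tanh(W h_t + b)$,
   softmax-normalized — pools the hidden states into a context vector,
   and a single sigmoid unit emits the class probability. Training
   minimizes binary cross-entropy.
3. **Decision rule**: probability ≥ threshold (default 0.5) is a
   positive call; ties go to positive. `multilabel_predict()` takes the
   union of per-class calls; the empty set is a legitimate prediction.

The concrete kernel sizes, filter counts, optimizer (Adam, learning rate
$10^{-3}$), batch size (8 records), and early-stopping patience (5) are
this package's own defaults, chosen as unremarkable values for 1-D
biosignal networks; all are configuration, not claims. The batch size
default keeps the peak memory of the im2col convolution caches modest on
a single-CPU machine — larger batches change speed and batch-norm
statistics, not semantics. Additive (rather than dot-product) attention
is the default because the scored sequence is short ($F_n = 10$) and a
learned query decouples the scoring dimension from the LSTM width.

The network is implemented in the package itself: batched im2col
convolutions multiplying against BLAS, hand-derived backward passes for
every layer (convolution, batch norm, max pool, global average pooling,
LSTM backpropagation through time, attention, sigmoid/cross-entropy),
and Adam. The test suite verifies every parameter group's analytic
gradient against central finite differences, which is the strongest
correctness check such an implementation admits.

Determinism: parameter initialization, shuffling and under-sampling all
flow from explicit seeds through named substreams; repeated runs with
the same configuration give bit-identical loss curves in a single-threaded
BLAS.

## Evaluation

Per class: precision $TP/(TP+FP)$, recall $TP/(TP+FN)$, F1 (their
harmonic mean). Degenerate 0/0 ratios are defined as 0 *and flagged* —
silently dropping rare-class results would bias macro averages upward.
Macro averages are unweighted means over classes (micro-averaged pooled
counts are also reported). The ROC curve sweeps the threshold over the
unique scores; the AUC is the trapezoidal area, which equals the
probability-of-correct-ranking statistic with ties counted half — the
test suite checks this equivalence exhaustively on small instances.

The two preprocessing arms are compared with a two-sided paired Wilcoxon
signed-rank test on per-class F1 scores. For $n \le 25$ non-zero pairs
the null distribution is computed exactly by dynamic programming over
the doubled mid-ranks, which stays exact under ties (the standard R
implementation falls back to a normal approximation there); above 25 a
normal approximation with tie and continuity correction is used.

## The synthetic generator

`generate_record()` / `generate_corpus()` exist so that the entire
pipeline is exercisable and testable without any external data. Each
beat is a template — Gaussian P wave, triangular QRS complex, Gaussian T
wave — repeated at RR intervals, modified per class: atrial fibrillation
draws RR intervals with high coefficient of variation and suppresses the
P wave; first-degree AV block lengthens the P-to-QRS delay; the bundle
branch blocks widen the QRS and flip its polarity in characteristic
leads; premature atrial/ventricular contractions intersperse early
narrow/wide beats; ST depression/elevation shifts the segment between
QRS end and T onset. Leads differ by a fixed gain/polarity vector, and
configurable noise (baseline wander at 0.3 Hz, 50 Hz powerline — the
mains frequency of the corpora the defaults mirror — and white noise) is
added on top. The default class mix is modeled on the class frequencies
of the 2018 public 12-lead challenge corpus, durations are uniform on
6–60 s, and about 7% of abnormal records receive a second compatible
label (pairs involving `Normal`, and the two bundle branch blocks
together, are excluded).

This is a stylized generator, not a biophysical simulator. Noiseless
class pairs are separable by their defining statistic (RR variation, QRS
width, ST offset) by construction — the test suite checks a ≥ 3-SD
margin — which makes the end-to-end training smoke test well-posed. What
passing those tests shows is that the pipeline, optimization and
evaluation machinery work; it says nothing about accuracy on real
clinical ECGs, whose within-class variability, artifacts and label noise
the generator does not emulate.

## Problem sizes in the shipped tests

The test suite and acceptance script run the full protocol at sizes a
single CPU handles comfortably: the architecture-level tests use a
reduced configuration (frames of 64 samples, 4–8 filters) where the
mathematics is identical, the training smoke test runs the full default
architecture on a 200-record two-class corpus for up to 8 epochs with
early stopping, and the preprocessing comparison uses a 60-record corpus
with a slimmed trunk. Headline clinical-corpus scores are out of scope:
they require the original multi-thousand-record datasets and GPU-scale
training of nine binary networks.

## Known limitations

* The synthetic classes are caricatures; effect sizes are larger and
  noise better behaved than in clinical data.
* Under-sampling discards majority-class information; cost-sensitive
  losses or oversampling are out of scope by design.
* Binary relevance ignores label correlations (it cannot learn, e.g.,
  that two labels rarely co-occur).
* The WFDB-style header dialect is minimal (`#Dx:` comment line); full
  WFDB parsing and other container formats are out of scope.
* Training is single-threaded CPU code: adequate for the shipped
  experiment sizes, not for corpus-scale studies.
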