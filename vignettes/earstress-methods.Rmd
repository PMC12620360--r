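---
title: "Methods: simulation, markers, and the cross-attention classifier"
author: "earstress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, markers, and the cross-attention classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope and model of the data

`earstress` implements an end-to-end pipeline for *subject-independent*
mental-stress detection from two-channel bilateral ear-EEG under a
rest-versus-rest design: 60-second eyes-open resting segments recorded after a
stressor are contrasted with segments recorded after relaxation. The package
covers five stages — a synthetic paired-condition EEG generator, the
preprocessing chain, seven canonical scalp-EEG stress markers with paired
nonparametric statistics, a convolutional cross-attention classifier trained
under eight-fold subject-level cross-validation, and explainability analyses
of the trained classifier. Because no public recordings accompany this
problem, the generator is a first-class, tested component: every downstream
stage is exercised on simulated data whose spectral structure encodes the
stress effects the marker analysis assumes.

# The synthetic generator

Each recording is synthesized in the frequency domain as a sum of components
with exact spectral control:

* a 1/f^a background (default exponent a = 1) on every channel, built from
  complex white noise with amplitude proportional to f^(-a/2);
* band-limited oscillators — theta (4–7 Hz) strongest at Fpz, alpha
  (8–13 Hz) at AF7/AF8, beta (14–30 Hz) at Cz — realized as white noise
  filtered by a unit-gain band mask with 0.5 Hz raised-cosine edges, so Welch
  estimates of the simulated bands have realistic variance (oscillators are
  *not* pure sines);
* one shared high-beta (23–36 Hz) source mixed into AF7–C3, AF8–C4 and
  Fpz–Cz together with channel-private high-beta noise, which makes
  band-averaged magnitude-squared coherence controllable through the shared
  source's weight;
* two temporal sources (alpha + beta energy) feeding the ear channels; each
  ear receives its own source plus a lagged copy of the opposite source
  (default lag 8 ms), realized as a frequency-domain phase ramp.

Every component is normalized to unit RMS via Parseval's identity and scaled
in microvolts (background ~2 uV RMS, oscillators 1–4 uV), an arbitrary but
documented convention. Components draw from independent RNG substreams keyed
by (root seed, subject, condition, component name), so adding a channel or an
effect never perturbs existing draws, and a fixed seed reproduces a dataset
bit-for-bit.

Condition effects are applied *only* as amplitude/mixing multipliers, never
in the seed path: the stress member of a pair differs from the relax member
by the injected effects plus an independent noise realization. The default
effect sizes encode the directions the marker analysis reports — frontal
midline theta power gain 2.0, alpha gain 0.7 (suppression), Cz beta gain 1.5,
shared high-beta power gain 1.6, an additive frontal-alpha-asymmetry shift of
-0.15 (toward symmetry under stress), and a 2 ms lag increase — at moderate
magnitudes chosen once to give subject-level effect sizes in the range the
seven-marker analysis is designed to detect. The ear channels inherit the
alpha/beta gains and the lag shift; no published quantitative ear-channel
effect exists, so this is an explicit modeling assumption exposed as
configuration (`effectSizes()`), with a `strongEffectSizes()` preset (theta
x6, alpha x0.25, beta x4, coherence x4) used for learnability and power
studies. Between-subject variability is log-normal per subject and band
(`subjectSd = 0.4`) and *shared across conditions*, deliberately making
subject identity a confound that only subject-level cross-validation handles
correctly.

What the generator does **not** emulate: ocular/muscular artifacts, electrode
impedance drift, non-stationarity within a segment, volume-conduction
topography, or any task timeline. Passing tests on simulated data therefore
demonstrate that the pipeline's statistics and learning machinery behave as
specified under a known ground truth — not that the classifier would reach
any particular accuracy on real recordings.

# Preprocessing

The chain mirrors standard practice for this montage: a sixth-order
Butterworth band-pass (1–40 Hz) and a 60 Hz notch at the raw 500 Hz rate,
then down-sampling to 125 Hz and extraction of one 7500-sample epoch per
1-minute rest block. Choices the package had to pin down:

* **Phase handling.** Filters are applied forward–backward (`filtfilt`), so
  the effective magnitude response is squared and no group delay shifts epoch
  alignment; a causal single-pass mode is available (`zeroPhase = FALSE`).
* **Notch design.** A constrained second-order IIR notch with quality factor
  30 (3 dB bandwidth 2 Hz); the band-pass already attenuates 60 Hz strongly,
  the notch adds a deep null at the line frequency.
* **Down-sampling.** Every 4th sample after filtering; the 40 Hz low-pass
  already prevents aliasing at the 62.5 Hz target Nyquist, so no second
  anti-alias filter is applied. Only integer decimation factors are
  supported.
* **Epoching.** The first 60 s of each block, half-open 0-based sample
  windows; consecutive-window multi-epoch slicing exists as a
  data-augmentation option but is off by default — whole 60-s epochs are
  the unit of classification.
* **File formats.** Recordings interchange as delimited numeric text
  (metadata header, labeled columns) plus a TSV manifest. This is the one
  supported on-disk format; it round-trips losslessly at the precision
  written.

# Markers and statistics

The seven markers are computed from the six scalp channels of each epoch:
frontal alpha asymmetry ln a(AF8) − ln a(AF7); alpha power at AF7 and AF8;
beta power at Cz; the theta/beta ratio at Cz; mean magnitude-squared
coherence at 23–36 Hz over AF7–C3, AF8–C4 and Fpz–Cz; and frontal-midline
theta power at Fpz. Spectral estimation uses Welch's method with 2-s Hamming
segments at 50% overlap (0.5 Hz resolution, ~59 averages per 60-s epoch;
segment means removed), band powers as trapezoidal integrals of the one-sided
PSD over closed bands, and coherence band-averaged arithmetically over bins
whose center lies in [23, 36] Hz. The overlapping beta (14–30 Hz) and
high-beta (23–36 Hz) definitions are kept as printed in the marker table.
No installed R package provides Welch averaging with overlap, so the
estimator is implemented here and validated against analytic oracles
(sinusoid variance A^2/2, flat-PSD bandwidth ratios, unit self-coherence).

Paired condition differences use the two-sided Wilcoxon signed-rank test with
zero differences dropped; the exact distribution (base `psignrank`) for at
most 25 tie-free nonzero pairs, otherwise a tie-corrected,
continuity-corrected normal approximation. The reported effect size is
Rosenthal's r = |z|/sqrt(n) with n the original pair count. FDR control
across the seven tests is Benjamini–Hochberg: q-values via
`p.adjust(method = "BH")` and the step-up rejection set (largest k with
p(k) <= kQ/m). q-values are rounded to four decimals in written reports only,
never internally.

# The classifier

The model ingests the raw two-channel 125 Hz epoch — shape (batch, 2, 7500)
— with no hand-crafted features. Each channel stream passes through four
temporal blocks (1-D convolution → batch normalization → ELU; average
pooling after blocks 1–3), a coarse-to-fine design with kernel lengths
decreasing 125 → 63 → 31 → 20 samples. With non-overlapping pools of 5, 6
and 7 the 7500 input samples reduce to exactly 35 token positions
(7500 → 1500 → 250 → 35, floor division). Block 4 keeps 32 feature maps
which a learned 1x1 pointwise convolution compresses to a single feature
map: a sequence of 35 scalar tokens per stream.

Since the exact layer hyperparameters of the original design are not
published, the filter counts (8, 16, 16, 32), pooling sizes, attention
dimensions and classifier width used here were pinned once to satisfy the
stated constraints — kernels from 125 to 20 samples, 35 tokens per stream,
and a total parameter budget near 0.07 M (this configuration has 59 848
trainable parameters). The two streams use separate (unshared) encoders;
`shareStreams = TRUE` is available.

Cross-attention is computed bidirectionally with scaled dot-product
attention softmax(QK'/sqrt(dk))V: once with the left stream's tokens lifted
to queries (dk = 8) against right-stream keys/values (dv = 1), once with the
roles reversed. "Two heads" is realized as the two directions, one head
each. Each direction yields a 35-vector of attended values; their
concatenation (70 features) feeds the shallow classifier: dense(70→64) →
batch norm → ELU → dropout 0.5 → dense(64→2), stress = class index 1.

Ablation variants share the encoder and classifier machinery:
`no_cross_attention` concatenates the compressed token streams directly;
`no_pointwise` replaces the learned compression with a parameter-free mean
over feature maps at each time bin (keeping 35 tokens — the wiring is
otherwise undefined for this removal, so the simplest order-preserving
compression was chosen); `no_both` combines the removals; `self_attention`
lifts each stream's tokens to 64 dimensions and applies shared single-head
within-stream self-attention followed by temporal averaging; and
`lightweight_transformer` concatenates both token streams, adds learned
positional and channel embeddings, and applies one two-head transformer
encoder layer (64-d, 128-d feed-forward, layer norm) before temporal
averaging. The proposed cross-attention model has fewer parameters than the
transformer baseline by construction, and that ordering is asserted in the
tests rather than exact counts.

All layers, the backward passes, and AdamW are implemented in the package
(R orchestration over compiled im2col/GEMM convolution kernels), since no
deep-learning framework is available in the target R stack; correctness is
established by numeric-gradient checks of every primitive and of the
assembled variants, and by brute-force oracles for the attention algebra.
AdamW uses beta = (0.9, 0.999), eps = 1e-8, constant learning rate 1e-3,
and decoupled weight decay 0.01 applied to weight matrices only (norm scales
and biases excluded — the usual convention; the decay value itself is a
package choice, as none is published). Batch normalization uses momentum
0.1 and eps 1e-5; evaluation mode uses running statistics, which makes
inference deterministic and batch-size invariant.

# Training protocol

Eight-fold subject-level cross-validation: subjects are shuffled once with
the root seed and partitioned contiguously into eight disjoint test groups
(4 of 32 subjects each); the remaining 28 subjects split 6:1 *by subject*
into 24 training and 4 validation subjects. The subject-level reading of the
6:1 split keeps early stopping subject-independent; an epoch-level split
would leak validation subjects into the stopping decision. Batches of 16
(training) and 8 (validation), the test set in one full pass; up to 200
epochs with early stopping after 30 consecutive epochs without a strictly
lower validation loss, best-validation parameters restored. Metrics are
accuracy and macro F1 (unweighted mean of per-class harmonic means),
averaged across folds. Fold-wise model comparisons reuse the signed-rank +
Benjamini–Hochberg machinery.

Problem sizes in the test suite are scaled to what the statistics need
rather than to the full protocol: the simulation-based checks run the full
32-subject, 8-fold protocol with `maxEpochs = 15, patience = 5` for the
headline accuracy criterion and the ablation comparison (convergence on
strong-effect synthetic data occurs within roughly ten epochs); marker power
and false-positive calibration use 10-subject replicates of 20-second
recordings, since type-I error is duration-free and the dosed effects are
large. These sizes are the package's own choices and
are asserted in `tests/testthat/test-acceptance.R`.

# Explainability

During evaluation the two directional attention maps (35 x 35,
row-stochastic; rows = query time bins) are recorded per sample. Two
summaries are computed: **row-wise entropy** — each row renormalized and its
Shannon entropy taken in nats (0 log 0 = 0), averaged over rows; the printed
formula is plain entropy, so "normalized" is read as the row renormalization,
with an optional H/ln 35 variant in [0, 1] exposed separately — and
**directional asymmetry** ||A − A'||_F / ||A||_F, zero for symmetric maps
and at most 2. **Temporal occlusion** slides a zero-baseline window (0.5 s →
62 samples, step 0.1 s → 12 samples at 125 Hz; seconds converted by floor)
over both channels jointly and records the class-logit change
logit_c(x) − logit_c(x_occ); windows overlapping the epoch end are dropped
and times are reported at window centers. Per-fold deltas aggregate as: mean
over samples within label, stress minus relax, then mean across folds, with
positive/negative fold counts reported. Occlusion-at-the-baseline is exact:
an all-zero epoch yields identically zero deltas, and a linear surrogate
model reproduces the closed-form window sums, both asserted in tests.

# Numerical and degenerate-input policy

Typed conditions (`earstress_*` classes) mark every contract violation:
unknown conditions or variants, non-positive gains, too-short recordings,
missing channels, bands outside (0, fs/2), all-zero paired differences,
p-values outside [0, 1], all-zero attention maps, zero-row maps, empty
train/validation/test sets, and architecture configurations that do not
yield 35 tokens. Welch band edges are closed; ties in the signed-rank
statistic switch the test to the corrected normal approximation; the exact
two-sided p is capped at 1. Cross-entropy clamps probabilities at 1e-300
before the log. All randomness flows from explicit seeds through keyed
substreams (`subSeed`), and training seeds shuffling, dropout and
initialization from the training configuration, so reruns on one platform
are bit-identical.

# Known limitations

The generator's stationary, artifact-free signals are easier than real
ear-EEG; accuracies on simulated data say nothing quantitative about the
real recordings. The ear-channel condition effect is an assumption. EDF
input is not supported (text interchange only). Exact reproduction of the
original study's cohort-dependent numbers (marker p/z/r values, real-data
accuracies, exact parameter/FLOP counts) is out of scope by design; the
package asserts structural identities, analytic oracles, and
simulation-calibrated statistical behaviour instead.
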