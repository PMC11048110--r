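---
title: "Zero-calibration prototype decoding of single-trial RSVP ERPs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Zero-calibration prototype decoding of single-trial RSVP ERPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In a rapid serial visual presentation (RSVP) experiment, images flash at
around 10 Hz while EEG is recorded; rare target images (roughly 1 in 25)
evoke a P300-like event-related potential (ERP) — a positive deflection over
centro-parietal channels some 300–500 ms after the stimulus. Decoding
single trials into target/nontarget is the computational core of RSVP
brain–computer interfaces. The hard part is *cross-subject transfer*: ERP
amplitude, latency and scalp topography differ enough between people that a
classifier trained on one group degrades on a new user, and collecting
labeled calibration data from every new user is exactly what applications
want to avoid. "Zero calibration" means the decoder must classify a new
subject's trials using no data from that subject at all.

`protoerp` implements a prototype-matching network for this setting,
trained episodically so that generalizing to an unseen subject *is* the
training task, together with a synthetic multi-subject ERP simulator so the
whole pipeline can be exercised and tested offline.

## The model

**Encoder.** Each epoch (a channels-by-samples matrix) is mapped to a
1024-dimensional feature vector `f(x)` by a two-block convolutional network
in the EEGNet lineage. Block 1 applies three parallel temporal convolutions
(default kernel durations 0.256, 0.128 and 0.064 s, eight filters each),
recalibrates the concatenated maps with a squeeze-and-excitation (SE)
block, and mixes channels with a depthwise spatial convolution (depth
multiplier 2). Block 2 applies a depthwise temporal convolution with an
efficient-channel-attention (ECA) gate in place of a pointwise convolution.
Each block ends with batch norm, ELU, average pooling and dropout; a single
linear head maps the flattened maps to 1024 features, followed by batch
norm without activation, so features arrive approximately standardized.
The final feature dimension is fixed at 1024. The `"plain"` encoder
variant, used by ablation pattern A, disables the SE and ECA gates and
keeps everything else.

**Prototypes.** During an episode, one training subject acts as the *query*
and the remaining `m − 1` subjects are the *support*. For each support
subject `i` and class `k ∈ {0 = nontarget, 1 = target}`, the class-mean
feature `f̄_ik` is computed. The class prototype is a weighted mean across
support subjects,

```
p_k = Σ_i α_i f̄_ik,
```

and with uniform weights `α_i = 1/(m−1)` this is the plain prototype (the
across-subject mean of class means) — the reduction the tests pin down.

**Subject-level attention** produces the weights `α`: each support subject
is scored against the query feature `q` by
`e_i = Σ_j tanh( (G u_i)_j · (G q)_j )`, where `G` is a learned
1024 × 1024 linear map and `u_i` is the subject's representative feature,
and `α = softmax(e)`. Two choices here were genuinely open. First, the
score is computed once per subject, but a subject has two class means; we
use their average `u_i = (f̄_i0 + f̄_i1)/2`, which is class-balanced and so
robust to the 1:24 imbalance (a pooled trial mean would be dominated by
nontargets). Second, `α` is recomputed per query trial, not per batch, so
each test trial picks its own most-similar support subjects.

**Feature-level attention** produces a per-dimension score vector `z_k` for
each class from the across-subject average class-mean feature: a small 1-d
convolution (9 taps) over the 1024-vector, ReLU, then a softmax over the
1024 dimensions scaled by 1024. The scaling fixes `mean(z_k) = 1`, which
gives the package its cleanest invariant: zeroed attention weights — or
disabling the module — yield `z = 1` everywhere and the distance

```
d(q, p_k) = Σ_j z_k[j] (q_j − p_kj)²
```

degenerates exactly to squared Euclidean distance.

**Probabilities and losses.** Class probabilities use the
negative-distance softmax `P(y = k) ∝ exp(−d_k)`, so the *nearer* prototype
gets the larger probability; the classification loss is mean binary
cross-entropy (probabilities clipped at 1e−12), and the metric loss is the
mean of (distance to own-class prototype) − (distance to other-class
prototype). The total objective is `L_class + λ · L_metric` with `λ = 1` by
default: a weighted sum keeps the objective monotone in both terms, and λ
is exposed in `train_config()`. Classification itself is nearest-prototype
with ties broken toward nontarget.

**Training.** One epoch consists of one episode per training subject, each
subject serving as the query exactly once, in shuffled order. Adam
(learning rate 1e−4, first-moment decay 0.9) with cosine annealing of the
learning rate to 1e−6 over the whole run. The default is 30 epochs with no
early stopping: at the package's cohort sizes a run is a few hundred
episodes and a rotating-validation stopping rule would cost more than it
saves; `epochs` is configurable. Per episode, each support subject
contributes a class-balanced sample of at most `support_cap = 24` trials
(all available targets up to 12, matched nontargets): prototypes are class
means, so a balanced two-dozen-trial sample estimates them with modest
extra variance at a fraction of the encoding cost. At evaluation time
prototypes use every trial of every training subject.

**Batch-norm frames and leakage.** Support and query batches are encoded
separately, so episode prototypes are bit-for-bit independent of query
data (the test suite asserts this by zeroing the query subject's
recordings). The query batch is normalized using the *support batch's*
batch-norm statistics rather than its own: a 12-trial query batch's own
statistics are so noisy that distances would be dominated by frame
mismatch, and reusing the support frame keeps both feature sets in one
space without moving any query information into the prototypes. Those
statistics are treated as constants in the query half of the backward
pass. At evaluation time both sides use the encoder's running statistics.

**Zero-calibration hygiene** is enforced structurally: `fit()` only ever
receives training subjects; `zero_calibration_eval()` refuses a test
subject whose id occurs in the training set; channel standardization is
fitted on training subjects only and applied unchanged to the held-out
subject.

## The synthetic cohort generator

`make_cohort()` emulates the statistical structure the method assumes:

* rare targets — `round(trials · target_ratio)` target trials per subject
  (default ratio 1/25), placed uniformly at random;
* a P300-like component — a Gaussian bump
  `A_s · exp(−(t − L)² / (2 · 0.08²))` added to target trials only, with
  per-subject amplitude `A_s ~ N(A, sd_A)`, per-subject latency
  `L_s ~ N(0.35 s, 0.03 s)` plus 0.02 s per-trial jitter;
* subject-specific topography — a fixed unit-norm raised-cosine loading
  peaking at a "Pz-like" channel (index `round(n_channels · 5/8)`,
  half-width `n_channels/4`), perturbed per subject (sd 0.1) and
  re-normalized;
* colored background noise — an AR(1) process per channel (coefficient
  0.95) driven by white noise of sd `noise_sd`, started from its
  stationary distribution. The stationary background RMS is therefore
  `noise_sd / sqrt(1 − 0.95²) ≈ 3.2 · noise_sd`.

Default amplitudes are 5 µV against a 5 µV driving noise — an
amplitude-to-noise ratio of 1, the condition used throughout the package's
synthetic experiments (`study_config(ratio = ...)` scales the amplitude,
keeping the between-subject amplitude sd at 20% of the mean; `ratio = 0`
gives the noise-only null cohort). Reproducibility is per subject: subject
`i` is generated from the derived stream `seed + i` with the RNG state
restored afterwards, so a subject's data never depends on cohort size.

The generator deliberately omits blinks/EMG artifacts, overlapping
responses of consecutive 10 Hz stimuli, multiple ERP components and
measured noise spectra. Passing tests on these cohorts therefore
demonstrate that the pipeline is correct and that cross-subject transfer
of a planted, jittered, subject-varying component works — not that the
model is robust to real-world artifacts.

### What the conditions imply about attainable accuracy

A point worth stating openly, because it frames every synthetic result:
with the 0.08 s Gaussian bump and AR(1)(0.95) channel noise, the *exact
ideal observer* — whiten each channel with the AR(1) filter, match the
bump, pool channels — achieves

```
d' = 0.36 · (A / noise_sd),
```

so at the package's standard amplitude-to-noise ratio of 1 the best
possible balanced accuracy of *any* single-trial classifier on these
cohorts is about `Φ(d'/2) ≈ 0.57`, and at ratio 0.25 about 0.52. The AR(1)
noise concentrates below ~2 Hz exactly where the slow bump carries most of
its energy, and its stationary variance is ten times the driving variance;
both effects make this simulator's single-trial problem *much* harder than
the same ratio against white noise. Reported balanced accuracies on these
cohorts must be read against that ceiling, not against the 80–90% figures
achievable on real multi-component ERPs with dozens of channels. The
noise-only cohort (`ratio = 0`) provides the corresponding null check:
every correct pipeline must sit at BA ≈ 0.5 there.

## Preprocessing

The standard pipeline (`preproc_config()`, applied by `prepare_cohort()`):
optional window slicing (half-open `[start, end)`, sample index
`floor(t · sfreq)`), then a 2–30 Hz Butterworth bandpass of design order 4
applied forward-backward (zero phase, so the ERP peak is not shifted;
odd-reflection padding of three filter lengths suppresses edge
transients), then integer decimation — the experiment default resamples
250 Hz epochs to 62.5 Hz, which is safe because the band is limited to
30 Hz, below the new 31.25 Hz Nyquist — and finally per-channel z-scoring
with statistics from training subjects only. Filtering is per epoch; with
the reflection padding the residual edge effects are at the 1e−3 level of
the passband amplitude, which the filter tests measure and tolerate. At
62.5 Hz the pooled epoch is 15 samples long when block 2 is reached, so
the experiment default sets the block-2 kernel to 8 samples (~128 ms); the
16-sample default applies at higher rates.

## Numerical choices

* Batch norm uses ε = 1e−5 and running-statistics momentum 0.1; biased
  variances throughout.
* Probabilities are computed with max-subtraction before exponentiation
  and clipped at 1e−12 before logs. With 1024-dimensional features raw
  squared distances are large, so probabilities saturate early in
  training; gradients then reduce to their sign, which is why the loss
  curves are noisy at small episode counts.
* Weight initialization is He-style scaled Gaussian; the two attention
  nets start near zero so the model begins as (and can always fall back
  to) a plain prototype network with Euclidean distance — pattern B.
* All gradients, including the batch-statistics terms of batch norm and
  both attention gates, are analytic and verified against central finite
  differences in the test suite.
* Distance ties classify as nontarget; rank-based (Mann–Whitney) AUC with
  ties counted 1/2; Wilcoxon signed-rank drops zero differences and uses
  the exact distribution where available.
* Subnormal floating-point results are flushed to zero inside the encoder
  (they occur in saturated activations and are far below meaningful
  scale).

## Problem sizes

The package's canonical study (`study_config()`) is a 10-subject cohort of
500 trials each, 16 channels, 1 s epochs: training is 30 epochs × 9
episodes on nine subjects (~a minute on one CPU core), evaluation decodes
all 500 trials of the held-out subject. The unit tests run the same
architecture at 8 channels/64 samples; the acceptance suite runs the
full-scale study across three seeds, three amplitude-to-noise ratios
(0.25, 0.5, 1) and the A/E ablation contrast, sharing cohorts and trained
models between checks.

## Known limitations

* On the synthetic cohorts at realistic ratios the trained network
  operates close to chance because the ideal-observer ceiling is itself
  low (see above); differences between ablation patterns are accordingly
  within sampling noise there. The architecture's benefits are expected
  to express on real, higher-d′ recordings.
* A held-out subject's balanced accuracy rests on ~20 target trials, so a
  single evaluation carries a standard error of roughly 0.05; multi-seed
  averages are reported wherever a claim depends on it.
* The container format is R-native serialization; it round-trips exactly
  within R but is not a cross-language interchange format.
* Training is single-threaded CPU; no GPU backend.
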