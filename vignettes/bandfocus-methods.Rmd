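---
title: "Decoding motor imagery of a supernumerary thumb: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding motor imagery of a supernumerary thumb: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

When a person imagines moving an artificial extra digit — a supernumerary
thumb — does the brain produce a signature distinguishable, in single-trial
EEG, from imagining the movement of the natural thumb? Answering this
matters for brain-computer interfaces that aim to control augmentation
devices concurrently with the natural body: if the two imageries were
indistinguishable, concurrent control would be impossible in principle.

`bandfocus` implements a complete pipeline for this question: a compact
band-branched convolutional classifier with squeeze-and-excitation channel
attention, a leave-one-subject-out (LOSO) evaluation harness, Shapley-value
scalp-topography explainability, event-related spectral perturbation (ERSP)
analysis with paired bootstrap statistics, and — because the motivating
study's raw EEG is not publicly deposited — a synthetic multi-subject
motor-imagery EEG simulator with planted, ground-truth spectral effects, so
that every stage of the pipeline is testable end to end.

## The classifier

The network processes three fixed spectral views of each trial — delta
(1–4 Hz), theta (4–8 Hz) and alpha (9–13 Hz) band-passed copies — through
one branch per band:

1. **Temporal convolution**: 8 kernels of 0.5 s applied per electrode
   (same padding).
2. **Electrode aggregation**: a depthwise spatial filter spanning all 64
   electrodes (2 spatial filters per temporal kernel), collapsing the
   electrode axis into 16 virtual channels per band — the EEGNet-style
   spatial filter.
3. **Exponential-linear nonlinearity**, average pooling (width 32) and
   dropout (p = 0.25).

The 48 band-tagged feature maps are then gated by a squeeze-and-excitation
block (squeeze: per-map temporal mean; excitation: 48 → 12 → 48 bottleneck
with a terminal logistic, giving one gate in (0, 1) per map), so the model
can re-weight whole bands per trial. Layer normalisation over the flattened
feature axis — rather than batch normalisation — follows the gate; trial-wise
normalisation is the natural choice when train and test subjects differ,
which is exactly the LOSO regime. An affine softmax layer closes the model.

Two implementation notes:

* **Linearity reordering.** The temporal and spatial stages are both linear
  and the temporal kernels use same padding, so the implementation applies
  the spatial projection first (64 → 16 virtual channels) and convolves the
  virtual channels. This is mathematically identical to convolving each
  electrode and then aggregating, and roughly eight times cheaper. The
  equivalence is locked down by finite-difference gradient tests.
* **Decimation.** Branch inputs are band-limited below 13 Hz, so after
  zero-phase band-pass filtering the input is decimated towards a 32 Hz
  effective rate (factor 4 at the default 128 Hz sampling) with no
  information loss for the modelled bands. The factor is part of the model
  configuration and decimation refuses to alias configured band edges.

Training is Adam (learning rate 1e-3, batch 64) on the cross-entropy, with
early stopping on a validation split of 20% of the training trials
stratified by subject and label (patience 4, at most 15 epochs). The epoch
budget is deliberately short: on cohorts of the standard validation size
the validation loss plateaus around epoch 10–12 and held-out accuracy is
indistinguishable from runs several times longer, so the budget buys
single-CPU throughput without costing accuracy for a network of this size
(~5,500 parameters, comfortably inside the lightweight < 60,000 contract).
The forward, backward pass and optimiser are
implemented in base R with BLAS matrix products and FFT convolutions, and
their gradients are verified against central finite differences at 1e-5
relative tolerance.

## Preprocessing

Band decomposition uses Hamming-window FIR filters with transition width
`max(1 Hz, 0.25 × bandwidth)`, applied forward-backward so the net phase is
exactly zero — ERS/ERD latencies are preserved, which matters for the ERSP
cross-validation. The forward-backward pass is computed as one FFT product
with |H(f)|²; since that multiplier is real and even, two real traces are
packed into one complex FFT (exactly, not approximately). Reflection
padding by the filter length suppresses edge transients, and the FFT length
keeps the circular wrap-around of the zero-phase kernel inside the padding.
The implementation is verified against direct double convolution to
machine precision and against `signal::filtfilt` as an external oracle.

Standardisation is per (band, channel), with mean and variance pooled over
*training* trials only; the same affine transform is applied to validation
and test trials. Inside the LOSO harness the statistics therefore never see
the held-out subject — a property asserted by mutating test-subject data
and checking that trained weights are bit-identical.

## The synthetic cohort

Each simulated trial is per-channel 1/f Gaussian background noise
(spectral exponent 1, low-frequency floor at 0.5 Hz) plus band-limited
oscillatory sources projected onto channel subsets: frontal delta and theta
sources confined to the ten frontal ROI channels (right: AF8, F6, F8, FC6,
C6; left: AF7, F5, F7, FC5, C5), and a broad alpha source over the
central/centro-parietal row. Condition effects are multiplicative amplitude
modulations of the source envelopes inside the MI window with 250 ms
raised-cosine ramps:

* natural-thumb trials (label 0): delta/theta power increase (default
  +3 dB) on the frontal ROI channels — event-related synchronisation;
* supernumerary-thumb trials (label 1): alpha power decrease (default
  −3 dB) over the broad central set — event-related desynchronisation.

Source amplitudes are set so that in-band source power dominates in-band
noise power by roughly 10:1 at the target channels, which lets an
independent periodogram-ratio oracle recover the planted dB values within
±1 dB at 200 trials (the residual bias from the noise floor is a few tenths
of a dB and is part of that budget). Between-subject variability multiplies
the planted dB values by a lognormal factor (sd 0.2 by default), drawn once
per subject from a stream derived from the master seed, so LOSO
generalisation is tested across genuinely heterogeneous subjects while the
whole cohort stays bit-reproducible.

Geometry defaults: 64-channel 10-10 montage, 128 Hz sampling, epochs from
−1 s (baseline start) to +4 s with the imagery cue at 0. 128 Hz is a
standard rate for compact EEG decoders and all modelled bands sit far below
its Nyquist; the cohort sizes used throughout the tests (16 subjects by
default; 8 subjects × 240 trials for the end-to-end decoding checks) are
the package's chosen study conditions.

What the simulator does **not** emulate: volume-conducted leadfields (the
spatial mixing is a direct projection, not a head model), ocular/muscular
artifacts, non-stationary drifts, electrode impedance differences, or any
task-irrelevant cognitive structure. Passing tests on synthetic cohorts
therefore demonstrate that the pipeline recovers the specific spectral
effect structure it plants — frontal low-frequency synchronisation versus
broad alpha desynchronisation — not that the classifier would reach any
particular accuracy on real recordings.

## Leave-one-subject-out evaluation

Each subject serves once as the entire test set; the model, including its
standardisation statistics, is fitted on the remaining subjects with early
stopping on a validation split drawn only from those training subjects.
Accuracy is the percentage of correctly argmax-classified test trials (ties
resolve to class 0), aggregated as mean ± sample standard deviation (n−1).
Every fold derives its seed from the master training seed and the held-out
subject's id, so per-fold results are independently reproducible.

On a zero-effect cohort the two condition distributions are identical, so
LOSO accuracy must sit at chance; on the planted ±3 dB cohort the model
must separate conditions well above the binomial null band. Both properties
are asserted in the acceptance tests at the 8-subject × 240-trial scale.

## Shapley explainability

Attributions are computed over channel × time-window super-features: a
feature absent from a coalition is replaced by the per-sample mean of a
class-balanced background set (32 trials by default), and the value of a
coalition is the model probability of the trial's predicted class. Exact
enumeration is available up to 20 super-features and is verified against an
independent all-orderings oracle; larger problems use permutation sampling
with antithetic pairs (each sampled order followed by its reverse), which
cancels the leading Monte-Carlo error term and keeps the efficiency axiom
exact because each permutation's marginal contributions telescope.

Aggregation follows the "absolute scaled" convention: absolute values,
mean across trials, then min-max scaling to [0, 1] across channels within
each time window (a zero-range window maps to the neutral 0.5). Scaling
per window rather than globally was an open choice; per-window scaling is
adopted because it makes each topographic frame self-normalising.
Topographies are rendered by inverse-distance-weighted interpolation on the
unit-disc head model, and data-driven ROI extraction ranks channels by
time-averaged scaled attribution, splitting the top k by hemisphere (sign
of the lateral coordinate, ties broken by montage order).

## ERSP and statistics

The time-frequency transform is a complex Morlet filter bank (frequencies
1–30 Hz in 1 Hz steps, cycles `max(3, f/2)`), applied via FFT with
reflection padding. Power is averaged over trials and the channel set, and
expressed as `10·log10(P(f,t) / baseline(f))` with a divisive baseline from
the trial-averaged pre-cue window. Cells closer than three wavelet standard
deviations to an epoch edge are flagged invalid and excluded from band/
window averages; at 1 Hz the baseline itself sits inside the wavelet
support, an intrinsic ERSP limitation at very low frequencies that the
reflection padding mitigates but cannot remove, and one reason the
delta/theta summaries average over 1–8 Hz rather than relying on the 1 Hz
row alone.

The headline condition contrast — delta/theta (1–8 Hz) ROI power during the
MI window, natural vs supernumerary — is tested with a subject-level paired
bootstrap: differences are resampled with replacement (2,000 draws), the
two-sided p value is twice the smaller tail fraction, floored at 1/n_boot;
Bonferroni correction multiplies by the number of tests (the two ROIs).
Whether the motivating analysis resampled subjects or trials was not
stated; subject-level resampling is adopted as the conservative choice.
Auxiliary statistics wrap `stats::t.test` (paired t, with explicit
degenerate handling: all-zero differences give t = 0, p = 1; constant
non-zero differences give an infinite statistic with p = 0) and
`stats::cor.test` (Pearson r with Fisher-z 95% CI). Calibration of all
three — type-I error of the bootstrap and the paired t at N = 16, CI
coverage of the Fisher interval at n = 18 — is asserted by simulation in
the test suite.

## Numerical and design notes

* All randomness flows from one master seed through a deterministic
  splitter (an FNV-style hash of stage tags), so any stage can be
  reproduced in isolation; `withr`-style local RNG scoping keeps library
  calls from perturbing user RNG state.
* Layer normalisation uses epsilon 1e-5; softmax is computed with the
  max-subtraction guard; cross-entropy clips probabilities at 1e-12.
* Zero-variance channels standardise with scale 1 (and a warning) instead
  of dividing by zero.
* The epoch store is a little-endian float64 payload plus JSON manifest
  with an md5 provenance hash; round trips are bit-exact and reads validate
  dims and hash. EDF+ (16-bit, with annotation markers) and BrainVision
  (float32 multiplexed) ingest cut epochs around condition markers,
  dropping markers too close to the recording edges with a warning.
* Problem sizes in the standard test run: 8 subjects × 240 trials for the
  decoding checks, 200 trials for ERSP calibration, 500–1,000 replicates
  for statistical calibration, 6–8 super-features for exact Shapley
  oracles. These sizes are the package's chosen validation conditions.

## Known limitations

* The exact architecture constants of the motivating study are not public;
  the implementation guarantees the lightweight parameter bound and the
  architectural structure, not a specific parameter count.
* The simulator's spatial model is a projection, not a biophysical forward
  model; spatial-pattern claims on real data need real recordings.
* ERSP values at 1–2 Hz inherit wide wavelet supports: baselines are
  partially contaminated by post-cue activity and sharp steps smear.
* Flexion-vs-extension decoding within the supernumerary thumb is out of
  scope, as is any re-implementation of the baseline architectures whose
  published accuracies are used purely as reporting fixtures.
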