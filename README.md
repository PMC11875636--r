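# bandfocus

Single-trial EEG decoding of motor imagery for a **supernumerary thumb**
versus the **natural thumb**, with the full trust pipeline around the
classifier: leave-one-subject-out (LOSO) evaluation, Shapley-value scalp
explainability, and ERSP-based spectral cross-validation.

## Who this is for

Researchers in EEG brain-computer interfaces and human augmentation who
want (a) a compact, fully inspectable band-branched CNN for two-class
motor-imagery decoding that generalises across subjects, and (b) the
statistical machinery to ask *why* it classifies — which electrodes and
frequency bands carry the decision — and whether those features agree with
the neurophysiology (event-related synchronisation and desynchronisation).

## The model

Each trial `x ∈ R^{C×T}` (C = 64 electrodes, MI window at 32 Hz effective
rate) is seen through three fixed band-pass views `x_δ, x_θ, x_α`
(δ = 1–4, θ = 4–8, α = 9–13 Hz; zero-phase FIR). Per band *b*:

    h_b = Dropout(AvgPool_32(ELU(W_b^{spat} * (k_b ⊛_t x_b))))

with 8 temporal kernels `k_b` of 0.5 s and a depthwise spatial filter
`W_b^{spat}` spanning all electrodes (2 per kernel, collapsing the
electrode axis). The 48 concatenated feature maps `U` pass a
squeeze-and-excitation gate

    g = σ(W₂ · ReLU(W₁ · mean_t U)),   V = g ⊙ U,

then layer normalisation (not batch normalisation — the right choice when
train and test subjects differ) and an affine softmax. About 5,500
trainable parameters; training is Adam with early stopping on a
subject-stratified validation split. Forward, backward and optimiser are
implemented in base R (BLAS + FFT) and gradient-checked against finite
differences.

Around the model:

* **`run_loso()`** — leave-one-subject-out harness with train-only
  standardisation (leakage is tested by construction).
* **`shapley_attributions()`** — exact or antithetic-sampled Shapley values
  over channel × time-window super-features; `scale_absolute()`,
  `topography_grid()`, `extract_rois()` for the topographic analysis.
* **`compute_ersp()`** — Morlet ERSP with divisive pre-cue baseline;
  `bootstrap_paired_test()` + `bonferroni()` for the ROI condition
  contrast; `paired_t_test()`, `pearson_with_ci()` for auxiliary
  statistics.
* **`generate_cohort()`** — a synthetic multi-subject MI-EEG simulator
  with planted frontal delta/theta synchronisation (natural thumb) and
  broad alpha desynchronisation (supernumerary thumb), so the entire
  pipeline is verifiable against ground truth.

## Worked example

```r
library(bandfocus)

# a small synthetic cohort: 3 subjects, 60 trials each, planted effects
cfg <- simulation_config(n_subjects = 3, trials_per_condition = 30, seed = 77)
cohort <- generate_cohort(cfg)

res <- run_loso(cohort, tc = train_config(max_epochs = 15, seed = 13))
print(res)
#> <bfn_loso> 3 subjects
#>   S01     60.00
#>   S02     63.33
#>   S03     70.00
#>   Average 64.44 ± 5.09

# did the natural-thumb condition synchronise frontal delta/theta?
roi <- roi_channels(make_default_montage())
ep <- cohort[[1]]
nt <- compute_ersp(ep, channel_set = roi, trials = which(ep$labels == 0))
st <- compute_ersp(ep, channel_set = roi, trials = which(ep$labels == 1))
dt <- band_spec("deltatheta", 1, 8)
round(c(natural = roi_band_average(nt, dt, c(0.5, 3.5)),
        supernumerary = roi_band_average(st, dt, c(0.5, 3.5))), 2)
#>       natural supernumerary
#>          2.57          0.44
```

The per-subject rows are held-out accuracies (%): each subject was
classified by a model that never saw any of its trials, so the average is a
cross-subject generalisation estimate, not a fit statistic. With only two
training subjects the model is data-starved; accuracy climbs steeply with
cohort size (the acceptance run below trains on seven subjects per fold at
twice the trial count). The ERSP
numbers are dB of delta/theta power during imagery relative to the pre-cue
baseline, averaged over the ten frontal ROI channels: the planted +3 dB
synchronisation appears in the natural-thumb condition and is absent in the
supernumerary condition — the dissociation the classifier exploits.

A command-line interface wraps the same functions
(`exec/bandfocus simulate|train-loso|explain|ersp|report`), reading a YAML
config and writing CSV/JSON outputs plus a reproducibility manifest.

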