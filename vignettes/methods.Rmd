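---
title: "Methods: synthetic flanker-task EEG, wavelet spectrograms, and deep-network discrimination of ADHD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic flanker-task EEG, wavelet spectrograms, and deep-network discrimination of ADHD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the generative
model behind the synthetic data, the signal-processing and learning
machinery, the numerical conventions, and — importantly — which design
choices were genuinely open and how they were resolved. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. What the pipeline models

The target analysis discriminates adult ADHD patients from healthy controls
(HC) using single-trial event-related spectral perturbations (ERSPs) of
7-channel EEG recorded during an Eriksen flanker task, classified by neural
networks under leave-pair-out cross-validation (LPOCV), with age treated as
a confounder through inverse-probability weighting (IPW), and interpreted
through activation maximization ("DeepDream"). The clinical recordings
behind the original analysis are not deposited, so the package ships a
generator whose *defaults are the stated study conditions*: 20 subjects per
group, 140 analyzable incongruent frames per subject pooled over 3
sessions (2800 frames per group), ADHD ages 43.85 (SD 14.78) years versus
HC 29.90 (SD 10.77), mean reaction times 368 versus 321 ms, 500 Hz
sampling, −200…+800 ms epochs, and a 2:1 congruent:incongruent trial ratio
with the stimulus-duration staircase grid (flanker-alone 136/114/92/70/48 ms
paired with target 62/52/42/32/22 ms, 500 ms black screen, 300 ms feedback
interval, fixation 200/300/400 ms).

Two reconciliations worth recording:

* **Frames per subject.** One 140-trial session contains ~47 incongruent
  trials, yet the analysis uses 140 incongruent frames per subject. We
  generate `n_sessions = 3` sessions and pool incongruent trials,
  truncating (3×47 = 141 → 140) or topping up to exactly
  `frames_per_subject`.
* **Trial-duration bounds.** The printed bounds (1070–1400 ms) are not
  exactly reproducible from the printed component durations; the closest
  reconstruction gives 1070–1398 ms. We implement the component grid
  verbatim and do not force the printed upper bound.
* **Non-integer ratio.** 140 trials at 2:1 cannot split exactly; the
  incongruent count is `round(n/3)` (= 47), keeping the realized ratio
  closest to the stated one.

## 2. The generative signal model

Each epoch (500 samples at 500 Hz, time stamps at bin left edges of the
half-open interval [−200, 800) ms) is a sum of four components, the first
three scaled per channel by `channel_gains`:

1. **Tonic alpha**: a sinusoid at a subject-specific alpha frequency
   ~N(10, 0.5) Hz (clamped to `alpha_band` = 8–12 Hz), random phase per
   trial, HC amplitude `alpha_amp` = 4 µV. ADHD amplitude is multiplied by
   `10^(alpha_attenuation/20)` — the attenuation parameter is stated in dB
   of *power*, applied as an amplitude factor.
2. **Event-locked theta burst**: a 5 Hz (centre of `theta_band` = 3–7 Hz)
   sinusoid under a Gaussian envelope centred at `theta_latency` = 100 ms
   whose FWHM is `theta_duration` = 100 ms; HC amplitude 2.5 µV; boosted in
   ADHD by `theta_boost` dB. Present only in task mode.
3. **N100**: a negative Gaussian deflection (SD 30 ms) peaking at 100 ms
   with 10 ms latency jitter, 5 µV, multiplied by `n100_gain` for ADHD.
4. **Background**: Gaussian noise with a 1/f^`noise_exponent` amplitude
   spectrum (spectral shaping of white noise), RMS `noise_rms` = 4 µV,
   independent per channel.

Between-subject heterogeneity enters as a dB offset on the oscillatory
amplitudes: `effect_z * subject_sd`, with `effect_z` a standard-normal
subject trait drawn once per subject. In **task** recordings
`subject_sd` = 1 dB; in **resting** (eyes-closed) mode only component 1 is
present and the between-subject SD is `resting_subject_sd` = 3 dB.

Why these numbers: a 4 µV alpha rhythm over a 4 µV-RMS 1/f floor gives
single-trial alpha SNR near 0 dB, typical of task EEG; 1 dB between-subject
spread keeps the −3 dB "strong effect" cohorts separable at the subject
level (effect ≈ 3 SD), while the 3 dB resting spread reflects the
well-known order-of-magnitude variability of idiosyncratic eyes-closed
alpha across individuals — it is precisely this dilution that makes
resting-state classification harder than task classification in the
pipeline, qualitatively mirroring the reported task > resting ordering. The
reaction-time Gamma shape (16) gives a ~25% coefficient of variation.
Ages are truncated at 18 years (adult cohort); the Monte-Carlo test of the
sampler therefore checks against closed-form *truncated*-normal moments,
not the untruncated mean.

What the generator does **not** emulate: eye-blink/EMG artifacts, volume
conduction and channel covariance, non-stationary alpha dynamics,
congruent-trial ERPs, symptom scores. A green recovery test therefore
establishes that the machinery can detect the injected class structure at
realistic SNR — not that it would reach any particular accuracy on clinical
data.

## 3. Preprocessing

The band-pass (1–20 Hz) is applied as an exactly zero-phase filter in the
frequency domain: the squared magnitude `|H(f)|²` of a Butterworth
band-pass prototype — the net response a forward–backward IIR pass would
have — multiplied onto the FFT of the reflection-padded signal. Two
deliberate choices:

* **FFT-domain instead of time-domain forward–backward IIR.** Identical
  magnitude behaviour, exactly zero phase (ERP latencies preserved), no
  dependency on a signal-processing package, and no IIR edge-transient
  management beyond reflection padding (half the signal length per side).
* **Prototype order 10.** The net amplitude response of a zero-phase pass
  is `|H|²`, i.e. twice the per-pass dB; orders 4–6 sag more than 1 dB by
  18 Hz. Order 10 keeps net ripple < 1 dB across 2–18 Hz while attenuating
  0.25 Hz drift and 40 Hz interference by ≫ 20 dB. The response template
  is verified empirically on long sinusoids in the test suite.

Baseline correction subtracts, per epoch and channel, the mean over the
closed window [−200, 0] ms; it is idempotent and linear, and both
operations preserve array shape.

Artifact removal is intentionally an identity hook: synthetic data are
artifact-free, and real-data cleaning (e.g. ICA) belongs to standard
external tooling.

## 4. Single-trial wavelet spectrograms

22 frequencies are geometrically spaced over [3, 20] Hz; wavelet cycle
counts rise *linearly over the bin index* from 1 to 10 (the `[c_min c_max]`
convention of the common time–frequency toolboxes — only the endpoint
cycle counts are stated). Each channel is convolved with a complex Morlet
wavelet (Gaussian SD `cycles/(2πf)`, support ±3.5 SD), normalized to unit
gain on a unit-amplitude sinusoid at its centre frequency, so that power is
in µV² and dB values are re 1 µV². Squared magnitudes are averaged within
20 half-open 40 ms bins covering [0, 800) ms (centres 20, 60, …, 780 ms),
converted to `10·log10`, and floored at −100 dB. There is **no divisive
single-trial baseline**: frames span post-stimulus time only and the
classifier standardization absorbs offsets.

Numerical conventions: the full epoch supports the convolution — the
pre-stimulus 200 ms give the lowest-frequency wavelets real support over
the early bins — and beyond the epoch edges the signal is taken as zero
(plain linear convolution). Mirror reflection was considered and rejected:
a reflected sinusoid has a phase kink at the edge that systematically
drags the spectral peak of late time bins toward lower frequencies,
violating the peak-locality property the stage is specified to have; zero
extension keeps edge truncation leakage symmetric in frequency. The FFT
convolution path is checked against a brute-force time-domain convolution
oracle (sliding dot products, no FFT) to 1e−6 relative error.

## 5. The network engine

No deep-learning framework exists in the target environment, so the engine
is authored in R with Rcpp/RcppArmadillo for the convolution/pooling
primitives (whole-batch im2col + BLAS GEMM; the batch index is the
fastest-varying array dimension, so im2col assembles from contiguous block
copies and the GEMM output aliases the output array with no repacking).
Every backward pass is verified against central-difference numerical
gradients in the test suite.

* **CNN.** The printed trainable-parameter total (75 106) is treated as an
  executable constraint: an exhaustive, deterministically ordered search
  over kernel sizes {3, 5}, filter counts 4…64, same/valid padding and
  floor/ceil 2×2 stride-2 pooling — constrained to two conv blocks plus
  dense 128/64 and a 2-logit head — yields four matching configurations;
  the first (conv 3×3 valid ×63 → pool → conv 3×3 same ×20 → pool →
  dense 128 → dense 64 → head) is frozen as the default, and the
  constructor *fails* if edits change the count. The frozen choice is a
  reconstruction, not a claim about the original hyperparameters. Dropout
  rates (unstated in the source): 0.25 after each pooling stage, 0.5 after
  each dense layer.
* **RNN.** Three stacked LSTM layers of 32 units consume the frame as a
  20-step sequence of 22×7 = 154-feature vectors (time as the recurrent
  axis), dropout between layers, softmax head on the final step. Pure-R
  BPTT — the RNN is exercised at small scale only.
* **SNN.** Flatten → 1024 rectifier units → head.
* **Training.** Weighted softmax cross-entropy on *frames*; Adam with
  lr 0.001 and β₁ = β₂ = 0.9 as printed (β₂ = 0.9 is unusual — a
  `conventional_beta2` flag restores 0.999); batch 32; at most 600 epochs;
  all weights and biases N(0, 0.1²); early stopping monitors the
  *training* loss (patience 25 epochs, min-delta 1e−4) because LPOCV
  leaves no validation set. Inputs are z-scored cell-wise using
  training-fold statistics only; the statistics are stored in the model
  and re-applied at prediction time, so no test-set leakage is possible.

## 6. Validation and confound adjustment

LPOCV enumerates every (ADHD, HC) pair over sorted subject ids — n²
folds for n per group, 400 at 20 vs 20 — holding the pair out and training
on the rest (balanced by construction). A subject's score is the arithmetic
mean of its frame-level ADHD probabilities; the predicted class is ADHD iff
the score exceeds 0.5, with an exact tie deterministically called HC.
Accuracy is the percentage of held-out subjects correct. Per-fold AUC over
a single pair is degenerate (values 0/0.5/1), so the fold-averaged AUC is
reported together with a pooled AUC over all held-out subject scores; the
± dispersions are across-fold SDs (the source's ± is not defined; both the
per-fold SD and the pooled statistic are exposed).

IPW fits a single-covariate binomial logit of group on age *on the
training subjects of each fold*, clips propensities to [0.05, 0.95] (the
standard guard against unbounded weights under near-separation), inverts
(`1/p` for ADHD, `1/(1−p)` for HC), replicates each subject's weight to its
frames, and normalizes the frame weights to mean 1 within the training set
so the effective learning rate is comparable with unweighted training.
When age carries no group information the weights are ~constant and IPW
must be neutral — that neutrality is an acceptance criterion, not an
assumption.

Model comparison uses a two-sample Welch t-test on per-fold performance
vectors, with degenerate zero-variance inputs handled explicitly.

## 7. DeepDream

Starting from a null or standard-noise image in *standardized input units*,
the input ascends the gradient of the chosen class **logit** (not the
softmax) for 30 iterations of step 1. "Step 1" is meaningful only under a
normalization convention: the gradient is divided by its mean absolute
value each iteration (standard DeepDream practice), and the image is
clamped to ±6 standardized units to keep dreams inside the training-data
envelope. Dreams are averaged over fold models and `n_seeds` = 8 noise
seeds by default (the number of random initializations is unstated in the
source; 8 averages out seed idiosyncrasies at modest cost); the seed
stream depends only on the noise-seed index, making the
fold average invariant to model order. Band × time summaries of the
ADHD − HC difference map (alpha 8–12 Hz across the epoch; 3–7 Hz × 50–150
ms) are the package's quantitative mirror of the reported class signature,
and a concordance check compares the dream map's sign pattern against the
empirical mean-ERSP difference of the same data.

## 8. Scaled acceptance runs

The stochastic acceptance criteria (effect recovery, task > resting,
CNN ≥ SNN, dream sign recovery, IPW neutrality) were budgeted assuming a
compiled deep-learning stack. Under this R/BLAS engine on one CPU the
suite runs them at reduced *scale* — 6 vs 6 subjects with 24 frames each,
the 6 diagonal LPOCV folds (each subject held out exactly once), 20
training epochs with early stopping (patience 8, min-delta 1e−3), and
majorities over 3 seeds instead of 5 — chosen from flop arithmetic before
the criteria were first executed. The decision *thresholds* (ACC ≥ 90%,
pooled AUC ≥ 0.95, strict orderings, < 2-point IPW difference, 95%
binomial null bands) are exactly the specified ones. Consequences of the
scale: each seed contributes 12 held-out decisions, so ACC ≥ 90% requires
at least 11 of 12 correct, and the null-cohort band at 12 decisions is
[25%, 75%].

## 9. Known limitations

* The generator's channels are independent given the signal components; no
  head-model spatial correlation. Single-channel ablation is implemented
  but its frontal/parietal ordering is only as informative as the assumed
  `channel_gains`.
* The CNN hyperparameters are one of several parameter-count-exact
  reconstructions; representational claims about "the" original
  architecture are out of scope.
* Training is single-threaded CPU; full-scale runs (400 folds × 600
  epochs × 2800 frames) are possible but slow — the package targets
  desk-scale scientific validation, not clinical throughput.
* The behavioural mixed-model analyses of the source study are outside the
  pipeline; reaction times are generated only as dataset colour.
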