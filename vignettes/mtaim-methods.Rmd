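---
title: "Movement classification from strain-sensor time series: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement classification from strain-sensor time series: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A six-channel wearable piezoresistive strain sensor array ("Motion Tape") is
placed in a 3x2 grid lateral to the lumbar spine: channels 1–2 over the upper
lumbar junctions, 3–4 over the middle, 5–6 over the lower; odd channels sit on
the left column, even on the right. Skin strain during movement changes each
sensor's electrical resistance, recorded roughly every 20 ms over ~6 s trials.
The task is to classify six low-back movements — standing extension, forward
flexion, left/right lateral bend, seated left/right rotation — from these six
resistance traces, optionally aided by paired lumbar Euler-angle kinematics
(upper↔lower lumbar and lower-lumbar↔pelvis, x/y/z each) captured by optical
motion capture during the same trials.

Datasets of this kind are small (tens of subjects, a few repetitions) and
noisy (sensor fabrication variability, skin adherence, spikes). `mtaim`
implements a full pipeline for this regime: conditional generative data
augmentation, frequency-domain and generated-kinematics feature augmentation,
three classifier heads, and distributional quality metrics — plus a seeded
cohort simulator that stands in for the private study data.

## The cohort simulator: a stated world

`make_cohort()` emits `n_subjects x 6 movements x reps` paired trials. Its
defaults encode the emulated study design: 10 subjects, 3 repetitions, 6 s
trials at 20 ms sampling (T = 300), for 180 trials.

Each movement has a deterministic 6-channel template: a smooth
rise–hold–return bump (cosine ramps over phase 0.15–0.35 and 0.65–0.85) with
signed per-channel gains:

* **flexion** — tension everywhere, ordered lower pair > middle pair > upper
  pair (the skin stretches most over the lower lumbar junctions);
* **extension** — compression with the reverse emphasis;
* **lateral bends** — mirror-asymmetric between the left and right sensor
  columns, tension on the convex (contralateral) side;
* **rotations** — smaller-amplitude profiles sharing a common part plus a
  column-asymmetry that is strongest in the upper sensor pair; the
  `class_overlap` parameter (default 0.5) linearly shrinks the left/right
  difference, making the rotation pair the most confusable classes, which
  mirrors the observed difficulty ordering. At `class_overlap = 1` the two
  rotation templates coincide; at 0 all six templates are pairwise distinct.

Ground-truth kinematics come from a fixed linear map of the strain channels
followed by light smoothing: in-phase (sagittal) strain drives the x-angle
channels negatively (flexion decreases the inter-segment angles), uniform
left/right column differences drive y, and the row-graded column difference
characteristic of rotation drives z. Because the map is known and linear,
translator recovery is testable: an all-zero template maps to all-zero angles,
and each movement class dominantly drives one axis.

Subject variability is amplitude and timing only: a lognormal amplitude scale
(SD 0.15), a lognormal time-warp exponent (SD 0.10) applied to the template
phase, and per-channel baseline resistances drawn around a nominal 10
(arbitrary units; the paper-grade nominal value is 10 kOhm, and the absolute
scale cancels under baseline normalization). There is deliberately no
subject-specific waveform signature, consistent with a subject classifier
performing at chance. Noise is additive Gaussian (`noise_sd`, default 0.05
strain units), sparse spikes are Poisson-counted per trial (default rate 0.3)
with magnitudes 0.5–1.5, and a slow linear drift plus offset (default
amplitude 0.05) emulates baseline wander. None of these magnitudes are stated
in the source study; they were chosen once as plausible for a skin-mounted
resistive sensor and are exposed in `cohort_config()`.

What a green test on this world does establish: the pipeline's contracts,
conditioning efficacy, and the direction of augmentation benefits on
small/noisy training sets. What it does not establish: absolute accuracies or
metric scales on real Motion Tape recordings — real sensors have placement,
adhesion and drift structure the simulator does not model, and the private
study's headline numbers are explicitly not reproduction targets.

## Preprocessing

The chain is fixed: baseline normalization `Rn = (R - R0)/R0` →
noisy-trial exclusion → Hampel filtering → alignment/trim against the paired
kinematics → per-(subject, movement) min-max scaling to [-1, 1]. Each trial
carries a provenance log of the applied steps.

Numerical choices worth knowing:

* **Hampel** (window 11, threshold 3 estimated SDs, MAD scaled by 1.4826) is
  iterated to a fixed point (at most 10 passes, usually 1–2). A single pass
  is not idempotent on noisy signals — replacing a point changes its
  neighbors' windows — and we want the filter to be a projection so that
  re-running a pipeline stage is harmless. `max_iter = 1` recovers the
  classic filter. In zero-MAD windows a point is replaced only when strictly
  different from the local median, so flat-plus-step signals survive.
* **Exclusion** drops a trial iff any channel exceeds its own within-trial
  mean + 10 SD (the most local reading of the rule). Note that at short trial
  lengths a single extreme spike inflates the channel SD enough to mask
  itself; at the realistic T = 300 a 50-SD spike is reliably caught. The
  stage runs before Hampel by default (`exclude_after_hampel` swaps), since
  the ordering is not pinned down by the source description.
* **Min-max** uses the min/max pooled over the three repetitions of one
  movement by one subject, per channel, so -1/+1 are that subject's own peak
  compression/tension; a constant channel maps to 0 rather than dividing by
  zero.

## Feature augmentation

`dtft_channels()` returns the magnitude of the length-T DFT divided by T,
as a full two-sided sequence stackable alongside the time channels (6 → 12).
Magnitude (not phase) makes the block invariant to circular shifts — the
"time-independent" property that motivates a frequency view of noisy,
imperfectly aligned movements. The frequency block is not re-normalized: it
derives from already-normalized strain (a config flag can re-enable). Whether
a one- or two-sided spectrum was used originally is unstated; two-sided is
chosen so the block length equals T.

The kinematics block (12 → 18) is either the trial's own paired kinematics
("feature augment" upper bound) or the output of the translator below.

## Generative models

Both condition modes share two backbones written on the package's own
reverse-mode autodiff engine (see below):

**C-VAE** (default: 4 decoder layers, hidden width 12, latent 12, lr 1e-3,
500 epochs, KL weight 1). The encoder mirrors the decoder. For
class-conditional strain generation the label embedding is summed into the
encoder hidden state, into the latent after reparameterization, *and into
every decoder hidden layer*. The last part deviates from the minimal
sum-into-latent design: with conditioning only in the latent, the decoder is
free to ignore the label (we measured 50–67% class-faithful samples); with
per-layer injection the same budget reaches 100% on the clean cohort. The
decoder output is squashed by `tanh` to honor the [-1, 1] data range.

**Diffusion** (default: 500 steps, cosine noise schedule, denoiser width 64,
12 residual layers). A DDPM-style epsilon-prediction MSE is the training
loss; the movement class enters as a learned embedding summed into the
denoiser's internal embedding together with a sinusoidal time embedding.
Sampling is ancestral with the predicted clean signal clipped to [-1, 1] at
every step (clipping, not tanh: the final iterate is already in range and
tanh would distort it).

**Kinematics translator** (condition mode `mt_series`): one single-head
self-attention encoder layer over the 6xT strain series (tokens = time steps,
sinusoidal positions) followed by mean pooling and a linear projection into
the generator's embedding width. The pooled strain embedding is *summed* —
not concatenated — with the kinematics latent (C-VAE; after
reparameterization, a flag point left open by the source design) or with the
per-step denoising embedding (diffusion). Training is supervised against the
ground-truth angle trajectories; generation replaces the learned latent with
a standard Gaussian draw plus the strain embedding. Hyperparameters are
shared with the class-conditional model of the same kind. Zeroing the
projection weights makes generation provably independent of the strain — the
ablation contract used in tests.

TimeGAN exists only as a rejected interface stub
(`train_class_conditional("timegan", ...)` raises a labeled error): it is
excluded from the pipeline for poor generative quality in this setting.

## The autodiff engine

No deep-learning framework is available in the target environment, so the
package carries a ~300-line reverse-mode automatic differentiation engine on
matrices (`R/autodiff.R`): nodes hold value, gradient, parents and a backward
closure; a creation-order index provides the topological order. Every neural
model (C-VAE, diffusion denoiser, attention condition path, CNN-LSTM,
transformer classifier) is a forward composition of these ops; gradients are
verified against central finite differences in the test suite (1e-6
agreement through dense/softmax/layernorm, conv1d/LSTM and masked batched
attention graphs). Self-attention over a minibatch is batched with a
block-diagonal additive mask, trading some wasted off-block compute for an
order-of-magnitude fewer tape nodes; chunk sizes cap the score matrix at
about 1024^2 entries. Optimization is Adam throughout.

## Classifiers

* **CNN-LSTM**: two 1-D convolutions (kernel 5, channels 32/64, stride 2,
  valid padding) over the stacked channels, then stacked LSTMs (default
  hidden 100, 2 layers), softmax head on the final hidden state.
* **Transformer**: per-step channel embedding into width 12, fixed sinusoidal
  positions, 4 post-layernorm encoder blocks, mean pooling, linear head.
* **GBT**: multinomial gradient boosting (learning rate 0.01, depth 3) with
  exhaustive-split regression trees written in the package, over 8 summary
  statistics per channel (mean, SD, min, max, median, IQR, normalized argmax
  time, dominant non-DC frequency bin); flattening the full CxT tensor is a
  config alternative. The same featurization applies to all 18 channels.

Deep heads train with cross-entropy, batch 16, early stopping on a
20-epoch training-loss plateau (budget default 200 epochs). All training is
seeded; identical data + config + seed give identical predictions.

## Metrics

* `wasserstein_1d()` is the exact empirical 1-D W1 via the quantile-function
  formula (for equal sizes, the mean absolute difference of sorted samples).
  The set-level score pools all values per channel across samples and time
  and averages the per-channel distances.
* `discrete_frechet()` is the Eiter–Mannila dynamic program over monotone
  index couplings with a Euclidean point metric across channels, implemented
  in C++; the set-level FTSD takes, for each synthetic sample, the minimum
  distance to the real samples of its class and averages over synthetic
  samples. Both set reductions are the package's own choice (the source
  leaves them unstated), so absolute metric scales are not comparable across
  implementations — they are config-exposed and not acceptance surfaces.

## Evaluation protocol

`make_split()` guarantees that synthetic samples never enter a test set
(asserted on every call). Stratified sampling uses largest-remainder
allocation so a 25% split of 180 real trials is exactly 45 with per-class
counts differing by at most one. LOSO yields one fold per subject (18 test
trials each for the default design).

`run_ablation()` runs the four-arm grid — base (6 channels, real only),
data augment (+synthetic strain, train only), feature augment (+DTFT + real
kinematics; the upper bound with perfect translation), and the combined arm
(+synthetic strain + DTFT + translated kinematics for every sample, test
included: translation uses only the test sample's strain, so no label
leakage). Generators are retrained per trial on that trial's training split
only; reported SDs are over trial-level accuracies. The
subject-identifiability control retrains a head on subject labels under
k-fold CV and reports the distance to the 1/n_subjects chance line.

### When does augmentation help?

On the simulator, the paired kinematics are a noiseless function of the
movement template, so the feature-augment arm with real kinematics is an
oracle (accuracy 1.0) — exactly its role as the upper bound for the combined
arm. The directional benefit of the *combined* augmentation (synthetic strain
+ DTFT + translated kinematics) only materializes when the base classifier is
genuinely data-starved and noise-limited: with 2–3 training trials per class
and noise SD around 0.2 (with rotation overlap 0.7), base accuracy drops to
~0.82 and the combined arm gains ~4 points; at low noise the base head
already sits at ceiling and augmentation has nothing to add. Two practical
lessons are baked into `run_ablation()` defaults and documented here: the
per-trial generators must be given a training budget appropriate to the tiny
split (hundreds of epochs when an epoch is a single minibatch), and
augmentation experiments should be read relative to the base arm's headroom.

## Scaling choices in tests

The shipped tests and acceptance checks run the neural paths at T = 48
(2.4 s at 50 ms) with reduced epochs; structural counts (180/120/300 trials,
12/18 channels) are independent of T and epochs, and the property gates
(conditioning efficacy ≥ 80%, translator < permuted control, combined arm ≥
base arm) keep their thresholds unchanged. This is purely a CPU-budget
choice.

## Known limitations

* The simulator's noise, drift and inter-subject variance magnitudes are
  placeholders (the source quantifies none of them); conclusions about real
  sensors require real recordings.
* Sensor drift correction, resampling, and LBP-patient movement patterns are
  out of scope.
* The diffusion backbone is a plain residual MLP denoiser; the
  Fourier-reconstruction loss of the Diffusion-TS lineage is not implemented
  (epsilon-prediction MSE is the default and only loss).
* Boosted trees use summary-statistic featurization by default; results are
  not directly comparable to a full XGBoost on raw sequences.
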