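---
title: "Methods: cycle-consistent ECG denoising and TCN arrhythmia classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cycle-consistent ECG denoising and TCN arrhythmia classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ecgdnn)
```

`ecgdnn` implements a two-stage pipeline for ambulatory ECG analysis: an
unpaired, cycle-consistent adversarial denoiser whose generators are
denoising autoencoders, and a multi-label arrhythmia classifier built from
parallel temporal convolutional network (TCN) branches.  Because clinical
ECG corpora cannot ship with a package, a synthetic 8-lead ECG simulator
provides the study conditions for every experiment in the test suite.  This
vignette records the models, their assumptions, the tunable parameters, and
the design decisions taken where the problem was genuinely open.

## The denoising model

Two generators translate between the noise domain $N$ and the clean domain
$C$: $G_{N2C}$ denoises and $G_{C2N}$ re-noises.  Two discriminators
$D_{N2C}$, $D_{C2N}$ judge whether a segment looks like a member of the
clean and noise domains respectively.  Training needs no paired data; the
coupling comes from the loss

$$\mathrm{Loss} = \mathrm{Loss}_{GAN}
  + \alpha\,\mathrm{Loss}_{cycle} + \beta\,\mathrm{Loss}_{identity},$$

where $\mathrm{Loss}_{GAN}$ is the two-direction adversarial objective
(log-likelihood on real samples plus $\log(1 - D(G(\cdot)))$ on generated
ones, logs clamped at $10^{-7}$), $\mathrm{Loss}_{cycle}$ is the mean L1
error of the round trips $G_{C2N}(G_{N2C}(n)) - n$ and
$G_{N2C}(G_{C2N}(c)) - c$, and $\mathrm{Loss}_{identity}$ is the mean L1
error of each generator applied to its own output domain,
$\|G_{N2C}(c) - c\|_1 + \|G_{C2N}(n) - n\|_1$.  The identity term keeps the
denoiser from altering signals that are already clean.

Each generator is a mirror-symmetric strided encoder–decoder: five
down-sampling blocks (1-D convolution, instance normalisation, tanh) and
five up-sampling blocks (1-D transposed convolution, instance
normalisation, tanh).  The output block omits the normalisation so the
reconstruction amplitude is not forced to unit variance; the final tanh
bounds outputs to $(-1, 1)$, which is why the pipeline min–max normalises
every lead to $[-1, 1]$ before denoising.  The transposed convolutions are
implemented as the exact adjoint of the strided convolutions over the same
padding geometry (total padding $= k - s$), so input and output lengths
match for any length divisible by $s^{5} = 32$.  Each discriminator is five
sub-sampling blocks (convolution, instance norm, leaky ReLU) followed by a
single stride-1 convolution producing a patch realness map; losses average
over patches.

Key training parameters (`denoiser_train_config()`):

| parameter | default | meaning |
|---|---|---|
| `alpha` | 10 | cycle-loss weight |
| `beta` | 5 | identity-loss weight |
| `lr` | 2e-4 | Adam step for the adversarial game |
| `pretrain_epochs` / `pretrain_lr` | 10 / 1e-3 | DAE pre-training budget |
| `batch_size` | 16 | segments per update |

$\alpha = 10,\ \beta = 5$ follow standard cycle-consistency practice (the
loss composition is fixed by the model but the weights are free
parameters).  The DAE phase tolerates a larger Adam step than the
adversarial game because it is a plain regression; both rates are exposed.

**Pre-training.**  Both generators are pre-trained symmetrically as
denoising autoencoders: each input segment is corrupted with simulated
noise and reconstructed under an L1 objective.  The default corruption is
the composite Gaussian + baseline-wander mixture at 0 dB — the same
ambient corruption the denoiser is meant to remove.  The package's
initialisation study (`compare_initializations()`) evaluates the total loss
of the freshly built model on a fixed batch under three schemes —
scaled-uniform random init, Gaussian init (sd 0.02), and DAE pre-training —
and the test suite asserts that pre-training yields the smallest initial
loss (median over three seeds).

**Divergence guard.**  Adversarial training aborts with a diagnostic error
when the total loss exceeds ten times its initial value for three
consecutive epochs.

## The classifier

The classifier maps an $8 \times T$ record to 34 independent class
probabilities (multi-label: a record may carry several arrhythmia events).
A front-end convolution spans all 8 leads with a temporal kernel of 50
inside a residual block; three parallel TCN branches with kernel sizes 3,
5 and 7 then extract temporal features; each branch is average-pooled over
time, the three pooled vectors are concatenated, and one linear layer
produces the 34 logits.

Each branch stacks one residual block per dilation factor (1, 2, 4), with
two dilated causal convolutions per block.  The receptive field of a branch
follows the closed form

$$\mathrm{field} = (k - 1) \cdot \textstyle\sum d \cdot n + 1,$$

giving 29, 57 and 85 samples for the three default branches; 85 is the
maximum receptive field of the parallel model, and the narrower branches
re-capture nearby context at higher effective weight.  `receptive_field()`
evaluates the formula and `probe_receptive_field()` verifies it empirically
by single-sample perturbation on a built branch (run with linear
activations, so the influence boundary is purely architectural rather than
an artifact of dead rectifier units).

**Causality.**  Every convolution in the classifier is causal (left padding
only), including the front end.  A centred front-end kernel would leak up
to 25 future samples into each feature, contradicting the leakage-free
design that motivates causal convolutions, so the front end pads its 50-tap
kernel entirely on the left.  `causality_check()` verifies at any time
index that perturbing later samples moves no pre-pooling feature.

**Class imbalance.**  `class_weights_from_counts()` implements inverse
frequency weights, capped at 100 times the smallest weight and normalised
to mean 1.  The inverse direction is deliberate: up-weighting the rare
classes is what counters imbalance, and the alternative
(`policy = "proportional"`, weights proportional to class share) is kept
selectable for comparison.  Zero-count classes receive the smallest
observed weight rather than the cap: a label slot with no positive
examples carries no frequency information, and giving it a large weight
would both dominate the loss (32 of 34 slots are empty in a two-class
experiment) and dilute — via the mean normalisation — the boost intended
for observed rare classes.  Training supports class-weighted BCE (the
product of the weight with the full cross-entropy bracket), plain BCE,
focal loss ($\gamma = 2$) and MSE on sigmoid outputs, all with numerically
stable logit-space gradients.  `tcn_preset("model_1")` …
`tcn_preset("model_5")` reproduce the architecture sweep configurations
(single branches of kernel 3/5/7; parallel branches with dilations 1,2,4 or
1,4,8).

TCN blocks use plain convolutions with scaled-uniform initialisation
rather than weight-normalised ones; weight normalisation is a
reparameterisation that changes no architectural property checked here,
and omitting it keeps the hand-derived backward passes simple.

## The synthetic data generator

Clinical-scale ECG corpora are replaced by a parametric simulator:

- **Beat model.**  Each PQRST complex is a sum of five Gaussian bumps
  (centres, widths and amplitudes per wave) evaluated on three latent
  "dipole-axis" components with distinct amplitude signatures; a fixed
  full-column-rank $8 \times 3$ matrix mixes the components onto the 8
  leads, with leads I/II anchored as the strongest projections so the
  12-lead derivation acts on physiologically ordered channels.  P and T
  timing and width scale with $\sqrt{RR}$ (Bazett-style).  A dynamical ODE
  heart model would be more realistic but is unnecessary: downstream code
  consumes only leads, labels and noise structure.
- **Rhythm classes.**  34 label slots; slots 1–8 are mechanistic (sinus
  rhythm, tachycardia > 100 bpm, bradycardia < 60 bpm, sinus arrhythmia at
  RR coefficient of variation ≥ 0.12, T-wave change, QRS low voltage, ST
  abnormality, pacing spikes); slots 9–34 are nominal morphology variants
  with deterministic per-class template perturbations.  The vocabulary is
  nominal by necessity — it exercises the 34-way head without claiming
  clinical realism.  Rate-derived labels are recomputed from detected R
  peaks in the tests and must agree with the emitted label bits.
- **Noise.**  Gaussian white noise, baseline wander (sinusoids at 0.15 and
  0.3 Hz with random phases per lead), impulse noise (Bernoulli spikes),
  and composites.  When a target SNR is requested the residual is scaled
  per lead so the corrupted record hits the target exactly; tests assert
  0.1 dB over $[-10, 20]$ dB.
- **Imbalance.**  `make_dataset()` samples a primary class per record from
  arbitrary frequency weights; the default profile decays geometrically
  across the 34 slots, mimicking the long-tailed distribution of clinical
  arrhythmia corpora.

What passing tests on this generator do **not** show: robustness to real
electrode-motion artifacts, inter-patient morphology variation, or
pathologies outside the template family.  The synthetic corpus shares only
the *structure* of the problem (quasi-periodicity, lead correlation, noise
families, label imbalance) with clinical data.

## Problem sizes and numerical choices

The experiments in the test suite are desk-scale, sized for a single CPU:
denoiser studies use 10-second records at 250 Hz, min–max normalised,
corrupted at 0 dB, and windowed into 500 segments of 256 samples; the
generator/discriminator configs for these runs use kernel 9, base width 8,
and widths capped at 64 channels (package defaults follow the full-size
description: kernel 16, base width 16, cap 256).  The denoising-efficacy
study trains with the default pre-training budget plus 20 adversarial
epochs and evaluates on 16 held-out records; the classifier studies use
240 five-second records at 100 Hz with 8-channel branches.  These sizes
are the package's chosen study conditions and are stated here so results
are read at the scale that produced them.

Numerics worth knowing: instance norm uses $\varepsilon = 10^{-5}$;
adversarial and BCE losses clamp probabilities at $10^{-7}$; L1 gradients
use the sign subgradient at 0; Adam uses $(\beta_1, \beta_2) =
(0.9, 0.999)$; dropout (0.1 in TCN blocks) is inverted and disabled at
evaluation; all randomness flows through explicit seeds and generation is
bitwise reproducible for a fixed seed.  Records whose length is not a
multiple of 32 are zero-padded on the right before denoising and trimmed
after.  Degenerate inputs are defined rather than fatal: identical signals
give `snr = +Inf`, constant leads normalise to zeros, a window longer than
the record yields zero segments.

## Known limitations

- The denoiser operates per lead with single-channel generators;
  multi-lead joint denoising is a natural extension.
- The adversarial value reported as `loss_gan` uses the saturating form
  for interpretability while generator updates use the non-saturating BCE
  objective — curves are therefore comparable across runs but not equal to
  the generator's training objective.
- The morphology-variant classes (9–34) are separable by construction;
  real inter-class confusion structure is not emulated.
- Training times assume the scaled configurations above; the full-size
  generator (kernel 16, 256 channels) is practical for inference but slow
  to train without batching across many cores.
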