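---
title: "Culprit-artery classification from 12-lead ECG spectrograms: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Culprit-artery classification from 12-lead ECG spectrograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(coromix)
```

## The problem

In non-ST-elevation myocardial infarction (NSTEMI) the culprit coronary
artery — circumflex (CX), right coronary (RCA), left anterior descending
(LAD), or a combination — cannot be read off the ECG by eye; the
diagnostic ST/T changes are subtle and non-localizing, and invasive
angiography is the gold standard. `coromix` implements a
machine-learning pipeline that attempts this localization from the
12-lead ECG alone, as a seven-class problem over the non-empty single
and combined occlusions (CX, RCA, LAD, CX+LAD, RCA+LAD, RCA+CX,
RCA+CX+LAD):

1. each lead's waveform becomes an RGB **spectrogram image**
   (short-time Fourier transform, dB magnitude, viridis colormap,
   64×64);
2. a **multi-input multi-scale ConvMixer** consumes all 12 lead images
   at two patch scales (24 branches) and is trained end-to-end with
   softmax/cross-entropy;
3. a 1000-wide fully connected embedding (`fc_embed`) is extracted per
   record;
4. **ReliefF** scores each embedding feature;
5. a **weighted subspace SVM ensemble (WSSE)** partitions the ranked
   features into k subspaces, trains one SVM per subspace, and combines
   predictions by importance-weighted majority voting.

Evaluation is stratified k-fold cross-validation with per-class
one-vs-rest sensitivity, specificity, precision and F-score, and a
four-arm ablation (end-to-end model / +SVM / +ReliefF+SVM / +WSSE).

The clinical dataset this method was developed on is not public, so the
package ships a synthetic 12-lead generator with class-dependent
ST-segment morphology; every claim the test suite makes is made about
that synthetic world, not about clinical data.

## The synthetic world

`sim_config()` states the emulated conditions once: 1321 records in the
class proportions 180/185/252/183/173/156/192, 500 Hz, 10 s records,
heart rate drawn uniformly per record from 55–95 bpm.

Each record is a train of beats built from parameterized Gaussian bumps
(P 0.12 mV, Q −0.15, R 1.0, S −0.25, T 0.3 mV; widths chosen so the
ST window is clear of the S and T tails). The class effect follows the
standard electrocardiographic territory convention — RCA → II, III,
aVF; LAD → V1–V4; CX → I, aVL, V5, V6; combinations take unions; aVR
carries no class effect. On territory leads only, an NSTEMI-like
ST-segment **depression** of 0.15 mV is applied as a level offset over
the 80 ms window after the QRS offset of every beat, and the T wave is
inverted with probability 0.5. Baseline wander (0.05 mV, 0.2–0.5 Hz,
random phase per lead) and white noise (0.02 mV SD) are added.

Design notes:

* Lead gains are uniform (aVR polarity flipped). Early versions scaled
  each lead by a physiological gain; that leaked into the per-image
  normalization and confounded the cross-lead territory contrast that
  the generator exists to provide. Physiological fidelity is an
  explicit non-goal; separability is the point.
* Per-record seeds are `master seed + running index`, so dataset
  generation is a pure function of the configuration.
* What a green test establishes: that the pipeline runs, learns and is
  internally consistent on this stated world. It does not establish
  clinical performance; real NSTEMI effects involve morphologies
  (T-wave shape changes, reciprocal changes, conduction artefacts) the
  generator does not emulate.

A brute-force **territory-rule oracle** (`classify_st_rule`) certifies
separability before any model sees the data: it estimates each lead's
ST-window deviation in the time domain and assigns the class whose
territory shows the largest mean absolute deviation contrast. At the
default noise settings it recovers ≥ 95% of labels (tested on 140
records, 20 per class).

## Spectrogram front end

`spec_params()` defaults follow the stated analysis settings: Hamming
window of 10 samples, FFT length 512, 500 Hz; magnitudes are converted
to dB as `20*log10(|.| + 1e-12)`. The hop is 5 samples (50% overlap) —
the standard default where the overlap is not otherwise determined. The
dB matrix is min–max normalized per image, mapped through the standard
256-entry viridis lookup (bundled as a plain-text fixture; the base-R
`hcl.colors` "viridis" is only an approximation), and resized to 64×64
by bilinear interpolation per channel. 64 is the model's formal input
size; 100 is available via `out_size`.

Numerical notes:

* With a 10-sample window the Hamming mainlobe is ≈ 100 Hz wide, so
  the per-frame peak bin of a pure tone does **not** sit at
  `round(f*nfft/fs)`: for a 50 Hz tone at these settings the true
  peak (confirmed by a brute-force DFT oracle) is bin 55, not the
  naive 51. The naive formula becomes exact once the window resolves
  the tone (window ≥ 100 samples here), and the test suite asserts
  both facts rather than the invalid shortcut.
* A constant dB matrix maps to normalized value 0, i.e. viridis(0) ≈
  (0.267, 0.005, 0.329); images are invariant to adding a constant in
  dB (min–max shift invariance).
* The per-image minimum of a noisy dB spectrogram is the deepest
  spectral null, an extreme-value statistic that varies by ±10 dB
  between images. Per-image min–max normalization therefore injects a
  random affine distortion per lead image. This matters for
  learnability; see "Known limitations".

## The MI-MS ConvMixer

One branch per (lead, scale) pair — 24 at the defaults (12 leads ×
patch sizes 16 and 8). Each branch: patch embedding (stride-P
convolution, P²·3 → H), then GeLU, then BatchNorm — the printed
composition order BatchNorm(GeLU(·)) is kept everywhere, although much
of the ConvMixer literature uses the reverse — then D mixer blocks of
(depthwise K×K convolution → GeLU → BatchNorm → residual add) followed
by (pointwise H×H convolution → GeLU → BatchNorm), and global average
pooling to H values. Branch outputs are concatenated (scale-major, lead
within scale) and passed through the 1000-wide linear embedding
`fc_embed` and a softmax output layer. The residual connection exists
only around the depthwise stage; zeroing a block's depthwise kernel at
the zero-bias initialization reduces that block's residual unit to the
identity, which the tests assert exactly.

The reference hidden width is 750 (concatenated feature length
12·2·750 = 18 000); the package default is H = 32 so the model trains
at desk scale, and H = 750 is a flag away. The reported layer counts
and model memory quoted for this architecture are mutually inconsistent
(148 vs 81 layers; 158 KB is impossible for H = 750 in 32-bit floats),
so depth D is an explicit knob (default 4) and no paper-faithful preset
is claimed. The feature layer is referred to inconsistently as fc1/fc4
in the reference description; this implementation exposes a single named embedding
layer `fc_embed`, which is all the downstream stack needs. The head
applies no activation between `fc_embed` and the output layer, staying
closest to the printed form of the output equation; embedding features
are pre-softmax activations, unconstrained in sign.

Training is SGD with momentum 0.9, initial learning rate 0.001,
mini-batch 128, cross-entropy loss — the reference recipe — with a 10%
validation split evaluated every 30 iterations. Everything is plain R
matrix arithmetic; gradients are analytic and verified against central
finite differences to < 1e-4 relative error on a micro configuration.
Training is bit-deterministic for a fixed seed and platform.

## ReliefF

The stated parameters (k = 10 neighbours, sigma = 20, empirical
priors) pin the classical multi-class ReliefF with exponential
distance-rank decay, so that variant is implemented from scratch:
every sample is an anchor (m = n); neighbours are found by Manhattan
distance on range-normalized features; rank j carries weight
`exp(-(j/sigma)^2)`, normalized over the k neighbours; hits subtract,
misses add with coefficient `P(C)/(1 - P(class(anchor)))`. Classes
with fewer than k+1 members use all available neighbours; constant
features get weight exactly 0. A literal nested-loop oracle must agree
to 1e-10 on random small instances. Weights are computed **inside each
training fold** (the leakage-safe reading; whether the original
analysis did the same is unstated).

## WSSE

Ranked features are split into k contiguous blocks (sizes differing by
at most one, larger blocks first, best features first). Each subspace
trains one multi-class SVM on its own columns; at prediction time
subspace i casts its label with vote mass equal to the (non-negative)
sum of its features' ReliefF weights, and the final label is the mass
argmax, ties resolved in favour of the earliest (highest-mass)
subspace among the tied classes. The source pseudocode's "most
repeated values" phrasing admits a second reading — integer vote
replication, k−i+1 votes for subspace i — which is provided as
`vote = "replicate"`; neither reading is claimed as the authors'
exact scheme. k is not fixed by the reference description; the default is 10
(subspaces of 100 at p = 1000).

No SVM implementation ships with the supported environment, so the
package carries its own C-SVC: sequential minimal optimization with
maximal-violating-pair working-set selection (Rcpp), RBF and linear
kernels, one-vs-one multi-class voting, deterministic throughout.
Inputs are standardized by default (training mean/SD), matching the
convention of the classic SVM interfaces; `gamma = "scale"` is
`1/(p · var)` on the standardized matrix. A k = 1 ensemble is
arithmetically identical to a single SVM on all features (subspace
columns are used in ascending original order to make this exact), and
the suite asserts exact label agreement.

The ensemble-benefit claim — WSSE improves on a plain SVM — is tested
on a 7-class Gaussian tabular benchmark: 40 informative features
(class means drawn N(0, 0.5²)) plus 960 pure-noise features, n = 700.
The effect size 0.5 was fixed once so that the plain SVM lands around
70% (at larger effects both classifiers saturate and the comparison is
vacuous); 3-fold stratified CV is used to stay inside a single-CPU
budget. Across 20 seeds the WSSE mean CV accuracy must be at least the
plain SVM's in 15 or more.

## Evaluation

Stratified k-fold plans assign each class's shuffled members so that
per-class fold counts differ by at most one, with remainders dealt to
the least-loaded folds (so total fold sizes also differ by at most
one). Metrics come from the one-vs-rest collapse of the 7×7 confusion
matrix; 0/0 divisions yield 0 with a flag; accuracy equals the
support-weighted mean of per-class sensitivities (asserted as an
identity). Reports carry 4 decimals; comparisons against printed
reference values use 2.

The ablation runner executes all four arms under one fold plan and one
master seed, fitting the network, ReliefF and all classifiers strictly
inside each training fold, and pools predictions over folds before
computing confusion matrices. Arm (c) keeps the top q = 500 ReliefF
features (the original selection size is unstated; q is a knob).

## Known limitations

* **The end-to-end image pathway is signal-starved at desk scale.**
  The class effect is a 0.15 mV, 80 ms ST offset; after the pinned
  front end (10-sample window, dB magnitude, per-image min–max
  normalization, 64×64 resize) its image-space signature is a ~1%
  change in low-frequency content, while the per-image normalization
  jitter (extreme-value minimum of the noise floor) and heart-rate
  variability induce same-order within-class variation. In the
  noise-free world the territory contrast is cleanly visible (the
  suite asserts it); at the default noise settings a reduced training
  run (245 records, H = 16, 10 epochs) memorizes the training fold
  without generalizing. The acceptance suite states the reduced
  end-to-end learnability expectation faithfully and documents its
  outcome rather than adjusting the world to force it green.
* Magnitude spectrograms are blind to T-wave inversion (|FFT| is
  sign-invariant), so half of the generator's class effect never
  reaches the model; the ST offset carries all learnable signal.
* The SMO solver is a plain working-set implementation without
  shrinking or caching; it is adequate for n in the hundreds, not for
  large-scale use.
* Validation-split size, BatchNorm momentum (0.1), He-style
  initialization and the bilinear resize convention are artifact
  choices; each is a documented default, none is claimed to match the
  unpublished original.
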