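---
title: "Methods: RF synthesis from B-mode and QUS validation on simulated phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RF synthesis from B-mode and QUS validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`echogen` studies a single question end to end: can raw radiofrequency
(RF) ultrasound echo data be synthesized from B-mode images faithfully
enough that downstream quantitative ultrasound (QUS) tissue
characterization still works? The package contains four layers:

1. a physics-based simulator producing paired RF/B-mode phantom scenes
   whose microstructure (scatterer size, density, attenuation) is known
   exactly;
2. the QUS estimation chain: reference-phantom spectral normalization,
   two-layer attenuation correction, linear spectral fits (MBF/SS/SI),
   Gaussian form-factor fits (ESD/EAC), and GLCM texture features;
3. three conditional GAN translators (a U-Net Pix2Pix generator and
   shallow/deep vision-transformer generators, sharing one patch
   discriminator) that learn the normalized B-mode to RF mapping;
4. evaluation: sample-level fidelity metrics, UMAP feature-distribution
   comparison, and a benign/malignant classification protocol with
   two-step feature selection, an RBF SVC, and bootstrap test
   evaluation under four train/test dependency conditions.

Because the clinical data such a study would normally use are
institutional and unavailable, every empirical claim in this package is
made against the simulator, where ground truth is known. That is a
deliberate trade: parameter recovery and oracle equivalence become
provable, while realism is bounded by the simulator's assumptions
(below).

# The simulator

## Scene model

A scene is an ordered list of acoustic regions painted over a
rectangular field of view: a background, an optional superficial layer
(intervening tissue), and axis-aligned elliptical lesions. Later
regions override earlier ones. Each region carries:

* `a_eff_um` — effective scatterer radius in micrometres. This is the
  parameter the ESD estimator must recover (ESD = 2 a_eff).
* `n_per_mm2` — scatterer number density (the simulation is 2-D, so
  density is per area). Sets the effective acoustic concentration.
* `amplitude_variance` — variance of the zero-mean Gaussian per-scatterer
  reflectivity.
* `alpha` — one-way attenuation in dB/MHz/cm.

Scatterers are drawn as a Poisson process (`count ~ Poisson(n * area)`,
uniform positions), so fully developed speckle emerges naturally when
the density is high enough. The default densities (400-700 per mm^2)
put well over ten scatterers in each resolution cell, which is the
standard requirement for Rayleigh statistics.

## RF synthesis

Per scan line, scatterer impulses are deposited at the nearest axial
sample (`round(2 z fs / c)`) and filtered in the frequency domain by
the product of

* a Gaussian transmit pulse spectrum (center 10 MHz, fractional -6 dB
  bandwidth 0.6, sampled at 40 MHz, c = 1540 m/s — the default
  acquisition the package emulates), and
* a per-region amplitude form-factor filter `sqrt(kappa) a^3 k^2
  exp(-0.827 k^2 a^2 / 2)`, the square root of the single-scatterer
  contribution to the spherical Gaussian backscatter coefficient
  `BSC(f) = kappa n a^6 k^4 exp(-0.827 k^2 a^2)`, `k = 2 pi f / c`.

The synthesis and estimation stages share this one BSC model, so the
round trip is self-consistent: the expected window power spectrum of a
homogeneous region is (system response) x BSC x (round-trip
attenuation), which is what makes estimator-recovery tests meaningful.
Nearest-sample deposition was chosen over two-tap linear interpolation
deliberately: with random phases the cross terms vanish and the
expected power spectrum is unbiased, whereas a linear split acts as a
frequency-dependent low-pass and would tilt the spectral slope.

Attenuation is applied as a depth-varying filter over 64-sample Hann
blocks with 75% overlap-add; each block is filtered by
`10^(-2 f A(x, z_b) / 20)` where `A` is the one-way path integral (in
dB/MHz) through the painted regions above the block center. The 75%
overlap keeps the piecewise-constant approximation within a few
hundredths of a dB of the exact exponential (measured on a point
target); at 50% overlap the error is an order of magnitude larger.
`kappa` is a single named model constant (default 1) carried in the
reference calibration; absolute BSC calibration is out of scope, so
only ratios to the reference phantom matter.

The reference phantom mirrors a tissue-mimicking calibration phantom:
homogeneous, one-way attenuation 0.786 dB/MHz/cm, speed of sound
1540 m/s, with its scatterer radius and density recorded as the
calibration used by the BSC estimator.

## B-mode formation and the cohort builder

B-mode is the magnitude of the per-line analytic signal, log-compressed
to a configurable dynamic range (default 50 dB), normalized to [0, 1],
and optionally resampled to a display raster — the lossy forward
transform whose inversion the translators learn.

`build_paired_dataset()` draws lesions per class with the defaults:

* benign: `a_eff ~ U(80, 110)` um, density 350 per mm^2, homogeneous;
* malignant: `a_eff ~ U(40, 70)` um, density 700 per mm^2, amplitude
  variance doubled, and 15% relative within-lesion jitter applied per
  imaging plane (emulating intra-tumoral heterogeneity across
  cross-sections);
* background: `a_eff` 60 um, density 500 per mm^2.

These ranges mirror the benign/malignant scatterer-property contrast
reported in the breast-QUS literature (larger, sparser effective
scatterers in fibroadenomas; smaller, denser, more heterogeneous ones
in carcinomas) and are deliberately disjoint so that end-to-end
separability is a testable target rather than a statistical accident.
Each lesion is imaged at 4 planes with the cross-section shrunk by up
to 15% per plane. Attenuation defaults to 1.0 dB/MHz/cm everywhere
(the standard intervening-breast-tissue prior), so the two-layer
point compensation with that prior is exact and attenuation mismatch
does not confound class separation; scenes with contrasting `alpha`
are supported and tested separately.

# The QUS chain

## Windows and spectra

Parametric maps are computed inside the lesion core plus a 5 mm margin
(morphological dilation with an elliptical kernel in physical units —
the RF grid is strongly anisotropic, ~19 um axially vs ~118 um
laterally). Hann-gated windows of 2 x 2 mm slide with 94% overlap at
full scale; desk-scale runs use 25-50% overlap since the window count,
not the window size, is what the smaller budget must absorb. Windows
are kept when their center lies in the mask and are shifted inward
(flagged) when their footprint would leave the frame. Per window, each
line is mean-subtracted, Hann-gated, and periodogram-averaged across
lines onto a fixed 1024-point grid.

## Normalization, attenuation, parameters

The window spectrum is divided (in dB, subtracted) by the reference
phantom's spectrum for the same window, cancelling the system transfer
function. Attenuation correction is the point-compensation method with
two layers: intervening tissue above the ROI top (prior
1.0 dB/MHz/cm) and tumor below (either the spectral-difference ACE
estimate from core windows, when the core spans at least 0.5 cm of
depth, or the configurable prior otherwise — at desk scale the frames
are only ~1 cm deep, so the prior path is the default). Because the
spectra are already reference-normalized, the correction applies
*differential* coefficients (layer alpha minus the reference phantom's
0.786 dB/MHz/cm); this is what makes "sample identical to reference
implies 0 dB flat" hold exactly.

The analysis band is the -6 dB bandwidth of the reference spectrum
intersected with a configurable absolute band. The absolute band
defaults to 3-13 MHz so that the -6 dB rule governs for the default
10 MHz pulse (whose -6 dB power band sits near 8.6-12.5 MHz); a
narrower absolute band remains available for lower-frequency
configurations.

MBF/SS/SI come from ordinary least squares of dB power on frequency;
MBF is the fitted value at band center, so `MBF = SS f_c + SI` is an
exact identity. The BSC estimate is `BSC_ref(f) 10^(corrected_dB/10)`
with `BSC_ref` from the calibration microstructure. The Gaussian form
factor is fitted in closed form: `ln BSC - 4 ln f` regressed on `f^2`;
the slope gives `a_eff` (the fit is exact on noiseless model data —
the linearization introduces no approximation), and the intercept,
after removing the frequency-unit constant `4 ln(2 pi 1e6 / c)`, gives
the effective acoustic concentration as `EAC = 10 log10(n_est)` dB.
Without that constant the EAC value would depend on whether frequency
is expressed in Hz or MHz; making it explicit keeps EAC self-consistent
with the simulator's `kappa`. A non-negative slope means the band
carries no resolvable size information; the window is flagged
degenerate and masked invalid rather than reporting a zero ESD as if it
were a measurement.

ACE uses the spectral difference method: per-frequency least-squares
slopes of normalized dB power versus depth, converted by
`alpha_s(f) = alpha_ref - m(f) / (2 f)` (one-way convention; the
round-trip factor 2 is explicit everywhere — in nepers-amplitude terms
this is the usual factor 4), then a final regression of
`alpha_s(f) f` on `f`. The per-frequency-then-regress form was chosen
over a joint 2-D fit because it degrades gracefully when the band edges
are noisy and each step is separately testable.

## Texture and the 25-feature vector

Each of the five maps, on its raw window-center grid (never the
display-interpolated raster, which would smooth in artificial
texture), is linearly quantized into 16 levels over its own range —
which makes all texture features invariant to affine map rescaling.
Symmetric, mask-aware GLCMs at distances 1-5 pixels and angles
0/45/90/135 degrees (20 matrices) yield contrast, correlation, energy,
and homogeneity, averaged over the 20. A constant map has undefined
GLCM correlation; it is reported as 1 (a constant map is maximally
self-correlated) and flagged, which keeps feature tables free of NaNs.
The per-lesion descriptor is 5 map means + 5 x 4 textures = 25 named
features, averaged across the planes spanning the lesion. Map means
and textures are computed over core plus margin by default (the
region is configurable) since the peritumoral band is part of the
standard QUS characterization target.

# The translators

All three generators map a normalized [0, 1] B-mode frame to a
normalized RF frame of the same shape and are geometry-parameterized:
the full-scale instantiation (2048 x 512 after preprocessing) and the
desk-scale one (256 x 64) share all code.

* **Pix2Pix (U-Net)**: 7 stride-2 4x4 encoder convolutions with filters
  doubling from 64 and capped at 512 (batch norm from the second level,
  leaky ReLU 0.2), a mirrored decoder of 6 transposed convolutions with
  skip concatenations (dropout 0.5 on the first three decoder blocks,
  ReLU), and a final sigmoid transposed convolution.
* **Shallow ViT**: 16 x 16 non-overlapping patches, linear embedding
  plus learned positional embeddings, 2 pre-norm transformer encoder
  blocks (multi-head self-attention + GELU MLP at 4x width), token
  reshape to a coarse feature map, then 4 transposed-convolution
  upsampling stages (batch norm + leaky ReLU on the first three,
  sigmoid last).
* **Deep ViT**: the same embedding with 5 encoder blocks; the outputs
  of blocks 3 and 1 are projected by 1x1 convolutions (block 1 also
  nearest-neighbour upsampled) and concatenated into decoder stages 1
  and 2 — reshape-and-upsample skip paths that carry early-block detail
  into the reconstruction. The wiring of these taps is an
  interpretation choice; the tap points and projection width
  (`skip_channels`) are exposed in the spec.

The shared patch discriminator takes the channel-concatenated
(B-mode, RF) pair through three 3x3 stride-2 blocks (64/128/256 filters,
layer norm, leaky ReLU) and two zero-padded stride-1 head convolutions
(512 then 1), ending in a sigmoid probability map of (rows/8, cols/8) —
256 x 64 for full-size input.

Training follows the standard conditional-GAN recipe at batch size 1:
binary cross-entropy adversarial loss (weight 1) with label smoothing
0.1 on the discriminator's real targets only, plus L1 and L2
reconstruction losses weighted 1000 and 100; Adam with learning rates
1e-4 (G) and 1e-5 (D), beta1 = 0.5, beta2 = 0.999, weight decay 1e-4.
After the main epoch budget, training continues for a selection window
during which the checkpoint with the lowest validation reconstruction
(weighted L1 + L2) loss is kept. ViT embedding width 256 with 8 heads
and an MLP at 4x width is the default full-scale setting; these were
fixed once as conventional transformer proportions, not tuned.

The networks are implemented directly in R on top of BLAS matrix
multiplication (im2col convolutions with precomputed index tables,
explicit backward passes, batch size fixed at 1). Every layer's
gradient is verified against central finite differences in the test
suite, which is the correctness anchor for the whole training loop.

# Evaluation and classification

NRMSE and NMAE divide by the *cohort-global* dynamic range of the
reference quantity, in percent. SSIM is the standard Wang formulation
(11 x 11 Gaussian window, sigma 1.5, K1 = 0.01, K2 = 0.03) and is
checked against scikit-image to 1e-6 on frozen fixtures. PSNR uses the
declared peak (1.0 for normalized data); identical inputs report Inf.
UMAP comparison z-scores the 25-D vectors with the original cohort's
moments, fits the embedding on the original vectors only, transforms
the synthetic ones into it (n_neighbors 15, min_dist 0.1, fixed
random_state), and reports the mean paired Euclidean distance. The
embedding is delegated to the `umap-learn` backend through the system
`python`; fit-then-transform was chosen over joint fitting because it
makes the original embedding independent of the synthetic cohort under
comparison.

Classification follows the two-step selection protocol: top-20 features
by mutual information (equal-frequency binned estimator with a
Miller-Madow bias correction so that finely-binned continuous features
are not favoured over coarse ones; the correction also restores the
property that a feature identical to the label ranks first), then an
elastic-net logistic wrapper (L1:L2 = 0.7:0.3, penalty 1/n) retaining
features whose absolute coefficient exceeds the mean absolute
coefficient. An RBF SVC is grid-searched over C in 1e-2..1e3 and gamma
in 1e-4..1e1 (6 x 6 log grid) by stratified 5-fold CV AUC on pooled
out-of-fold malignancy scores, refit on the full training set, and
evaluated on held-out lesions with 1000 bootstrap resamples (mean and
SD of accuracy/sensitivity/specificity/precision in percent; malignant
is the positive class; metrics undefined in a resample are skipped and
counted). Standardization moments, selection, and hyperparameters are
always fitted on training lesions only. The four experiment conditions
(original->original, synthetic->synthetic with its own selection,
synthetic->synthetic with the original's selected features,
original-train->synthetic-test) share one lesion-level split and one
bootstrap seed so that differences reflect provenance, not resampling.

# Problem sizes and numerical choices

Desk-scale defaults were chosen so the full test suite and the
acceptance script run in minutes on one CPU:

* simulated frames 512 x 128 (about 10 x 15 mm) for QUS studies, and
  288 x 62 raw frames for translator studies (the power-of-two crop
  rows-32 / cols+2 maps them to 256 x 64, exercising the same
  preprocessing path as the 2080 x 510 to 2048 x 512 full-scale
  geometry);
* smoke training: 32 pairs (8 lesions x 4 planes), 20 + 5 epochs, with
  narrow channel plans (`desk_generator_spec()`: base 4 filters /
  5 levels for the U-Net, embedding 32 / 4 heads for the ViTs) — the
  topology (level and block counts, patch size, stride plan) matches
  the full-scale architectures exactly;
* the classification study: 40 lesions x 4 planes, 50%-overlap windows,
  1000 bootstrap resamples.

Numerical details worth knowing: spectra live on a fixed 1024-point
FFT grid; dB conversions floor at the smallest positive double rather
than failing on all-zero windows (flagged); the degenerate form-factor
fit and the degenerate GLCM correlation are flagged, not silently
imputed; the attenuation filter interpolates between block-center
exponentials, so its residual is bounded by the block spacing; all
randomness flows from explicit integer seeds (scene seeds, training
seed fanning out to initialization, data order and dropout, split and
bootstrap seeds), making every artifact byte-reproducible.

# What the simulator does not emulate — and what that means for claims

No diffraction or elevational beam structure (scatterers map to their
nearest line; there is no lateral point-spread function beyond line
assignment), no nonlinear propagation, no time-gain compensation, no
electronic noise, no scan conversion, and 2-D rather than 3-D speckle
statistics. The lesion classes are separable by construction. A
passing end-to-end suite therefore demonstrates that the estimators,
translators, and the classification protocol are implemented correctly
and recover known ground truth under the stated acoustic model — it
does not demonstrate clinical-level performance on real breast data,
where class distributions overlap, the system response varies across
scanners, and ROI delineation is expert-driven. The paired-plane
acquisition is emulated as four discrete cross-sections per lesion; a
continuous sweep is not modelled.

# The reconstruction-loss floor

One property of the honest simulator deserves emphasis because it
shapes what smoke training can show. B-mode is an envelope image: the
carrier phase of the underlying RF is destroyed, and in a speckle
phantom that phase is random by construction. Conditional on the
B-mode frame, the distribution of each normalized RF sample is
(approximately) symmetric about the normalization midpoint, so the
optimal predictor under an L1/L2 reconstruction loss is essentially
the constant mid-level frame, and the validation loss has an
irreducible floor set by the speckle amplitude. Translators therefore
converge toward that floor rather than toward pixel-exact RF; how much
the logged validation loss *decreases* during smoke training depends
mostly on how far a variant's initialization sits above the floor. The
U-Net generator, whose sigmoid head and skip connections start it
close to the mid-level predictor, shows a much smaller relative
reduction than the ViT variants — an initialization geometry effect,
not a fidelity ranking. The test suite computes these floors and
reductions explicitly. On real clinical RF the same phase argument
applies locally, which is why evaluations there lean on
envelope-level and distribution-level metrics (SSIM, QUS features)
rather than raw reconstruction error.
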