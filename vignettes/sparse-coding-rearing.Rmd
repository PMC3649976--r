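---
title: "Sparse coding of binocular input and abnormal visual rearing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse coding of binocular input and abnormal visual rearing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(v1rear)
```

## The model

Simple cells in primary visual cortex (V1) are the first neurons to combine
input from the two eyes, and their receptive fields are strongly reshaped by
abnormal visual experience during the critical period: occluding one eye,
restricting experience to one orientation, or misaligning the eyes each
produces a characteristic change in ocular dominance and orientation tuning.
`v1rear` asks how much of that plasticity follows from a single principle —
that cortex learns a *sparse* code of its input — by training unsupervised
sparse-coding models on binocular image patches whose statistics mimic each
rearing condition, and measuring the resulting model receptive fields with
the same indices used in physiology.

The central learner is a product of Student-t experts. A whitened input
patch $x \in \mathbb{R}^k$ is assigned the unnormalized log density

$$\log p^*(x) = \sum_{i=1}^{M} -\alpha_i \log\!\left(1 +
\tfrac{1}{2}(w_i^\top x)^2\right),$$

where each expert $i$ has a receptive-field filter $w_i$ and a sparseness
exponent $\alpha_i > 0$. Heavy-tailed experts make typical projections
small but tolerate occasional large ones — a sparse response distribution.
With $M = k$ the model is equivalent to independent component analysis;
with $M > k$ (we default to 1.5-fold overcompleteness) the partition
function is intractable, so the model is trained by contrastive divergence
(CD): each gradient step contrasts the energy gradient at the data with the
gradient at samples obtained by a short Hamiltonian Monte Carlo (HMC) chain
started at the data. Two further learners, FastICA (`ica::icafast`) and
k-means on whitened patches, bracket the PoE results: all three acquire
sparse codes, so agreement across them attributes outcomes to sparsity
rather than to one algorithm's mechanics.

Before learning, patches are reduced to their leading $k$ principal
components and whitened; learned filters are mapped back to pixel space
through the right inverse of the whitening transform (the de-whitened
feature direction), and all receptive-field metrics are computed on those
pixel-space fields.

## Input: synthetic stereo images

The full-scale protocol samples 100,000 binocular patches (2 eyes × 25 × 25
pixels) from stereo photographs: five focal points per image, patches drawn
uniformly inside a 300-pixel square around each focal point. Because no
stereo photograph library ships with the package, `gen_naturalistic_stereo()`
synthesizes stereo pairs with the properties the analysis actually relies
on:

* a `1/f`-type radial power spectrum (log–log slope near −2, like natural
  scenes);
* sparse oriented structure: Gabor/edge elements with random orientation,
  log-uniform scale, and heavy-tailed (Laplace) amplitudes on a Gaussian
  `1/f` background (`element_gain = 1.2` sets the element-to-background RMS
  ratio), giving positive excess kurtosis of bandpass-filter responses;
* binocular geometry: each element is shifted horizontally in the right
  view by a Gaussian disparity (`disparity_scale`, default 2 px), so
  interocular correlation decays with disparity and decays *faster for
  vertically oriented structure* (horizontal structure is invariant to
  horizontal shifts) — the asymmetry that makes vertical-preferring model
  units more monocular;
* half-occlusion: a `mono_fraction` (default 0.15) of elements appears in
  one randomly chosen eye only, as at depth boundaries in real stereo
  images. Without this the synthetic "normal" condition is unrealistically
  binocular (every unit lands in the central ocular-dominance bin); with
  it, normal rearing yields the mid-bin spread seen in normally reared
  animals, while a flat, zero-disparity scene still yields exactly
  identical views.

What the generator does **not** emulate: photometric nonlinearities,
occlusion of extended surfaces, depth-dependent blur, and the full
scale-invariance of natural scenes. Tests passing on synthetic input
therefore demonstrate that the pipeline reacts correctly to the controlled
statistics, not that any particular quantitative value will transfer to a
given photograph library.

The sparse-rearing stimuli are simpler: every pixel of a patch is drawn
i.i.d. from Student-t with 2 degrees of freedom (sparse), Gaussian, or
uniform, standardized to zero mean and unit variance before mixing with
natural patches (`normalize_mean_var()`).

## Rearing conditions

`rearing_config()` encodes each condition; `build_training_set()` applies
it. Filters act at image level, before patch extraction.

| condition | manipulation | key parameter (default) |
|---|---|---|
| normal | none | — |
| stripe | oriented Gaussian filter, both eyes | `filter_strength` 4, 10% unfiltered |
| orthogonal | left eye at `stripe_orientation`, right at +90° | same |
| monocular | 150-px boxcar blur on the deprived eye | `deprived_eye = "right"` |
| alternating | per-patch fair coin picks the occluded eye | — |
| partial_monocular | share of normal patches among monocular ones | `binocular_fraction` |
| strabismic | independent per-eye patch offsets | — |
| noise_mixture | share of i.i.d. noise patches | `noise_fraction`, `noise_spec` |

Numerical choices worth stating:

* The oriented filter is a frequency-domain Gaussian on orientation angle,
  `exp(-(strength * sin(d))^2/2)` at angular distance `d`; `strength` is the
  reciprocal angular bandwidth. Effect sizes in stripe-rearing experiments
  depend on how severely experience was restricted (goggles vs striped
  drums), and the model's effect sizes likewise depend on the attenuation
  strength, so it is a configuration parameter; 4 gives strong but not
  total attenuation (2% passband at 45°).
* The 10% unfiltered share in stripe/orthogonal rearing (which prevents the
  retained principal subspace from collapsing onto the reared orientation)
  is enforced as an exact patch count, not in expectation.
* The boxcar occlusion is circular (FFT) convolution; with a 150-px kernel
  on 256-px images virtually no contrast survives within a 16-px patch.
* Mixtures interleave sources by a seeded shuffle; alternation uses a fair
  coin per patch, so eye counts are Binomial, not exactly equal.

## Receptive-field characterisation

For each unit's pixel-space field, split into per-eye halves
(`split_eyes()`):

* **Binocularity** $b = (\lVert w_L\rVert - \lVert w_R\rVert) /
  (\lVert w_L\rVert + \lVert w_R\rVert)$, binned on a 7-point
  ocular-dominance scale with boundaries at ±0.15, ±0.5, ±0.85. Bin 1
  holds strongly left-dominated fields, bin 7 strongly right-dominated
  ones, so under the default right-eye deprivation open-eye units occupy
  the low bins ("monocular fraction" = bins 1 or 7).
* **Grating tuning**: the phase-invariant quadrature response
  $r(\theta,f) = \sqrt{(w\cdot g_{\cos})^2 + (w\cdot g_{\sin})^2}$ on a
  1°-spaced orientation grid and spatial frequencies 0.02–0.5
  cycles/pixel in steps of 0.02.
* **Circular variance** $CV = 1 - |\sum_\theta r(\theta) e^{2i\theta}| /
  \sum_\theta r(\theta)$ of the orientation curve at the unit's preferred
  SF (max-over-orientation argmax, ties to the lower frequency). An eye is
  *oriented* when it is responsive (peak grating response at least 10% of
  the unit's binocular peak — a small floor that keeps the empty eye of a
  deprived unit, whose tiny residual weights have arbitrary CV, from being
  counted) and its CV is strictly below 0.6.
* **FWHM** of the orientation curve, with linear interpolation at the
  half-maximum crossings and circular topology on [0°, 180°).
* **Localization fraction**: the share of weights more than 1 SD from the
  filter mean — about 0.32 for diffuse Gaussian-like fields and of order
  `1/D` for fields concentrated on a few pixels, so *small* values signal
  the pixel-localized fields that sparse-noise rearing produces.

Orientation-preference histograms include only units with CV < 0.6 in at
least one eye, using the better-tuned responsive eye.

## Statistics and problem sizes

Every condition comparison uses two-sided tests: Kolmogorov–Smirnov on
pooled per-unit distributions against the normal baseline (raw p-values, no
multiplicity correction), paired t where the full-scale protocol uses it,
and Kruskal–Wallis for tuning-width contrasts. `repeat_conditions()` runs a
seed ladder (`base_seed + 0, 1, ...`; each seed drives image sampling *and*
model fitting) and reports means with standard errors; the full-scale
protocol uses 25 repeats.

The package's own test suite and acceptance script run at desk scale,
chosen so the whole suite completes in minutes on one core: 16×16 binocular
patches, $k = 48$ components, $M = 72$ PoE units, 8,000 patches, 60 CD
epochs for condition runs; 12×12 / $k=36$ / $M=54$ / 5,000 patches for
repeat-based checks; and a 10k/20k/40k-patch sweep (at a constant total
update count) for the training-set-size robustness check. At these sizes
every qualitative effect is large and stable across seeds; the printed
full-scale percentages are not expected to reproduce numerically at desk
scale or on synthetic imagery.

## Training defaults and degenerate inputs

CD uses learning rate 0.01 with `1/(1 + 2e-4 t)` decay, heavy-ball momentum
0.9, batch size 100, CD-1, and an HMC sampler (5 leapfrog steps) whose step
size adapts towards 90% acceptance; filters start i.i.d. Gaussian (sd 0.1)
and sparseness exponents at 1, learned on the log scale. An unadjusted
Langevin sampler is available. Non-finite parameters abort training with
the offending update index. Empty k-means clusters trigger a reseeded
restart; FastICA non-convergence returns the partial result with a warning.
Degenerate inputs (zero-variance patch sets, all-zero tuning curves,
both-eye-zero fields) raise errors rather than NaNs, except the constant
field in `localization_fraction()`, which returns 0 by convention.

## Known limitations

* No temporal dimension, colour, complex cells, topographic maps, or
  intrinsic (pre-eye-opening) activity: outcomes are asymptotic endpoints
  of input statistics, not developmental trajectories.
* The synthetic generator's parameters (element density, disparity scale,
  occlusion share) are plausibility choices, not fits to measured stereo
  statistics; quantitative population percentages depend on them.
* ICA is complete by construction, so conditions whose outcome depends on
  overcompleteness (notably recovery under partial monocular rearing) are
  weaker under ICA than under PoE or k-means.
* Desk-scale unit counts (72) make histogram-level statistics coarse;
  orderings and presence/absence effects are the reliable desk-scale
  readouts.
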