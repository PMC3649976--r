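# v1rear

Sparse-coding models of binocular V1 receptive-field development under
normal and abnormal visual rearing.

## The problem

Rearing experiments in cats — occluding one eye, alternating the occluded
eye, limiting experience to one orientation (the same or orthogonal in the
two eyes), misaligning the eyes — each reshape primary visual cortex
simple-cell receptive fields in a characteristic way: ocular-dominance
shifts, loss or biasing of orientation selectivity, loss of binocularity.
`v1rear` tests how much of this plasticity follows from a single coding
principle: that V1 learns a **sparse code** of its binocular input. The
package simulates each rearing condition as a statistical manipulation of
stereo image patches, learns sparse codes with three unsupervised
algorithms, and measures the resulting model receptive fields with the
indices used in physiology. It also implements a model-driven experimental
prediction: rearing on per-pixel sparse noise (Student-t, 2 df) should
produce radically abnormal, pixel-localized receptive fields even when
mixed with substantial natural input.

It is aimed at computational neuroscientists who want a tested, seedable
pipeline for "rearing-condition in, receptive-field statistics out"
experiments on sparse-coding models.

## The model

Binocular patches (2 eyes × P × P pixels) are reduced to their leading
`k` principal components and whitened. The central learner is an
overcomplete **product of Student-t experts**: a whitened patch `x` has
unnormalized log density

    log p*(x) = Σ_i  −α_i · log(1 + ½ (w_iᵀ x)²),   α_i > 0,

with `M = 1.5 k` experts, trained by **contrastive divergence** (CD-1,
Hamiltonian Monte Carlo negative phase, step size tuned to 90%
acceptance). FastICA (complete, `M = k`) and k-means centroids provide
algorithm-independence controls. Filters are back-projected to pixel space
through the right inverse of the whitening transform, and characterised
by:

* binocularity `b = (‖w_L‖ − ‖w_R‖)/(‖w_L‖ + ‖w_R‖)` on a 7-bin
  ocular-dominance scale (bin 1 left-monocular, bin 7 right-monocular,
  boundaries ±0.15/0.5/0.85);
* quadrature grating tuning over orientation (1° grid) and spatial
  frequency (0.02–0.5 cycles/pixel), circular variance (selective iff
  CV < 0.6), preferred orientation/SF, tuning FWHM;
* the fraction of weights more than 1 SD from the filter mean (small
  values = pixel-localized fields).

Because no stereo photograph library can be bundled, the package
ships a tested synthetic generator (`gen_naturalistic_stereo`): 1/f
background plus sparse oriented Gabor elements with per-element horizontal
disparities and a share of half-occluded (single-eye) elements, which
reproduces the interocular-correlation structure the analysis depends on.

## Worked example

```r
library(v1rear)

images <- gen_naturalistic_stereo(8, size = 256, seed = 101)
res <- run_condition(rearing_config("monocular", deprived_eye = "right"),
                     images = images, seed = 1,
                     n_patches = 8000, patch_side = 16, k = 48,
                     train_cfg = train_config(M = 72, n_epochs = 60, seed = 1))
print(res)
#> <condition_result: monocular / poe, seed 1, 72 units>
#>   OD histogram: 52 19 1 0 0 0 0
#>   monocular fraction 0.72 | oriented L 0.50 R 0.00
```

Reading: with the right eye occluded (boxcar-filtered), all 72 learned
units land in ocular-dominance bins 1–3 (left/open-eye dominated, none
beyond the central bin), 72% are fully monocular, half the units are
orientation-selective through the open eye and none through the deprived
eye — the monocular-deprivation outcome. Swap in
`rearing_config("strabismic")` or
`rearing_config("noise_mixture", noise_fraction = 0.75, noise_spec =
noise_spec("student_t_df2"))` to reproduce the other conditions, or use
`repeat_conditions()` for seed-laddered repeats with SEMs and KS tests
against the normal baseline.

The `analysis/` directory holds the numbered workflow
(`01_generate_stimuli.R` … `05_sparse_noise.R`) that generates stimuli,
runs the condition sweeps, and writes tables and receptive-field mosaics
under `results/`.

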