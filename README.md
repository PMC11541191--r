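# mitoquant

Quantification of mitochondria in multi-channel 3D (+time) fluorescence
z-stacks of small dividing cells, built around one observation: **global
threshold-based segmentation is invariant under photobleaching**. Every
acquisition bleaches the fluorophore, so raw integrated fluorescence decays
(≈1.75% per minute for a matrix-targeted GFP), yet a global threshold
computed from the image's own grey-value histogram scales along with the
signal — for an exact multiplicative decay $s$, the Isodata threshold
satisfies $t(sI) = s\,t(I)$ and the foreground voxel set is unchanged — so
segmented mitochondrial volumes and areas are directly comparable across
timepoints without any bleaching correction.

The package is aimed at quantitative microscopists who want that workflow
as tested, scriptable code, together with a ground-truthed synthetic-data
generator to validate it:

* **Preprocessing** — per-slice rigid z-stack alignment with transform
  reuse across channels (`align_stack()`, `apply_transforms()`), spectral
  bleedthrough subtraction (`subtract_bleedthrough()`), cropping
  (`crop_roi()`), Richardson–Lucy deconvolution with theoretical
  Born–Wolf PSFs (`rl_deconvolve()`, `theoretical_psf()`).
* **Segmentation** — Isodata / legacy-ImageJ-Default / Otsu global
  thresholds (`global_threshold()`), an Imaris-Surface-like chain with
  Gaussian background elimination (`imaris_like_surface()`), polygonal ROI
  masking (`mask_outside_rois()`), 2D/3D object quantification with
  volumes, areas and sphericity (`measure_objects()`).
* **Histogram analytics** — fixed vs relative 256-class grey-value
  distributions (`grey_histogram()`), log–log frequency regression with an
  extra-sum-of-squares F-test against slope 1
  (`log_frequency_regression()`), fitted-curve area contrasts
  (`delta_auc()`), threshold class positioning
  (`threshold_class_position()`).
* **Time series** — integrated-density traces in cell ROIs, linear decay
  fits, normality-gated one-sample invariance tests, threshold-algorithm
  comparisons (`integrated_density_trace()`, `fit_decay()`,
  `invariance_test()`, `compare_threshold_algorithms()`).
* **Synthetic data** — tubular mitochondria (random-walk capsules) inside a
  dividing ellipsoidal cell, membrane+chromatin red channel, 8% channel
  bleedthrough, linear per-acquisition photobleaching with capped lognormal
  fluctuations, per-slice motion jitter, PSF blur, Poisson+read noise, and
  exact voxel-level ground truth (`generate_scene()`,
  `simulate_division()`, `simulate_timeseries()`,
  `simulate_division_batch()`).
* **Geometric optics** — the Snell's-law chain for longitudinal spherical
  aberration under refractive-index mismatch and Rayleigh resolution in
  pixels (`refraction_chain()`, `longitudinal_shift_at_depth()`,
  `rayleigh_radius_px()`).

## Worked example

```r
library(mitoquant)

## geometric optics: aberration of the imaging geometry
print(refraction_chain(optical_geometry(), rounded = TRUE))
#> Optical geometry (oil/glass/specimen RI: 1.518 / 1.52 / 1.37 )
#>   r_max 198.5 um, OL-APP 310 um, CG-APP 2.000 um
#>   theta 32.63 deg, theta_r 36.81 deg
#>   H 2.381 um, L 1.286 um, H' 2.137 um
#>   CG-ACT 1.710 um, LS 0.290 um  (rounded mode)

## one synthetic division, bleached 13 acquisitions at 1.75%/min
sc   <- generate_scene(scene_spec(rng_seed = 1))
post <- simulate_division(sc)
psf  <- theoretical_psf(510, shape = c(7L, 15L, 15L))
sim  <- simulate_timeseries(sc, bleach_schedule(), psf = psf,
                            noise = noise_model(), rng_seed = 1,
                            materialise = c(1L, 13L), post_scene = post)
g_meta <- subtract_bleedthrough(sim$stack[1, 2, , , ], sim$stack[1, 1, , , ], 0.08)
g_post <- subtract_bleedthrough(sim$stack[2, 2, , , ], sim$stack[2, 1, , , ], 0.08)
print(global_threshold(g_meta, "isodata"))
#> Global threshold (isodata): 932  [14154 foreground voxels]
print(global_threshold(g_post, "isodata"))
#> Global threshold (isodata): 742.6  [14009 foreground voxels]
```

The applied bleach multiplier ratio in this run is 0.790: the threshold tracks it
(ratio 0.797) while the segmented quantity barely moves (ratio 0.990) —
fluorescence decayed by a fifth, the measured mitochondrial quantity by
one percent. `simulate_division_batch()` repeats this over seeded
replicates and `run_pipeline()` writes the measurement table, invariance
test report and provenance log to disk.

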