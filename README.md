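# myxopix

Quantification of *Myxococcus xanthus* aggregation and rippling from
grayscale time-lapse microscopy, including phase-contrast → fluorescence
image translation with a two-head conditional GAN.

## Why

Starving *M. xanthus* swarms aggregate into fruiting bodies connected by
cell streams; during predation they form traveling density waves
(ripples). Fluorescence microscopy reports cell density faithfully —
aggregates are bright and uniform, streams visible after histogram
equalization — but needs engineered fluorophores and phototoxic
illumination. Phase contrast is label-free but its halo and shade-off
artifacts decorrelate intensity from density, distorting aggregate
segmentation and hiding streams and weak wave crests. `myxopix`
implements the analysis stack for both modalities and the model that
bridges them.

## What is inside

* **Preprocessing** — `rescale_image()` (Lanczos-3), `clahe_normalize()`
  (contrast-limited adaptive histogram equalization),
  `hist_equalize()` (global CDF equalization), `scale_to_range()`.
* **Segmentation** — `segment_aggregates()`: difference-of-Gaussians
  bandpass, Otsu threshold (maximizing between-class variance
  σ²_b(t) = w₀w₁(μ₀ − μ₁)²), morphological refinement.
* **Aggregate comparison** — `match_aggregates()` (greedy
  nearest-centroid, one-to-one, rejecting non-overlapping or >2×-area
  pairs), `pixel_confusion()` with precision = TP/(TP+FP) and
  recall = TP/(TP+FN).
* **Similarity metrics** — `mse()` (MSE(r,s) = Σ(r−s)²/NₗN_w ∈ [0,4] on
  [−1,1] images) and global `ssim()`
  ((2μᵣμₛ+c₁)(2σᵣₛ+c₂) / ((μᵣ²+μₛ²+c₁)(σᵣ²+σₛ²+c₂)), c₁ = 0.004,
  c₂ = 0.0036), calibrated into an equivalent pixel shift
  (`equivalent_shift()`) and an equivalent Gaussian noise level
  σ = √MSE (`equivalent_noise_sigma()`).
* **Ripple wavelength** — `ripple_wavelength()`: 2-D DFT, amplitudes
  averaged over integer-radius annuli, window-3 moving average, peak
  wave-number k₁ above a cutoff k_min = ⌈L/λ_max⌉ (λ_max = 84 µm, so
  k_min = 6 for a 504 µm field), λ = L/k₁.
* **pix2pixHD-HE-style GAN** — `train_gan()`, `translate_image()`,
  `resume_training()`: a shared generator trunk branching into a
  normalized-fluorescence head and a histogram-equalized head, one
  multi-scale patch discriminator per head, LSGAN + feature-matching
  losses, linear decay of the first head's loss weight over the first
  500 epochs, checkpoint resume for transfer learning. Implemented as a
  compact self-contained CPU conv-net framework with
  finite-difference-verified backpropagation.
* **Synthetic scenes** — `generate_aggregate_scene()` /
  `generate_ripple_scene()` produce paired phase-like and
  fluorescence-like images with exact ground truth (masks, aggregate
  tables, wavelengths), so the whole stack is testable without data.

A thin CLI covering all of the above ships in `inst/cli/myxopix`
(subcommands `simulate`, `preprocess`, `segment`, `compare`, `metrics`,
`ripple`, `train`, `translate`).

## Worked example

```r
library(myxopix)

## a synthetic development scene with known ground truth
params <- aggregate_scene_params(field_size_px = 192, n_aggregates = 4,
                                 seed = 7)
scene <- generate_aggregate_scene(params)

## segment the fluorescence-like channel and score it against the truth
mask <- segment_aggregates(scene$fluor_like)
pixel_confusion(scene$truth$mask, mask)
#> <mx_confusion> TP 1445  FP 34  TN 35367  FN 18  (precision 0.977, recall 0.988)

match_aggregates(scene$truth$aggregates, label_aggregates(mask))
#> <mx_match> 4 pairs, 0 ref / 0 test unmatched
#>   displacement 0.12 um (mean), area ratio 1.026 (mean)

## ripple wavelength from a 504 um field with a 42 um wave
ripple <- generate_ripple_scene(ripple_scene_params(wavelength_um = 42,
                                                    seed = 1))
ripple_wavelength(ripple$fluor_like)
#> <mx_ripple> k1 = 12, lambda = 42.00 um (L = 504 um, kmin = 6, k0 = 1)
```

All four truth aggregates are recovered (pixel precision 0.977, recall
0.988), their centroids sit within 0.12 µm of the truth on average with
areas within ~3%, and the spectral estimator returns the 12th wave-number
of the 504 µm field — exactly the 42 µm wavelength that was generated.
The `k0 = 1` diagnostic is the global spectral peak: a large-scale
intensity gradient that the k ≥ 6 cutoff exists to ignore.

Training a desk-scale translation model on synthetic pairs:

```r
pairs <- lapply(1:8, function(i) {
  sc <- generate_aggregate_scene(aggregate_scene_params(
    field_size_px = 64, n_aggregates = 3, radius_range_px = c(6, 10),
    seed = i))
  list(phase       = scale_to_range(sc$phase_like)$values,
       fluor_clahe = scale_to_range(clahe_normalize(sc$fluor_like,
                                                    tile_px = 32))$values,
       fluor_he    = scale_to_range(hist_equalize(sc$fluor_like))$values)
})
model <- train_gan(pairs,
                   gen_cfg = generator_config(base_width = 8,
                                              n_downsample = 2,
                                              n_resblocks = 2),
                   disc_cfg = discriminator_config(base_width = 8),
                   train_cfg = train_config(lr = 1e-3, epochs = 10,
                                            seed = 3),
                   steps = 50)
out <- translate_image(model, mx_image(pairs[[1]]$phase,
                                       intensity_range = c(-1, 1)))
```

`out$syn_fluor` and `out$syn_fluor_he` are the two synthesized channels in
[−1, 1]; `model$log` records every loss term per step.

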