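---
title: "Quantifying aggregation and rippling in M. xanthus images: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying aggregation and rippling in M. xanthus images: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Starving *Myxococcus xanthus* swarms self-organize into fruiting-body
aggregates connected by streams of moving cells; during predation they form
traveling density waves (ripples). Time-lapse microscopy captures both
behaviors, but the two common modalities disagree about what they show.
Fluorescence intensity tracks local cell density, so aggregates appear as
bright, fairly uniform mounds and streams as intermediate-intensity
channels. Phase contrast has better contrast and needs no fluorophore, but
its halo and shade-off artifacts decorrelate intensity from density:
aggregate interiors carry dark bands, boundaries carry bright rims, and
streams are invisible.

`myxopix` implements the computational stack for working with such data:

* preprocessing (Lanczos rescaling, CLAHE, histogram equalization, range
  scaling);
* aggregate segmentation (difference-of-Gaussians bandpass, Otsu threshold,
  morphological refinement);
* aggregate matching and pixel-level precision/recall between two
  segmentations;
* global MSE/SSIM image similarity with perturbation-equivalence
  calibrations (equivalent pixel shift, equivalent Gaussian noise);
* ripple wavelength estimation from radially binned 2-D Fourier spectra;
* a two-head conditional GAN (pix2pixHD-HE style) translating
  phase-contrast into synthesized fluorescence channels;
* a synthetic scene generator that provides ground truth for all of the
  above.

## Synthetic scenes and what they do (not) emulate

No public imaging dataset accompanies this problem, so every quantitative
test in the package runs against generated scenes with known ground truth.

`generate_aggregate_scene()` renders aggregates with a plateaued radial
profile: flat at `aggregate_intensity` over the inner 80% of the radius,
then a half-cosine falloff to zero over the outer 20%. The half-maximum
support of this profile is a circle at 0.9 R, which defines the
ground-truth mask unambiguously. Streams join each aggregate to its
nearest neighbor as 3-px-wide segments at `stream_intensity` and are
deliberately excluded from the mask — they are interaggregate features.
Centers are rejection-sampled with a minimum spacing of the sum of radii
plus 4 px (capped at 1000 attempts per aggregate) so mask components map
one-to-one onto the aggregate list. The phase-contrast rendering of the
same scene has a mid-gray background, a bright rim of width
`halo_width_px`, sinusoidal interior dark bands of period
`shade_band_period_px`, no stream signal, and doubled noise — the three
artifacts that make phase contrast hard to segment. Noise is additive
Gaussian, clipped to `[0, 1]` after addition.

`generate_ripple_scene()` renders a plane sinusoid: the fluorescence
channel is `amplitude * (1 + sin(2*pi*(x cos phi + y sin phi) *
pixel_size/lambda)) / 2` plus noise; the phase channel is the same wave at
30% of the contrast with three times the noise, imitating the weak
visibility of wave crests in phase contrast. Wavelengths below twice the
pixel size are rejected (Nyquist). Coordinates are zero-based, so a field
of `L` pixels holds exactly `L * pixel_size / lambda` periods.

Defaults (256-px aggregate fields with 8 aggregates of radius 8–16 px at
~2% noise; 504-px ripple fields at 46 µm wavelength) were chosen once as
typical of developmental time-lapse data at ~1 µm/px and are exposed in the
parameter objects rather than hard-coded.

What the generator does **not** emulate: optics (no point-spread function,
no shot noise, no illumination gradients), cell-scale texture, aggregate
shape irregularity, and temporal correlation (movie frames are generated
independently). Passing tests therefore demonstrate algorithmic
correctness on idealized geometry, not performance on real microscopy;
parameters such as the segmentation sigmas will need re-tuning on real
data.

## Preprocessing

`rescale_image()` is separable Lanczos-3 (windowed sinc, a = 3)
resampling. When downscaling, the kernel is widened by `1/factor` so it
acts as an anti-aliasing low-pass; edges are replicated; the kernel weights
are zeroed exactly at integer offsets so `factor = 1` is the identity.
Output is clipped back into the image's intensity range because windowed
sinc kernels overshoot near edges. The physical pixel size is divided by
the factor.

`clahe_normalize()` wraps tile-based contrast-limited adaptive histogram
equalization (clip limit 2, ~64 px tiles by default — common defaults, both
exposed). The input is min–max normalized first, which makes the operation
invariant to affine intensity rescaling, and padded by edge replication so
the tile grid divides the image exactly. A constant image is returned
unchanged; there is no contrast to equalize.

`hist_equalize()` is global histogram equalization through the empirical
CDF on 256 bins (8-bit-equivalent resolution) spanning the image's
declared intensity range. The mapping is monotone and idempotent up to bin
quantization, and it is *not* invertible — which is exactly why the GAN
below needs a dedicated histogram-equalized output head rather than
post-hoc equalization of its normalized output.

Internally everything lives in `[0, 1]`; `scale_to_range()` converts to
`[-1, 1]` only at the model/metrics boundary, because the similarity-metric
constants and the tanh output layer assume that range.

## Segmentation

Aggregates are brighter than their surroundings, so segmentation is
bandpass + threshold + morphology:

1. **Bandpass**: difference of Gaussians, `blur(sigma_low) -
   blur(sigma_high)` with defaults 2 px and 30 px. The blur is a separable
   truncated-at-3-sigma Gaussian with replicated edges, so the response to
   a constant image is exactly zero. The response is *not* clipped.
2. **Otsu threshold** on the bandpass response min–max normalized to
   `[0, 1]` (making the whole pipeline invariant to affine rescaling of
   the input), over a 256-bin histogram. Candidate thresholds are interior
   bin edges; ties break toward the lowest maximizing threshold. The
   implementation is cross-checked in the tests against an exhaustive
   between-class-variance search.
3. **Morphology**, in a fixed documented order: opening with a disc of
   radius 3 px, hole filling, removal of components below 64 px, closing
   with the same disc. The order matters (opening before hole filling
   prevents noise bridges from sealing spurious holes) and is asserted by
   tests; hole filling never removes foreground and speck removal never
   adds it.

Whether to threshold the bandpass response or the raw intensities is
genuinely open; the bandpass response is the default because it removes
slow background drift, and `seg_config(threshold_on = "raw")` provides the
alternative.

Connected components use 8-connectivity (diagonal contact joins), computed
as a 4-connected labeling pass followed by union-find merging of labels
that touch diagonally.

## Aggregate comparison

`match_aggregates()` ranks all cross pairs by centroid distance (ties by
lower reference id, then lower test id) and assigns greedily one-to-one. A
candidate pair is accepted only if the pixel sets overlap and neither
aggregate is more than twice the other's area; the size rule is applied
symmetrically. Rejected aggregates stay available for later candidates and
otherwise end up unmatched. Greedy nearest-centroid assignment is the
simplest scheme consistent with matching "the same aggregate" by shortest
centroid distance; a globally optimal assignment would differ only when
aggregates are densely packed relative to their movement, which the
minimum-spacing rule of the generator avoids in tests. Area ratios are
reported as test/reference.

`pixel_confusion()` labels every pixel TP/FP/TN/FN against the reference
mask (white/orange/black/red palette), and `precision()` / `recall()` are
the standard ratios; a zero denominator yields `NA`, never 0.

## Image similarity and its calibration

`mse()` is the plain mean squared difference; on `[-1, 1]` images it lies
in `[0, 4]`, 0 iff identical. `ssim()` is the *global* structural
similarity statistic — single means, variances, covariance over the whole
image, not a windowed mean — with constants `c1 = 0.004`, `c2 = 0.0036`
for `[-1, 1]` data. Two remarks:

* the formula is negative for sufficiently anti-correlated images (the
  covariance term `2*cov + c2` goes negative); its true minimum is not 0.
  The tests pin the closed-form value for `s = -r`.
* `c1 = 0.004` is an order of magnitude larger than the conventional
  `(0.01 * range)^2 = 0.0004`. Both constants are arguments, so the
  conventional values are one call away; the defaults follow the reference
  analysis this package reproduces.

Raw MSE/SSIM numbers are hard to interpret, so they are calibrated into
perturbations of the real image that would produce the same value.
`equivalent_shift()` shifts the image by integer pixel offsets (averaged
over the four axis directions, computed on the overlapping region only —
no wraparound, no fabricated padding), and returns the smallest shift at
which the metric crosses the observed value; if no shift up to half the
image side crosses it, the result is flagged capped. The four-direction
average is implementation policy; a single direction would make the
calibration depend on scene anisotropy. `equivalent_noise_sigma()` uses
the closed form: additive i.i.d. `N(0, sigma)` noise has expected MSE
`sigma^2`, so `sigma = sqrt(MSE)`, reported as a percentage of the
intensity span (2 for `[-1, 1]`). Clipping at the range boundary is not
modeled; the closed form is validated by seeded Monte Carlo in the tests.
Movie-level reports average per-frame values.

## Ripple wavelength

`radial_spectrum()` computes the centered 2-D DFT magnitude and averages
it over integer-radius annuli `[k, k + 1)` about the DC bin — the exact
pixel sets, no interpolation. A plane wave with `p` periods across the
field puts its spectral mass at radius `p`. `smooth_profile()` applies a
centered window-3 moving average (endpoints over their two available
neighbors) to suppress bin-to-bin noise.

`detect_wavelength()` selects the wave-number `k1` above a low-frequency
cutoff and reports `lambda = L / k1` for a physical field side `L`. The
cutoff generalizes as `kmin = ceiling(L / lambda_max)` with
`lambda_max = 84` µm, the largest biologically plausible ripple
wavelength — for a 504 µm field this gives `kmin = 6`. Peaks below the
cutoff (`k0`, recorded for diagnostics) reflect large-scale intensity
gradients, not rippling.

Peak selection needed one careful choice. The smoothed profile *locates*
the peak (global maximum by default; a first-local-maximum policy is
available), but the reported bin is *refined* to the largest unsmoothed
amplitude within the 3-bin smoothing window around that location. Without
refinement the moving average smears a narrow spectral line into three
nearly equal bins, and the choice among them would be decided by noise (or
by floating-point ties on noiseless data); with it, a sinusoid of integer
period count `p` is always reported at exactly `k1 = p`, and a fractional
period count at its nearest bin, `lambda = L / round(L / lambda_true)`.
Non-square inputs are center-cropped to a square, since `lambda = L / k`
assumes an `L x L` field. An all-zero spectrum above the cutoff returns a
no-ripple sentinel rather than a number.

## The two-head conditional GAN

The translation model is a pix2pixHD-family conditional GAN with one
shared encoder/residual trunk and **two** decoder heads: one trained
against CLAHE-normalized fluorescence and one against histogram-equalized
fluorescence. The second head exists because equalization is not
invertible: a model trained only on normalized targets cannot be
equalized after the fact into a faithful stream image, so the stream
information must be a training target of its own.

Architecture (configurable; defaults in parentheses follow the pix2pixHD
lineage): 7×7 input convolution to `base_width` (64) features, `n`
stride-2 downsampling stages (4), residual blocks (9) at the bottleneck,
`n` nearest-neighbor-upsample + 3×3 convolution decoder stages, and a 7×7
output convolution with tanh per head. Instance normalization and ReLU
throughout. Branch candidates sit at decoder-stage boundaries: candidate 0
duplicates the whole decoder, candidate `n` only the output convolution;
candidate 2 is the default, giving each head its own final decoder stages.
Earlier branching strictly increases the parameter count (asserted by
exact layer arithmetic in the tests).

Each head has its own multi-scale PatchGAN discriminator (2 scales, 3
conv blocks, LSGAN objective) conditioned on the concatenation of the
input phase image with that head's channel, and a feature-matching loss
(weight 10) over discriminator activations. A perceptual VGG loss is
deliberately omitted: these are single-channel microscopy images and no
pretrained grayscale backbone is assumed. The generator loss is

```
L_G(epoch) = w1(epoch) * (adv + fm)_CLAHE + w2 * (adv + fm)_HE
```

with `w2` constant and `w1` decaying linearly over the first
`g1_decay_epochs` (500) epochs. The reference schedule names two loss
weights G1 and G2 without defining them structurally; this package
interprets them as the two head weights (CLAHE head decayed, HE head
constant), which matches the two-discriminator design, and makes the
decay endpoint explicit (default floor 0.5 — decaying to zero would
silence the normalized head entirely). Swapping the interpretation is a
matter of exchanging the two weights in `train_config()`.

Training uses Adam (beta1 = 0.5) at the reference learning rate 5e-5 for
2000 epochs at full scale. Checkpoints embed parameters, optimizer state,
epoch counter and an architecture signature; `resume_training()` continues
from a checkpoint on a new dataset — the transfer-learning route for
adapting an aggregation-trained model to rippling with a fraction of the
epochs — and refuses architecture mismatches. Resuming with zero steps
reproduces parameters bit-exactly.

### Implementation and desk-scale choices

The network stack is a compact, self-contained CPU framework: im2col
convolutions evaluated as BLAS matrix products, nearest-neighbor
upsampling, instance normalization, LSGAN and feature-matching losses, and
Adam — all with hand-written backward passes verified against finite
differences in the test suite (agreement to ~1e-5 relative at double
precision). Training is deterministic given the seed: initialization is
the only stochastic element, and batches are taken cyclically.

The test and example configuration is deliberately tiny — 64×64 images,
`base_width` 8, 2 downsampling stages, 2 residual blocks, 8 training
pairs, tens of optimizer steps at learning rate 1e-3 — sized so a training
smoke run finishes in well under a minute on one CPU while still
exercising every loss path, both heads, both discriminators and the
checkpoint machinery. These runs demonstrate that the adversarial
machinery optimizes (the generator objective decreases over 50 steps) and
that gradients from the HE head reach the shared trunk; they say nothing
about image quality at publication scale, which requires the full
configuration on GPU-class hardware and real training movies.

## Numerical conventions

* Degenerate inputs: constant images pass through CLAHE unchanged, error
  in Otsu (no histogram to split), produce exactly-zero bandpass
  responses, and cap the equivalent-shift search.
* Ties: Otsu breaks toward the lowest maximizing threshold; matching
  breaks by lower reference id then lower test id; spectral peaks break
  toward smaller `k` after raw-amplitude refinement.
* All random components (scene generation, initialization) take explicit
  integer seeds and restore the caller's RNG state.
* Instance-norm epsilon 1e-5; Adam epsilon 1e-8, beta = (0.5, 0.999).

## Known limitations

* The synthetic scenes are geometric idealizations (see above); none of
  the quantitative guarantees transfer automatically to real movies.
* Segmentation has no watershed splitting: touching aggregates merge into
  one component.
* Wavelength estimation assumes a dominant single spatial frequency;
  superposed wave trains of similar power yield whichever ring is
  (marginally) stronger.
* The GAN framework is CPU-bound R; it is suitable for desk-scale
  experiments and correctness work, not for 2000-epoch training at native
  resolution.
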