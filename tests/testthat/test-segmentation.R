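test_that("bandpass response of a constant image is exactly zero", {
  img <- mx_image(matrix(0.42, 64, 64))
  out <- bandpass_filter(img, seg_config(low_sigma_px = 2, high_sigma_px = 10))
  expect_true(all(out$values == 0))
})

test_that("bandpass matches a direct difference-of-Gaussians convolution", {
  set.seed(8)
  v <- matrix(0, 64, 64)
  v[28:36, 28:36] <- 1   # blob between the two sigma scales
  v <- v + matrix(rnorm(64 * 64, 0, 0.01), 64, 64)
  cfg <- seg_config(low_sigma_px = 2, high_sigma_px = 8)
  mine <- bandpass_filter(mx_image(clip01(v)), cfg)$values
  oracle <- naive_gauss_blur(clip01(v), 2) - naive_gauss_blur(clip01(v), 8)
  interior <- 20:44
  expect_gt(stats::cor(as.vector(mine[interior, interior]),
                       as.vector(oracle[interior, interior])), 0.999)
  # qualitative contract: positive at the blob, ~0 far away
  expect_gt(mine[32, 32], 0)
  expect_lt(abs(mine[5, 5]), 0.02 * max(abs(mine)))
})

test_that("bandpass strongly attenuates pixel-scale checkerboard noise", {
  n <- 64
  v <- outer(seq_len(n), seq_len(n), function(i, j) (i + j) %% 2)
  out <- bandpass_filter(mx_image(v), seg_config(low_sigma_px = 2,
                                                 high_sigma_px = 10))$values
  amp_in <- (max(v) - min(v)) / 2
  # evaluate away from the replicated border, which breaks the alternation
  interior <- out[7:58, 7:58]
  amp_out <- (max(interior) - min(interior)) / 2
  expect_lt(amp_out, 0.1 * amp_in)
})

test_that("sigma ordering is enforced", {
  expect_error(seg_config(low_sigma_px = 5, high_sigma_px = 2), "smaller")
})

test_that("Otsu separates a perfectly bimodal image", {
  v <- matrix(c(rep(0, 50), rep(1, 50)), 10, 10)
  thr <- otsu_threshold(v)
  expect_gt(thr, 0)
  expect_lt(thr, 1)
  expect_true(all(v[v > thr] == 1) && all(v[v <= thr] == 0))
})

test_that("Otsu equals the exhaustive between-class-variance maximizer", {
  # Gaussian mixture instance from the module contract
  set.seed(123)
  v <- c(rnorm(3000, 0.2, 0.05), rnorm(7000, 0.8, 0.05))
  expect_equal(otsu_threshold(v, 256), otsu_brute_force(v, 256))

  # three-level image with asymmetric weights
  v3 <- c(rep(0, 45), rep(0.5, 10), rep(1, 45))
  expect_equal(otsu_threshold(v3, 256), otsu_brute_force(v3, 256))

  # randomized property over mixed histogram shapes
  for (seed in 1:25) {
    set.seed(seed)
    w <- runif(1, 0.2, 0.8)
    n <- 2000
    v <- c(rnorm(round(w * n), runif(1, 0.1, 0.4), runif(1, 0.02, 0.1)),
           rnorm(n - round(w * n), runif(1, 0.6, 0.9), runif(1, 0.02, 0.1)))
    expect_equal(otsu_threshold(v, 128), otsu_brute_force(v, 128))
  }
})

test_that("Otsu errors on a constant image", {
  expect_error(otsu_threshold(matrix(0.5, 4, 4)), "constant")
})

test_that("refinement fills holes, drops specks, shaves spikes", {
  cfg <- seg_config(min_object_px = 20, se_radius_px = 2)
  # disk with an interior hole
  n <- 41
  r <- sqrt(outer((1:n) - 21, (1:n) - 21, function(a, b) a^2 + b^2))
  disk <- r <= 15
  holed <- disk & !(r <= 4)
  out <- refine_mask(mx_mask(holed), cfg)
  expect_true(all(out$values[r <= 4]))

  # isolated 2-px speck below min_object_px
  speck <- matrix(FALSE, 41, 41); speck[3, 3:4] <- TRUE
  expect_false(any(refine_mask(mx_mask(speck), cfg)$values))

  # 1-px boundary spike on a large blob: removed, area nearly unchanged
  spiked <- disk
  spiked[21, 37:40] <- TRUE
  ref <- refine_mask(mx_mask(spiked), cfg)
  expect_false(any(ref$values[21, 39:40]))
  expect_lt(abs(sum(ref$values) - sum(disk)) / sum(disk), 0.05)
})

test_that("hole filling never removes foreground; speck removal never adds", {
  set.seed(31)
  for (i in 1:5) {
    m <- matrix(runif(40 * 40) > 0.6, 40, 40)
    filled <- as.matrix(EBImage::fillHull(m * 1)) > 0
    expect_true(all(filled[m]))
    dropped <- myxopix:::drop_small_components(m, 10)
    expect_true(all(m[dropped]))
  }
})

test_that("full segmentation recovers noiseless synthetic scenes", {
  sc <- generate_aggregate_scene(aggregate_scene_params(
    n_aggregates = 3, background_noise_sigma = 0, field_size_px = 160,
    seed = 17))
  seg <- segment_aggregates(sc$fluor_like)
  aggs <- label_aggregates(seg)
  expect_length(aggs, 3)
  conf <- pixel_confusion(sc$truth$mask, seg)
  expect_gte(precision(conf), 0.95)
  expect_gte(recall(conf), 0.95)
})

test_that("pure noise segments to an empty mask", {
  set.seed(99)
  img <- mx_image(matrix(pmin(pmax(rnorm(128 * 128, 0.5, 0.05), 0), 1),
                         128, 128))
  # no noise-induced component is as large as a real aggregate at this
  # scale, so a size floor of half the field empties the mask
  seg <- segment_aggregates(img, seg_config(min_object_px = 8000))
  expect_false(any(seg$values))
})

test_that("fluorescence-like scenes segment with at least phase-like recall", {
  sc <- generate_aggregate_scene(aggregate_scene_params(
    n_aggregates = 4, field_size_px = 160, seed = 23))
  cfg <- seg_config()
  rec_f <- recall(pixel_confusion(sc$truth$mask,
                                  segment_aggregates(sc$fluor_like, cfg)))
  rec_p <- recall(pixel_confusion(sc$truth$mask,
                                  segment_aggregates(sc$phase_like, cfg)))
  expect_gte(rec_f, rec_p)
})

test_that("segmentation is invariant under affine intensity rescaling", {
  sc <- generate_aggregate_scene(aggregate_scene_params(
    n_aggregates = 3, field_size_px = 128, seed = 13))
  a <- segment_aggregates(sc$fluor_like)
  shifted <- mx_image(0.25 + 0.5 * sc$fluor_like$values,
                      sc$fluor_like$pixel_size_um, c(0, 1))
  b <- segment_aggregates(shifted)
  expect_identical(a$values, b$values)
})
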