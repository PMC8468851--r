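#' Segmentation configuration
#'
#' Parameters of the aggregate segmentation pipeline: a difference-of-
#' Gaussians bandpass (small sigma removes pixel-scale noise, large sigma
#' removes slowly varying background), Otsu thresholding, and morphological
#' refinement.
#'
#' @param low_sigma_px Small Gaussian sigma (high-frequency cut), pixels.
#' @param high_sigma_px Large Gaussian sigma (low-frequency cut), pixels;
#'   must exceed `low_sigma_px`.
#' @param min_object_px Foreground components smaller than this many pixels
#'   are removed.
#' @param se_radius_px Radius of the disc structuring element used for
#'   opening/closing.
#' @param otsu_bins Histogram bins for Otsu thresholding.
#' @param threshold_on Threshold the `"bandpass"` response (default) or the
#'   `"raw"` intensities.
#' @return A list of class `mx_seg_config`.
#' @export
seg_config <- function(low_sigma_px = 2, high_sigma_px = 30,
                       min_object_px = 64L, se_radius_px = 3L,
                       otsu_bins = 256L,
                       threshold_on = c("bandpass", "raw")) {
  stopifnot(low_sigma_px > 0, high_sigma_px > 0, min_object_px >= 0,
            se_radius_px >= 1, otsu_bins >= 2)
  if (low_sigma_px >= high_sigma_px)
    stop("`low_sigma_px` must be smaller than `high_sigma_px`")
  structure(list(low_sigma_px = low_sigma_px, high_sigma_px = high_sigma_px,
                 min_object_px = as.integer(min_object_px),
                 se_radius_px = as.integer(se_radius_px),
                 otsu_bins = as.integer(otsu_bins),
                 threshold_on = match.arg(threshold_on)),
            class = "mx_seg_config")
}

#' Difference-of-Gaussians bandpass filter
#'
#' `blur(img, low_sigma) - blur(img, high_sigma)`: removes the DC/low-
#' frequency background together with pixel-scale noise, leaving structures
#' at aggregate scale. The response of a constant image is exactly zero. The
#' output is not clipped; its `intensity_range` records the actual response
#' range.
#'
#' @param img An [mx_image()].
#' @param cfg A [seg_config()].
#' @return An [mx_image()] holding the bandpass response.
#' @export
bandpass_filter <- function(img, cfg = seg_config()) {
  stopifnot(is_mx_image(img), inherits(cfg, "mx_seg_config"))
  if (diff(range(img$values)) == 0) {
    # DC-only input: the response is identically zero
    return(mx_image(img$values * 0, img$pixel_size_um,
                    intensity_range = c(-0.5, 0.5)))
  }
  lo <- gaussian_blur(img$values, cfg$low_sigma_px)
  hi <- gaussian_blur(img$values, cfg$high_sigma_px)
  v <- lo - hi
  rng <- range(v)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)  # constant response
  mx_image(v, img$pixel_size_um, intensity_range = rng)
}

# separable Gaussian blur with replicated edges; kernel truncated at 3
# sigma and normalized, so constants are preserved exactly and the kernel
# may be wider than the image
gaussian_blur <- function(v, sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  g <- stats::dnorm(-r:r, sd = sigma)
  g <- g / sum(g)
  t(blur_rows(t(blur_rows(v, g, r)), g, r))
}

blur_rows <- function(v, g, r) {
  n <- nrow(v)
  out <- matrix(0, n, ncol(v))
  for (j in -r:r) {
    idx <- pmin(pmax(seq_len(n) + j, 1L), n)
    out <- out + g[j + r + 1L] * v[idx, , drop = FALSE]
  }
  out
}

#' Otsu threshold
#'
#' The threshold maximizing the between-class variance of the intensity
#' histogram over `bins` equal-width bins spanning the data range. Candidate
#' thresholds are the interior bin edges; ties are broken toward the lowest
#' maximizing threshold. Foreground is the set of pixels strictly above the
#' returned value.
#'
#' @param img An [mx_image()] or a numeric matrix.
#' @param bins Number of histogram bins.
#' @return The threshold as a scalar on the intensity scale of the input.
#' @export
otsu_threshold <- function(img, bins = 256L) {
  v <- if (is_mx_image(img)) img$values else img
  stopifnot(is.numeric(v), bins >= 2)
  rng <- range(v)
  if (rng[1] == rng[2])
    stop("Otsu threshold undefined for a constant image")
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  idx <- findInterval(v, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  p <- tabulate(idx, nbins = bins) / length(v)
  mids <- (breaks[-1] + breaks[-(bins + 1)]) / 2
  w0 <- cumsum(p)[-bins]                       # background mass per cut
  m0 <- cumsum(p * mids)[-bins]                # background first moment
  mt <- sum(p * mids)
  sb2 <- (mt * w0 - m0)^2 / (w0 * (1 - w0))
  sb2[!is.finite(sb2)] <- -Inf
  breaks[which.max(sb2) + 1L]                  # first max = lowest threshold
}

#' Morphological refinement of a binary mask
#'
#' Applied in a fixed order: opening with a disc of radius `se_radius_px`
#' (removes small spots and boundary spikes), hole filling (background
#' components not connected to the image border become foreground), removal
#' of foreground components below `min_object_px`, and closing with the same
#' disc (smooths boundaries). Hole filling never removes foreground; speck
#' removal never adds it.
#'
#' @param mask An [mx_mask()].
#' @param cfg A [seg_config()].
#' @return The refined [mx_mask()].
#' @export
refine_mask <- function(mask, cfg = seg_config()) {
  stopifnot(inherits(mask, "mx_mask"), inherits(cfg, "mx_seg_config"))
  brush <- EBImage::makeBrush(2L * cfg$se_radius_px + 1L, shape = "disc")
  m <- mask$values * 1
  m <- EBImage::opening(m, brush)
  m <- EBImage::fillHull(m)
  m <- drop_small_components(m > 0, cfg$min_object_px)
  m <- EBImage::closing(m * 1, brush)
  mx_mask(as.matrix(m) > 0, mask$pixel_size_um)
}

drop_small_components <- function(m, min_px) {
  if (min_px <= 0 || !any(m)) return(m)
  lab <- label_components_8(m)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_px)
  m & matrix(lab %in% keep, nrow(m), ncol(m))
}

#' Segment aggregates from a grayscale image
#'
#' The full pipeline: bandpass filter, min-max normalization of the response
#' to `[0, 1]` (making the segmentation invariant to affine intensity
#' rescaling of the input), Otsu thresholding, and morphological refinement.
#' Foreground is the set of pixels above the threshold.
#'
#' @param img An [mx_image()].
#' @param cfg A [seg_config()].
#' @return An [mx_mask()] of the same shape as `img`.
#' @export
segment_aggregates <- function(img, cfg = seg_config()) {
  stopifnot(is_mx_image(img), inherits(cfg, "mx_seg_config"))
  base <- if (cfg$threshold_on == "bandpass") bandpass_filter(img, cfg) else img
  v <- base$values
  rng <- range(v)
  if (rng[1] == rng[2]) {
    return(mx_mask(matrix(FALSE, nrow(v), ncol(v)), img$pixel_size_um))
  }
  v <- (v - rng[1]) / (rng[2] - rng[1])
  thr <- otsu_threshold(v, bins = cfg$otsu_bins)
  refine_mask(mx_mask(v > thr, img$pixel_size_um), cfg)
}
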