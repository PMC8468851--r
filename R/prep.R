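#' Rescale an image with Lanczos (windowed-sinc, a = 3) resampling
#'
#' Separable Lanczos-3 resampling, the standard high-quality resampler for
#' microscopy downscaling. When downscaling, the kernel is widened by the
#' scale factor so it acts as a proper anti-aliasing low-pass. Edge samples
#' are replicated. Output dimensions are `round(dim * factor)` and the pixel
#' size is divided by `factor`; the result is clipped back into the image's
#' `intensity_range` (windowed-sinc kernels can overshoot).
#'
#' @param img An [mx_image()].
#' @param factor Positive scale factor (`< 1` shrinks).
#' @return The rescaled [mx_image()].
#' @export
rescale_image <- function(img, factor) {
  stopifnot(is_mx_image(img), is.numeric(factor), length(factor) == 1L,
            is.finite(factor), factor > 0)
  d <- dim(img$values)
  out_d <- round(d * factor)
  if (any(out_d < 1))
    stop("scale factor yields an empty image (", out_d[1], " x ", out_d[2], ")")
  wr <- lanczos_weights(d[1], out_d[1], factor)
  wc <- lanczos_weights(d[2], out_d[2], factor)
  v <- wr %*% img$values %*% t(wc)
  v <- pmin(pmax(v, img$intensity_range[1]), img$intensity_range[2])
  mx_image(v, pixel_size_um = img$pixel_size_um / factor,
           intensity_range = img$intensity_range)
}

# n_out x n_in row-normalized Lanczos-3 weight matrix; edge clamped
lanczos_weights <- function(n_in, n_out, factor) {
  a <- 3
  s <- max(1, 1 / factor)           # kernel widening for downscale
  W <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    u <- (i - 0.5) / factor + 0.5         # source-space center, 1-based
    lo <- floor(u - a * s)
    hi <- ceiling(u + a * s)
    j <- lo:hi
    t <- (j - u) / s
    w <- lanczos_kernel(t, a)
    keep <- w != 0
    j <- pmin(pmax(j[keep], 1L), n_in)    # replicate edges
    w <- w[keep]
    w <- w / sum(w)
    for (m in seq_along(j)) W[i, j[m]] <- W[i, j[m]] + w[m]
  }
  W
}

lanczos_kernel <- function(t, a) {
  out <- numeric(length(t))
  z <- abs(t) < 1e-9
  out[z] <- 1
  # exact zeros at the other integers, so factor 1 is the identity
  zero <- !z & abs(t - round(t)) < 1e-9
  inside <- !z & !zero & abs(t) < a
  ti <- t[inside]
  out[inside] <- a * sin(pi * ti) * sin(pi * ti / a) / (pi^2 * ti^2)
  out
}

#' Contrast-limited adaptive histogram equalization (CLAHE)
#'
#' Tile-wise histogram equalization with a clip limit, used to normalize the
#' inconsistent contrast of raw time-lapse frames. The image is first
#' min-max normalized (making the operation invariant to affine intensity
#' rescaling of the input), padded by edge replication so the tile grid
#' divides it exactly, equalized with `EBImage::clahe()`, cropped back, and
#' finally stretched to span `[0, 1]`. A constant image is returned
#' unchanged: there is no contrast to equalize.
#'
#' @param img An [mx_image()].
#' @param clip_limit CLAHE clip limit (default 2).
#' @param tile_px Approximate tile side in pixels (default 64); the actual
#'   grid uses at least 2 x 2 tiles.
#' @param bins Histogram bins per tile.
#' @return An [mx_image()] with `intensity_range = c(0, 1)`.
#' @export
clahe_normalize <- function(img, clip_limit = 2, tile_px = 64L, bins = 256L) {
  stopifnot(is_mx_image(img), clip_limit > 0, tile_px >= 1, bins >= 2)
  v <- img$values
  rng <- range(v)
  if (rng[1] == rng[2])
    return(mx_image(v, img$pixel_size_um, img$intensity_range))
  v <- (v - rng[1]) / (rng[2] - rng[1])

  d <- dim(v)
  nx <- max(2L, as.integer(round(d[1] / tile_px)))
  ny <- max(2L, as.integer(round(d[2] / tile_px)))
  pad <- c((nx - d[1] %% nx) %% nx, (ny - d[2] %% ny) %% ny)
  if (any(pad > 0)) {
    ridx <- c(seq_len(d[1]), rep(d[1], pad[1]))
    cidx <- c(seq_len(d[2]), rep(d[2], pad[2]))
    v <- v[ridx, cidx]
  }
  eq <- EBImage::clahe(v, nx = nx, ny = ny, bins = as.integer(bins),
                       limit = clip_limit)
  eq <- eq[seq_len(d[1]), seq_len(d[2]), drop = FALSE]
  r2 <- range(eq)
  if (r2[1] < r2[2]) eq <- (eq - r2[1]) / (r2[2] - r2[1])
  mx_image(matrix(as.numeric(eq), d[1], d[2]), img$pixel_size_um, c(0, 1))
}

#' Global histogram equalization
#'
#' Monotone remapping of intensities through the empirical CDF computed on
#' `bins` equal-width bins spanning the image's `intensity_range`. This is
#' the normalization that reveals the dim interaggregate streams in
#' fluorescence images; it is not invertible. A constant image maps to a
#' single value.
#'
#' @param img An [mx_image()].
#' @param bins Number of histogram bins (default 256, 8-bit equivalent).
#' @return An [mx_image()] with values in `[0, 1]`.
#' @export
hist_equalize <- function(img, bins = 256L) {
  stopifnot(is_mx_image(img), bins >= 2)
  v <- img$values
  r <- img$intensity_range
  breaks <- seq(r[1], r[2], length.out = bins + 1)
  idx <- findInterval(v, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(idx, nbins = bins)
  cdf <- cumsum(counts) / length(v)
  out <- matrix(cdf[idx], nrow(v), ncol(v))
  mx_image(out, img$pixel_size_um, c(0, 1))
}

#' Affinely rescale image intensities to a target range
#'
#' Maps the image's `intensity_range` onto `target` and updates the stored
#' range. Used at the model/metrics boundary, where images live in
#' `[-1, 1]` (the constants of the similarity metrics assume that range).
#'
#' @param img An [mx_image()].
#' @param target Length-2 numeric `(lo, hi)`, `lo < hi`.
#' @return The rescaled [mx_image()].
#' @export
scale_to_range <- function(img, target = c(-1, 1)) {
  stopifnot(is_mx_image(img))
  target <- as.numeric(target)
  if (length(target) != 2L || target[1] >= target[2])
    stop("`target` must be (lo, hi) with lo < hi")
  r <- img$intensity_range
  if (r[1] >= r[2]) stop("degenerate source intensity range")
  v <- (img$values - r[1]) / (r[2] - r[1]) * (target[2] - target[1]) + target[1]
  mx_image(v, img$pixel_size_um, target)
}
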