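#' Grayscale microscopy image with physical pixel size
#'
#' The basic container used throughout the package: a 2-D numeric grid of
#' intensities together with the pixel size in micrometers per pixel and the
#' nominal intensity range the values live in. Most operations keep images in
#' the canonical `[0, 1]` range; conversion to `[-1, 1]` happens only at the
#' model/metrics boundary (see [scale_to_range()]).
#'
#' @param values Numeric matrix of intensities (rows = image length,
#'   columns = image width).
#' @param pixel_size_um Positive scalar, micrometers per pixel.
#' @param intensity_range Length-2 numeric `(lo, hi)` with `lo < hi`. Values
#'   are expected to lie within this range; set `clip = TRUE` to enforce it.
#' @param clip If `TRUE`, clamp `values` into `intensity_range`.
#' @return An object of class `mx_image`.
#' @export
mx_image <- function(values, pixel_size_um = 1,
                     intensity_range = c(0, 1), clip = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("image must have at least one row and one column")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("`pixel_size_um` must be a positive scalar")
  intensity_range <- as.numeric(intensity_range)
  if (length(intensity_range) != 2L || intensity_range[1] >= intensity_range[2])
    stop("`intensity_range` must be (lo, hi) with lo < hi")
  if (clip) {
    values <- pmin(pmax(values, intensity_range[1]), intensity_range[2])
  }
  structure(
    list(values = values,
         pixel_size_um = as.numeric(pixel_size_um),
         intensity_range = intensity_range),
    class = "mx_image"
  )
}

#' @export
dim.mx_image <- function(x) dim(x$values)

#' @export
as.matrix.mx_image <- function(x, ...) x$values

#' @export
print.mx_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<mx_image> %d x %d px, %.4g um/px, range [%.3g, %.3g], values in [%.3g, %.3g]\n",
    d[1], d[2], x$pixel_size_um, x$intensity_range[1], x$intensity_range[2],
    min(x$values), max(x$values)))
  invisible(x)
}

is_mx_image <- function(x) inherits(x, "mx_image")

as_mx_image <- function(x, pixel_size_um = 1, intensity_range = c(0, 1)) {
  if (is_mx_image(x)) return(x)
  mx_image(x, pixel_size_um, intensity_range)
}

#' Binary segmentation mask
#'
#' @param values Logical matrix; `TRUE` marks aggregate (foreground) pixels.
#' @param pixel_size_um Micrometers per pixel, inherited from the source image.
#' @return An object of class `mx_mask`.
#' @export
mx_mask <- function(values, pixel_size_um = 1) {
  if (is.numeric(values)) values <- values > 0
  if (!is.matrix(values) || !is.logical(values))
    stop("`values` must be a logical matrix")
  structure(list(values = values, pixel_size_um = as.numeric(pixel_size_um)),
            class = "mx_mask")
}

#' @export
dim.mx_mask <- function(x) dim(x$values)

#' @export
as.matrix.mx_mask <- function(x, ...) x$values

#' @export
print.mx_mask <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<mx_mask> %d x %d px, %.4g um/px, %d foreground px (%.1f%%)\n",
              d[1], d[2], x$pixel_size_um, sum(x$values),
              100 * mean(x$values)))
  invisible(x)
}

# ---- file I/O --------------------------------------------------------------

#' Read a grayscale image from TIFF or PNG
#'
#' Values are returned in `[0, 1]` (the convention of both the `tiff` and
#' `png` readers). RGB input is converted to grayscale by channel averaging.
#' Multi-page TIFFs are read with [read_stack()].
#'
#' @param path File path; format chosen by extension (`.tif`, `.tiff`, `.png`).
#' @param pixel_size_um Micrometers per pixel to attach to the image.
#' @return An [mx_image()].
#' @export
read_image <- function(path, pixel_size_um = 1) {
  v <- read_raster(path)
  mx_image(v, pixel_size_um = pixel_size_um, intensity_range = c(0, 1))
}

#' Read a multi-frame grayscale TIFF stack
#'
#' @inheritParams read_image
#' @return A list of [mx_image()] frames.
#' @export
read_stack <- function(path, pixel_size_um = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(p) {
    mx_image(collapse_gray(p), pixel_size_um = pixel_size_um,
             intensity_range = c(0, 1))
  })
}

#' Write a grayscale image to TIFF (16-bit) or PNG
#'
#' The image is affinely mapped from its `intensity_range` to `[0, 1]` before
#' writing, so files always use the full dynamic range of the container.
#'
#' @param img An [mx_image()] or [mx_mask()].
#' @param path Output path; format chosen by extension.
#' @param bits Bit depth for TIFF output (8 or 16).
#' @export
write_image <- function(img, path, bits = 16L) {
  if (inherits(img, "mx_mask")) {
    v <- img$values * 1
  } else {
    r <- img$intensity_range
    v <- (img$values - r[1]) / (r[2] - r[1])
  }
  v <- pmin(pmax(v, 0), 1)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(v, path, bits.per.sample = as.integer(bits))
  } else if (ext == "png") {
    png::writePNG(v, path)
  } else {
    stop("unsupported image extension: ", ext)
  }
  invisible(path)
}

read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  v <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image extension: ", ext))
  collapse_gray(v)
}

collapse_gray <- function(v) {
  if (length(dim(v)) == 3L) {
    nch <- dim(v)[3]
    # drop alpha if present, average color channels
    use <- seq_len(min(nch, 3L))
    v <- apply(v[, , use, drop = FALSE], c(1, 2), mean)
  }
  v
}

# clamp helper used across modules
clip01 <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

# run `expr` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
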