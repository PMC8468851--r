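#' Mean squared error between two images
#'
#' `MSE(r, s) = sum((r - s)^2) / (Nl * Nw)`. For images scaled to `[-1, 1]`
#' the value lies in `[0, 4]`: 0 iff the images are identical, 4 for a
#' constant -1 image against a constant +1 image.
#'
#' @param r,s Same-shape [mx_image()] objects or numeric matrices.
#' @return A scalar.
#' @export
mse <- function(r, s) {
  rv <- if (is_mx_image(r)) r$values else r
  sv <- if (is_mx_image(s)) s$values else s
  if (!identical(dim(rv), dim(sv))) stop("images have different shapes")
  mean((rv - sv)^2)
}

#' Global structural similarity (SSIM) between two images
#'
#' The single global statistic
#' `SSIM(r, s) = (2 mu_r mu_s + c1)(2 cov_rs + c2) /
#'  ((mu_r^2 + mu_s^2 + c1)(var_r + var_s + c2))`
#' computed over the whole image (no sliding window), with population
#' moments. Defaults `c1 = 0.004`, `c2 = 0.0036` are tuned for images in
#' `[-1, 1]`. The value is 1 iff the images are identical; note the formula
#' is negative for sufficiently anti-correlated images. A windowed mean-SSIM
#' variant is available via `window` for comparison but is never the
#' default.
#'
#' @param r,s Same-shape [mx_image()] objects or numeric matrices, expected
#'   in `[-1, 1]`.
#' @param c1,c2 Stabilizing constants.
#' @param window Optional odd window side in pixels; if supplied, the mean
#'   of per-window global statistics (stride 1, valid positions) is returned
#'   instead of the whole-image statistic.
#' @return A scalar.
#' @export
ssim <- function(r, s, c1 = 0.004, c2 = 0.0036, window = NULL) {
  rv <- if (is_mx_image(r)) r$values else r
  sv <- if (is_mx_image(s)) s$values else s
  if (!identical(dim(rv), dim(sv))) stop("images have different shapes")
  stopifnot(c1 > 0, c2 > 0)
  if (is.null(window)) return(ssim_stat(rv, sv, c1, c2))
  w <- as.integer(window)
  stopifnot(w >= 2, w <= min(dim(rv)))
  vals <- c()
  for (i in seq_len(nrow(rv) - w + 1L)) {
    for (j in seq_len(ncol(rv) - w + 1L)) {
      vals <- c(vals, ssim_stat(rv[i:(i + w - 1L), j:(j + w - 1L)],
                                sv[i:(i + w - 1L), j:(j + w - 1L)], c1, c2))
    }
  }
  mean(vals)
}

ssim_stat <- function(rv, sv, c1, c2) {
  n <- length(rv)
  mur <- mean(rv); mus <- mean(sv)
  vr <- sum((rv - mur)^2) / n            # population variance
  vs <- sum((sv - mus)^2) / n
  cov <- sum((rv - mur) * (sv - mus)) / n
  ((2 * mur * mus + c1) * (2 * cov + c2)) /
    ((mur^2 + mus^2 + c1) * (vr + vs + c2))
}

#' Metric value of an image against integer-pixel shifts of itself
#'
#' For shift magnitude `d`, the metric is computed between the image and its
#' copy shifted by `d` pixels along each of the four axis directions
#' (+row, -row, +col, -col), on the overlapping region only (no wraparound
#' or padding), and averaged. This is the perturbation curve underlying the
#' equivalent-shift calibration.
#'
#' @param img An [mx_image()] or matrix in the metric's expected range.
#' @param d Positive integer shift in pixels.
#' @param metric `"mse"` or `"ssim"`.
#' @param ... Passed to [ssim()] (constants).
#' @return The direction-averaged metric value at shift `d`.
#' @export
shift_metric <- function(img, d, metric = c("mse", "ssim"), ...) {
  metric <- match.arg(metric)
  v <- if (is_mx_image(img)) img$values else img
  d <- as.integer(d)
  stopifnot(d >= 1, d < nrow(v), d < ncol(v))
  nr <- nrow(v); nc <- ncol(v)
  f <- if (metric == "mse") mse else function(a, b) ssim(a, b, ...)
  vals <- c(
    f(v[seq_len(nr - d), , drop = FALSE], v[(d + 1):nr, , drop = FALSE]),
    f(v[(d + 1):nr, , drop = FALSE], v[seq_len(nr - d), , drop = FALSE]),
    f(v[, seq_len(nc - d), drop = FALSE], v[, (d + 1):nc, drop = FALSE]),
    f(v[, (d + 1):nc, drop = FALSE], v[, seq_len(nc - d), drop = FALSE]))
  mean(vals)
}

#' Equivalent spatial shift for a metric value
#'
#' Interprets an observed metric value between a real and a synthesized
#' image as the smallest spatial displacement of the real image that
#' produces an equally large discrepancy: the smallest integer shift `d`
#' (in pixels, reported as `d * pixel_size_um`) at which the
#' direction-averaged shifted metric crosses the target — exceeds it for
#' MSE, falls below it for SSIM. If no crossing occurs by
#' `d = floor(min(Nl, Nw) / 2)`, the result is flagged as capped.
#'
#' @param img The real [mx_image()] (in `[-1, 1]` for the default metric
#'   constants).
#' @param target The observed metric value to match (>= 0 for MSE, <= 1 for
#'   SSIM).
#' @param metric `"mse"` or `"ssim"`.
#' @param pixel_size_um Micrometers per pixel; defaults to the image's.
#' @param ... Passed to [ssim()].
#' @return A list with `shift_um`, `shift_px`, `capped` (logical) and the
#'   search `curve` (data frame of `d_px`, `value`).
#' @export
equivalent_shift <- function(img, target, metric = c("mse", "ssim"),
                             pixel_size_um = NULL, ...) {
  metric <- match.arg(metric)
  stopifnot(is.numeric(target), length(target) == 1L)
  if (metric == "mse" && target < 0) stop("MSE target must be non-negative")
  if (metric == "ssim" && target > 1) stop("SSIM target cannot exceed 1")
  v <- if (is_mx_image(img)) img$values else img
  if (is.null(pixel_size_um))
    pixel_size_um <- if (is_mx_image(img)) img$pixel_size_um else 1
  # trivial targets need no search
  if (metric == "mse" && target <= 0)
    return(list(shift_um = 0, shift_px = 0L, capped = FALSE,
                curve = data.frame(d_px = integer(), value = numeric())))
  if (metric == "ssim" && target >= 1)
    return(list(shift_um = 0, shift_px = 0L, capped = FALSE,
                curve = data.frame(d_px = integer(), value = numeric())))
  dmax <- floor(min(dim(v)) / 2)
  curve <- data.frame(d_px = integer(), value = numeric())
  for (d in seq_len(dmax)) {
    val <- shift_metric(v, d, metric, ...)
    curve <- rbind(curve, data.frame(d_px = d, value = val))
    crossed <- if (metric == "mse") val >= target else val <= target
    if (crossed) {
      return(list(shift_um = d * pixel_size_um, shift_px = d,
                  capped = FALSE, curve = curve))
    }
  }
  list(shift_um = NA_real_, shift_px = NA_integer_, capped = TRUE,
       curve = curve)
}

#' Equivalent Gaussian-noise sigma for an MSE value
#'
#' The expected MSE created by adding i.i.d. `N(0, sigma)` noise to every
#' pixel is `sigma^2`, so the minimum noise level reproducing a target MSE
#' is `sigma = sqrt(target_mse)`; it is reported as a percentage of the
#' intensity span (2 for images in `[-1, 1]`). Clipping at the range
#' boundary is not modeled.
#'
#' @param target_mse Non-negative observed MSE.
#' @param intensity_span Width of the intensity range (default 2).
#' @return Noise sigma as a percentage of the intensity span.
#' @export
equivalent_noise_sigma <- function(target_mse, intensity_span = 2) {
  if (!is.numeric(target_mse) || target_mse < 0)
    stop("`target_mse` must be non-negative")
  stopifnot(intensity_span > 0)
  100 * sqrt(target_mse) / intensity_span
}

#' Full similarity report for an image pair
#'
#' Computes MSE and SSIM plus their calibrations: the equivalent spatial
#' shift under each metric and the equivalent Gaussian-noise percentage for
#' the MSE.
#'
#' @param real,synth Same-shape [mx_image()] objects in `[-1, 1]`.
#' @param c1,c2 SSIM constants.
#' @return A list of class `mx_metric_report` with `mse`, `ssim`,
#'   `equiv_shift_mse_um`, `equiv_shift_ssim_um` (each `NA` and flagged via
#'   `capped_*` when the search capped out) and `equiv_noise_pct`.
#' @export
metric_report <- function(real, synth, c1 = 0.004, c2 = 0.0036) {
  m <- mse(real, synth)
  s <- ssim(real, synth, c1 = c1, c2 = c2)
  es_m <- equivalent_shift(real, m, "mse")
  es_s <- equivalent_shift(real, s, "ssim", c1 = c1, c2 = c2)
  structure(list(
    mse = m, ssim = s,
    equiv_shift_mse_um = es_m$shift_um, capped_mse = es_m$capped,
    equiv_shift_ssim_um = es_s$shift_um, capped_ssim = es_s$capped,
    equiv_noise_pct = equivalent_noise_sigma(m)),
    class = "mx_metric_report")
}

#' @export
print.mx_metric_report <- function(x, ...) {
  cat(sprintf("<mx_metric_report> MSE %.4f (shift %s um, noise %.2f%%), SSIM %.4f (shift %s um)\n",
              x$mse, format(x$equiv_shift_mse_um), x$equiv_noise_pct,
              x$ssim, format(x$equiv_shift_ssim_um)))
  invisible(x)
}

#' Per-frame similarity metrics for a movie
#'
#' Applies [metric_report()] frame by frame and summarizes with means and
#' standard deviations, the movie-level procedure used for reporting
#' similarity between real and synthesized movies.
#'
#' @param real,synth Lists of same-shape [mx_image()] frames in `[-1, 1]`.
#' @param ... Passed to [metric_report()].
#' @return A list with `frames` (data frame, one row per frame) and
#'   `summary` (named means/sds).
#' @export
movie_metrics <- function(real, synth, ...) {
  stopifnot(length(real) == length(synth), length(real) > 0)
  rows <- lapply(seq_along(real), function(i) {
    rep <- metric_report(real[[i]], synth[[i]], ...)
    data.frame(frame = i, mse = rep$mse, ssim = rep$ssim,
               equiv_shift_mse_um = rep$equiv_shift_mse_um,
               equiv_shift_ssim_um = rep$equiv_shift_ssim_um,
               equiv_noise_pct = rep$equiv_noise_pct)
  })
  frames <- do.call(rbind, rows)
  num <- frames[, -1, drop = FALSE]
  list(frames = frames,
       summary = list(mean = colMeans(num, na.rm = TRUE),
                      sd = apply(num, 2, stats::sd, na.rm = TRUE)))
}
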