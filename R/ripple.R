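#' Radially binned 2-D Fourier amplitude spectrum
#'
#' Computes the centered 2-D DFT magnitude of an image, assigns every
#' Fourier-space pixel the radius `sqrt(kx^2 + ky^2)` about the DC bin, and
#' averages magnitudes over the exact pixel sets with radius in `[k, k + 1)`
#' for integer wave-numbers `k = 0 .. floor(min(Nl, Nw) / 2)`. No
#' interpolation is used. A plane wave with `p` full periods across the
#' image contributes its spectral mass to bin `p`.
#'
#' @param img An [mx_image()] or numeric matrix, at least 8 x 8.
#' @return A list of class `mx_spectrum` with integer `k`, `amplitude`, and
#'   `amplitude_smoothed` (`NULL` until [smooth_profile()] is applied).
#' @export
radial_spectrum <- function(img) {
  v <- if (is_mx_image(img)) img$values else img
  stopifnot(is.matrix(v), nrow(v) >= 8, ncol(v) >= 8)
  nr <- nrow(v); nc <- ncol(v)
  M <- Mod(stats::fft(v))
  # shift DC to (ic, jc)
  ic <- floor(nr / 2) + 1L; jc <- floor(nc / 2) + 1L
  M <- M[c((ic):nr, seq_len(ic - 1L)), c((jc):nc, seq_len(jc - 1L))]
  rows <- matrix(seq_len(nr), nr, nc) - ic
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - jc
  radius <- sqrt(rows^2 + cols^2)
  kmax <- floor(min(nr, nc) / 2)
  kbin <- floor(radius)
  amp <- vapply(0:kmax, function(k) mean(M[kbin == k]), numeric(1))
  structure(list(k = 0:kmax, amplitude = amp, amplitude_smoothed = NULL),
            class = "mx_spectrum")
}

#' @export
print.mx_spectrum <- function(x, ...) {
  cat(sprintf("<mx_spectrum> k = 0..%d%s\n", max(x$k),
              if (is.null(x$amplitude_smoothed)) "" else ", smoothed"))
  invisible(x)
}

#' Smooth a radial spectrum with a window-3 moving average
#'
#' Centered moving average of window 3 over the amplitude profile, removing
#' small bin-to-bin fluctuations before peak detection. The two endpoints
#' are averaged over their two available neighbors. Profiles shorter than 3
#' are returned unsmoothed with a warning.
#'
#' @param prof An `mx_spectrum` from [radial_spectrum()].
#' @return The profile with `amplitude_smoothed` filled in.
#' @export
smooth_profile <- function(prof) {
  stopifnot(inherits(prof, "mx_spectrum"))
  a <- prof$amplitude
  n <- length(a)
  if (n < 3) {
    warning("profile shorter than 3 bins; returned unsmoothed")
    prof$amplitude_smoothed <- a
    return(prof)
  }
  sm <- a
  sm[2:(n - 1)] <- (a[1:(n - 2)] + a[2:(n - 1)] + a[3:n]) / 3
  sm[1] <- mean(a[1:2])
  sm[n] <- mean(a[(n - 1):n])
  prof$amplitude_smoothed <- sm
  prof
}

#' Detect the ripple wavelength from a radial spectrum
#'
#' The selected wave-number `k1` is the peak of the smoothed amplitude
#' profile over `k >= kmin`, and the wavelength is `lambda = L / k1` where
#' `L` is the physical image side. The low-frequency cutoff `kmin` excludes
#' gradual intensity variation: by default `kmin = ceiling(L / lambda_max)`
#' with `lambda_max = 84` micrometers, the largest biologically plausible
#' ripple wavelength (`kmin = 6` for a 504-micrometer field). The global
#' low-frequency peak `k0` (argmax over `k >= 1`) is recorded for
#' diagnostics.
#'
#' Peak selection uses the global maximum of the smoothed profile (a
#' first-local-maximum policy is available via `peak`), refined to the bin
#' with the largest unsmoothed amplitude inside the 3-bin smoothing window
#' around that maximum. The refinement matters for narrow spectral lines:
#' the moving average smears a single-bin line over three nearly equal
#' bins, and without it the choice among them would be arbitrary.
#'
#' @param prof An `mx_spectrum`; smoothed automatically if needed.
#' @param L_um Physical side of the (square) image in micrometers.
#' @param kmin Integer low-frequency cutoff; default derived from
#'   `lambda_max_um`.
#' @param lambda_max_um Largest plausible ripple wavelength, used to derive
#'   `kmin` when it is not given.
#' @param peak `"global"` (default) or `"first_local"` maximum above `kmin`.
#' @return A list of class `mx_ripple` with `k0`, `k1`, `lambda_um`, `L_um`,
#'   `kmin`, and `no_ripple` (`TRUE` when the spectrum carries no power
#'   above the cutoff, in which case `lambda_um` is `NA`).
#' @export
detect_wavelength <- function(prof, L_um, kmin = NULL, lambda_max_um = 84,
                              peak = c("global", "first_local")) {
  stopifnot(inherits(prof, "mx_spectrum"), L_um > 0)
  peak <- match.arg(peak)
  if (is.null(kmin)) kmin <- as.integer(ceiling(L_um / lambda_max_um))
  kmin <- as.integer(kmin)
  stopifnot(kmin >= 1)
  if (max(prof$k) < kmin) stop("profile does not cover k >= kmin")
  if (is.null(prof$amplitude_smoothed)) prof <- smooth_profile(prof)
  a <- prof$amplitude
  sm <- prof$amplitude_smoothed
  k <- prof$k

  sel0 <- k >= 1L
  k0 <- k[sel0][pick_peak(sm[sel0], a[sel0], "global")]

  sel <- k >= kmin
  if (all(sm[sel] == 0)) {
    return(structure(list(k0 = k0, k1 = NA_integer_, lambda_um = NA_real_,
                          L_um = L_um, kmin = kmin, no_ripple = TRUE),
                     class = "mx_ripple"))
  }
  k1 <- k[sel][pick_peak(sm[sel], a[sel], peak)]
  structure(list(k0 = k0, k1 = as.integer(k1),
                 lambda_um = L_um / k1, L_um = L_um, kmin = kmin,
                 no_ripple = FALSE),
            class = "mx_ripple")
}

# Index of the selected peak. The smoothed profile locates the peak; the
# exact bin is then refined to the largest *raw* amplitude within the
# 3-bin smoothing window around it (ties -> smaller k). Without the
# refinement the window-3 average leaves the three bins around a narrow
# spectral line nearly equal, and the argmax among them would be decided
# by noise rather than by the signal.
pick_peak <- function(sm, raw, policy) {
  i <- NA_integer_
  if (policy == "first_local") {
    n <- length(sm)
    for (j in 2:length(sm)) {
      left_ok <- sm[j] > sm[j - 1]
      right_ok <- j == n || sm[j] >= sm[j + 1]
      if (left_ok && right_ok) { i <- j; break }
    }
  }
  if (is.na(i)) i <- which.max(sm)
  win <- max(1L, i - 1L):min(length(sm), i + 1L)
  win[which.max(raw[win])]
}

#' @export
print.mx_ripple <- function(x, ...) {
  if (x$no_ripple) {
    cat("<mx_ripple> no ripple detected above cutoff k >=", x$kmin, "\n")
  } else {
    cat(sprintf("<mx_ripple> k1 = %d, lambda = %.2f um (L = %g um, kmin = %d, k0 = %d)\n",
                x$k1, x$lambda_um, x$L_um, x$kmin, x$k0))
  }
  invisible(x)
}

#' Ripple wavelength of an image
#'
#' Convenience wrapper running [radial_spectrum()], [smooth_profile()] and
#' [detect_wavelength()]. Non-square images are center-cropped to a square
#' (with a warning), since the wavelength formula assumes an `L x L` field.
#'
#' @param img An [mx_image()].
#' @param kmin,lambda_max_um,peak Passed to [detect_wavelength()].
#' @return An `mx_ripple` result.
#' @export
ripple_wavelength <- function(img, kmin = NULL, lambda_max_um = 84,
                              peak = c("global", "first_local")) {
  stopifnot(is_mx_image(img))
  v <- img$values
  d <- dim(v)
  if (d[1] != d[2]) {
    warning("non-square image center-cropped to ", min(d), " px for wavelength estimation")
    n <- min(d)
    r0 <- floor((d[1] - n) / 2)
    c0 <- floor((d[2] - n) / 2)
    v <- v[(r0 + 1):(r0 + n), (c0 + 1):(c0 + n)]
  }
  L_um <- nrow(v) * img$pixel_size_um
  prof <- smooth_profile(radial_spectrum(v))
  detect_wavelength(prof, L_um = L_um, kmin = kmin,
                    lambda_max_um = lambda_max_um, peak = match.arg(peak))
}

#' Per-frame ripple wavelengths across a movie
#'
#' @param movie List of same-shape [mx_image()] frames.
#' @param ... Passed to [ripple_wavelength()].
#' @return A data frame with one row per frame (`frame`, `k0`, `k1`,
#'   `lambda_um`); frames with no detectable ripple yield `NA`. Mean and sd
#'   of the wavelength are attached as the `"summary"` attribute.
#' @export
wavelength_timeseries <- function(movie, ...) {
  stopifnot(length(movie) > 0)
  d0 <- dim(movie[[1]])
  rows <- lapply(seq_along(movie), function(i) {
    if (!identical(dim(movie[[i]]), d0)) stop("movie frames differ in shape")
    r <- ripple_wavelength(movie[[i]], ...)
    data.frame(frame = i, k0 = r$k0,
               k1 = if (r$no_ripple) NA_integer_ else r$k1,
               lambda_um = r$lambda_um)
  })
  out <- do.call(rbind, rows)
  attr(out, "summary") <- list(
    lambda_um_mean = mean(out$lambda_um, na.rm = TRUE),
    lambda_um_sd = stats::sd(out$lambda_um, na.rm = TRUE),
    n_detected = sum(!is.na(out$lambda_um)))
  out
}
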