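#' Parameters for a synthetic aggregate scene
#'
#' Describes a field of fruiting-body-like aggregates as they appear in
#' fluorescence microscopy of developing *M. xanthus*: bright, near-uniform
#' mounds connected by dimmer streams over a dark noisy background. The same
#' scene is also rendered as a phase-contrast-like image with the two classic
#' artifacts of that modality: a bright halo rim around each object and
#' interior dark bands (shade-off), with streams invisible.
#'
#' Aggregates use a plateaued radial profile: intensity is flat over the inner
#' 80% of the radius and falls smoothly (half-cosine) to zero over the outer
#' 20%, so the half-maximum support is well defined. The ground-truth mask is
#' the set of pixels where the noiseless aggregate field exceeds half of
#' `aggregate_intensity` (radius 0.9 R for this profile). Streams join each
#' aggregate to its nearest neighbor with a 3 px wide segment and are excluded
#' from the mask: they are interaggregate features, not aggregates.
#'
#' @param field_size_px Side of the square field in pixels.
#' @param pixel_size_um Micrometers per pixel.
#' @param n_aggregates Number of aggregates to place (rejection sampling with
#'   minimum center spacing `sum of radii + 4 px`, capped at 1000 attempts per
#'   aggregate; fewer may be placed, recorded in the truth metadata).
#' @param radius_range_px `(min, max)` aggregate radius in pixels.
#' @param stream_intensity Stream level in `(0, 1)`; keep it below half of
#'   `aggregate_intensity` or streams would enter the half-maximum mask.
#' @param aggregate_intensity Plateau level of aggregates in `(0, 1]`.
#' @param background_noise_sigma SD of additive Gaussian noise (fluorescence
#'   channel); the phase-contrast rendering uses twice this value.
#' @param halo_width_px Width of the bright phase-contrast rim.
#' @param shade_band_period_px Period of the interior dark bands in the
#'   phase-contrast rendering.
#' @param seed Integer RNG seed; identical parameters and seed give
#'   bit-identical scenes.
#' @return A list of class `mx_aggregate_params`.
#' @export
aggregate_scene_params <- function(field_size_px = 256L,
                                   pixel_size_um = 1,
                                   n_aggregates = 8L,
                                   radius_range_px = c(8, 16),
                                   stream_intensity = 0.35,
                                   aggregate_intensity = 0.9,
                                   background_noise_sigma = 0.02,
                                   halo_width_px = 2,
                                   shade_band_period_px = 6,
                                   seed = 1L) {
  stopifnot(field_size_px >= 8, pixel_size_um > 0, n_aggregates >= 0,
            length(radius_range_px) == 2, radius_range_px[1] > 0,
            radius_range_px[1] <= radius_range_px[2],
            stream_intensity > 0, stream_intensity < 1,
            aggregate_intensity > 0, aggregate_intensity <= 1,
            background_noise_sigma >= 0,
            halo_width_px > 0, shade_band_period_px > 0)
  structure(list(
    field_size_px = as.integer(field_size_px),
    pixel_size_um = pixel_size_um,
    n_aggregates = as.integer(n_aggregates),
    radius_range_px = as.numeric(radius_range_px),
    stream_intensity = stream_intensity,
    aggregate_intensity = aggregate_intensity,
    background_noise_sigma = background_noise_sigma,
    halo_width_px = halo_width_px,
    shade_band_period_px = shade_band_period_px,
    seed = as.integer(seed)), class = "mx_aggregate_params")
}

#' Parameters for a synthetic ripple scene
#'
#' A plane sinusoidal cell-density wave of known wavelength and orientation,
#' as seen during *M. xanthus* predation. The fluorescence-like rendering is
#' the full-contrast wave; the phase-contrast-like rendering is the same wave
#' at strongly reduced contrast with heavier noise, mimicking the weak
#' visibility of wave crests in phase contrast.
#'
#' @param field_size_px Side of the square field in pixels.
#' @param pixel_size_um Micrometers per pixel.
#' @param wavelength_um Ripple wavelength; must be at least
#'   `2 * pixel_size_um` (Nyquist).
#' @param orientation_rad Wave direction in `[0, pi)`.
#' @param amplitude Peak-to-trough contrast of the fluorescence wave, `(0, 1]`.
#' @param noise_sigma SD of additive Gaussian noise on the fluorescence
#'   channel; the phase channel uses three times this value.
#' @param seed Integer RNG seed.
#' @return A list of class `mx_ripple_params`.
#' @export
ripple_scene_params <- function(field_size_px = 504L,
                                pixel_size_um = 1,
                                wavelength_um = 46,
                                orientation_rad = 0,
                                amplitude = 0.8,
                                noise_sigma = 0.02,
                                seed = 1L) {
  stopifnot(field_size_px >= 8, pixel_size_um > 0,
            wavelength_um > 0, amplitude > 0, amplitude <= 1,
            noise_sigma >= 0,
            orientation_rad >= 0, orientation_rad < pi)
  if (wavelength_um < 2 * pixel_size_um)
    stop("wavelength_um below the Nyquist limit of 2 * pixel_size_um")
  structure(list(
    field_size_px = as.integer(field_size_px),
    pixel_size_um = pixel_size_um,
    wavelength_um = wavelength_um,
    orientation_rad = orientation_rad,
    amplitude = amplitude,
    noise_sigma = noise_sigma,
    seed = as.integer(seed)), class = "mx_ripple_params")
}

#' Generate a paired synthetic aggregate scene with ground truth
#'
#' @param params An [aggregate_scene_params()] object.
#' @return A list with elements `phase_like` and `fluor_like` (both
#'   [mx_image()] in `[0, 1]`) and `truth`, a list holding the ground-truth
#'   `mask` ([mx_mask()]), the per-aggregate table `aggregates` (as returned
#'   by [label_aggregates()] on the mask), the sampled `centers`/`radii`, and
#'   any placement `warnings`.
#' @export
generate_aggregate_scene <- function(params) {
  stopifnot(inherits(params, "mx_aggregate_params"))
  n <- params$field_size_px
  with_seed(params$seed, {
    placed <- place_aggregates(n, params$n_aggregates, params$radius_range_px)
    centers <- placed$centers
    radii <- placed$radii
    k <- nrow(centers)

    rows <- matrix(seq_len(n), n, n)
    cols <- matrix(seq_len(n), n, n, byrow = TRUE)

    agg_field <- matrix(0, n, n)    # noiseless aggregate profile field
    phase <- matrix(0.5, n, n)      # phase contrast: mid-gray background
    if (k > 0) {
      band_phi <- stats::runif(k, 0, pi)   # per-aggregate band orientation
      for (i in seq_len(k)) {
        r <- sqrt((rows - centers[i, 1])^2 + (cols - centers[i, 2])^2)
        prof <- plateau_profile(r, radii[i])
        agg_field <- pmax(agg_field, params$aggregate_intensity * prof)

        # phase rendering: bright rim, banded interior, no stream signal
        R <- radii[i]
        rim <- r >= R - params$halo_width_px & r <= R
        inside <- r < R - params$halo_width_px
        u <- rows * cos(band_phi[i]) + cols * sin(band_phi[i])
        bands <- 0.45 + 0.2 * sin(2 * pi * u / params$shade_band_period_px)
        phase[inside] <- bands[inside]
        phase[rim] <- 0.95
      }
    }

    streams <- matrix(0, n, n)
    if (k >= 2) {
      dmat <- as.matrix(stats::dist(centers))
      diag(dmat) <- Inf
      for (i in seq_len(k)) {
        j <- which.min(dmat[i, ])
        seg <- segment_distance(rows, cols, centers[i, ], centers[j, ])
        streams[seg <= 1.5] <- params$stream_intensity  # 3 px wide
      }
    }

    fluor <- pmax(agg_field, streams)
    if (params$background_noise_sigma > 0) {
      fluor <- fluor + stats::rnorm(n * n, 0, params$background_noise_sigma)
      phase <- phase + stats::rnorm(n * n, 0, 2 * params$background_noise_sigma)
    }
    fluor <- clip01(fluor)
    phase <- clip01(phase)

    mask <- agg_field > params$aggregate_intensity / 2
    mask <- mx_mask(mask, params$pixel_size_um)
    truth <- list(
      mask = mask,
      aggregates = label_aggregates(mask),
      centers = centers,
      radii = radii,
      warnings = placed$warnings)

    list(phase_like = mx_image(phase, params$pixel_size_um),
         fluor_like = mx_image(fluor, params$pixel_size_um),
         truth = truth)
  })
}

#' Generate a paired synthetic ripple scene with known wavelength
#'
#' The fluorescence-like field is
#' `amplitude * (1 + sin(2 * pi * (x cos(phi) + y sin(phi)) * pixel_size_um /
#' lambda)) / 2` plus Gaussian noise, clipped to `[0, 1]`; coordinates are
#' zero-based so a field of `L` pixels at orientation 0 holds exactly
#' `L * pixel_size_um / lambda` full periods.
#'
#' @param params A [ripple_scene_params()] object.
#' @return A list with `phase_like`, `fluor_like` ([mx_image()]) and `truth`
#'   (list with `wavelength_um` and `orientation_rad`).
#' @export
generate_ripple_scene <- function(params) {
  stopifnot(inherits(params, "mx_ripple_params"))
  n <- params$field_size_px
  with_seed(params$seed, {
    x <- matrix(0:(n - 1), n, n)              # row coordinate, 0-based
    y <- matrix(0:(n - 1), n, n, byrow = TRUE)
    phi <- params$orientation_rad
    arg <- 2 * pi * (x * cos(phi) + y * sin(phi)) *
      params$pixel_size_um / params$wavelength_um
    wave <- sin(arg)

    fluor <- params$amplitude * (1 + wave) / 2
    phase <- 0.5 + 0.15 * params$amplitude * wave  # reduced contrast
    if (params$noise_sigma > 0) {
      fluor <- fluor + stats::rnorm(n * n, 0, params$noise_sigma)
      phase <- phase + stats::rnorm(n * n, 0, 3 * params$noise_sigma)
    }
    list(phase_like = mx_image(clip01(phase), params$pixel_size_um),
         fluor_like = mx_image(clip01(fluor), params$pixel_size_um),
         truth = list(wavelength_um = params$wavelength_um,
                      orientation_rad = phi))
  })
}

# flat core out to 0.8 R, half-cosine falloff over the outer 20%;
# crosses one half exactly at 0.9 R
plateau_profile <- function(r, R) {
  p <- numeric(length(r))
  core <- r <= 0.8 * R
  edge <- r > 0.8 * R & r < R
  p[core] <- 1
  p[edge] <- 0.5 * (1 + cos(pi * (r[edge] - 0.8 * R) / (0.2 * R)))
  dim(p) <- dim(r)
  p
}

# rejection-sample centers so that every pair is separated by at least the
# sum of their radii plus 4 px; give up on an aggregate after 1000 attempts
place_aggregates <- function(n, k, radius_range) {
  centers <- matrix(numeric(0), 0, 2)
  radii <- numeric(0)
  warnings <- character(0)
  for (i in seq_len(k)) {
    R <- stats::runif(1, radius_range[1], radius_range[2])
    ok <- FALSE
    for (att in seq_len(1000L)) {
      c_try <- stats::runif(2, R + 1, n - R)
      if (nrow(centers) == 0) { ok <- TRUE; break }
      d <- sqrt(rowSums((centers - matrix(c_try, nrow(centers), 2,
                                          byrow = TRUE))^2))
      if (all(d >= radii + R + 4)) { ok <- TRUE; break }
    }
    if (!ok) {
      warnings <- c(warnings, sprintf(
        "aggregate %d could not be placed after 1000 attempts", i))
      next
    }
    centers <- rbind(centers, c_try)
    radii <- c(radii, R)
  }
  list(centers = centers, radii = radii, warnings = warnings)
}

# distance from each grid point to the segment from a to b (pixel coords)
segment_distance <- function(rows, cols, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt((rows - a[1])^2 + (cols - a[2])^2))
  t <- ((rows - a[1]) * ab[1] + (cols - a[2]) * ab[2]) / len2
  t <- pmin(pmax(t, 0), 1)
  sqrt((rows - (a[1] + t * ab[1]))^2 + (cols - (a[2] + t * ab[2]))^2)
}
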