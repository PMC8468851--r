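# Shared fixtures, all generated in code.

clip01 <- function(x) pmin(pmax(x, 0), 1)

# aligned (phase, fluor_clahe, fluor_he) training triplets in [-1, 1]
make_training_pairs <- function(n = 8, px = 64, seed = 42) {
  lapply(seq_len(n), function(i) {
    sc <- generate_aggregate_scene(aggregate_scene_params(
      field_size_px = px, n_aggregates = 3, radius_range_px = c(6, 10),
      seed = seed + i))
    to11 <- function(img) scale_to_range(img)$values
    list(phase = to11(sc$phase_like),
         fluor_clahe = to11(clahe_normalize(sc$fluor_like, tile_px = 32)),
         fluor_he = to11(hist_equalize(sc$fluor_like)))
  })
}

tiny_gen_cfg <- function(branch_point = 2L) {
  generator_config(base_width = 8L, n_downsample = 2L, n_resblocks = 2L,
                   branch_point = branch_point)
}

tiny_disc_cfg <- function() {
  discriminator_config(base_width = 8L, n_layers = 3L, n_scales = 2L)
}

# exhaustive O(bins^2) between-class-variance maximizer over the same
# histogram binning; independent of the cumulative-sum implementation
otsu_brute_force <- function(v, bins = 256L) {
  rng <- range(v)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  idx <- findInterval(v, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(idx, nbins = bins)
  mids <- (breaks[-1] + breaks[-(bins + 1)]) / 2
  best <- -Inf; best_i <- NA
  for (i in seq_len(bins - 1L)) {
    n0 <- sum(counts[1:i]); n1 <- sum(counts) - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(counts[1:i] * mids[1:i]) / n0
    mu1 <- sum(counts[(i + 1):bins] * mids[(i + 1):bins]) / n1
    sb2 <- (n0 / sum(counts)) * (n1 / sum(counts)) * (mu0 - mu1)^2
    if (sb2 > best + 1e-15) { best <- sb2; best_i <- i }
  }
  breaks[best_i + 1L]
}

# direct (loop-based) Gaussian blur with replicated edges, for cross-checks
naive_gauss_blur <- function(v, sigma) {
  r <- ceiling(3 * sigma)
  g <- dnorm(-r:r, sd = sigma)
  g <- g / sum(g)
  clampi <- function(i, n) pmin(pmax(i, 1L), n)
  nr <- nrow(v); nc <- ncol(v)
  tmp <- v
  for (i in seq_len(nr)) tmp[i, ] <- colSums(v[clampi(i + (-r:r), nr), ] * g)
  out <- tmp
  for (j in seq_len(nc)) out[, j] <- colSums(t(tmp[, clampi(j + (-r:r), nc)]) * g)
  out
}

# direct dense 2-D convolution of a small conv layer, for gradient oracles
naive_conv <- function(x, W, b, k, stride, pad) {
  d <- dim(x)
  xp <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  Ho <- (d[1] + 2 * pad - k) %/% stride + 1
  Wo <- (d[2] + 2 * pad - k) %/% stride + 1
  oc <- ncol(W)
  out <- array(0, c(Ho, Wo, oc))
  for (o in seq_len(oc)) {
    Wk <- array(W[, o], c(k, k, d[3]))
    for (i in seq_len(Ho)) for (j in seq_len(Wo)) {
      r0 <- (i - 1) * stride; c0 <- (j - 1) * stride
      out[i, j, o] <- sum(xp[r0 + seq_len(k), c0 + seq_len(k), ] * Wk) + b[o]
    }
  }
  out
}

# finite-difference gradient of `fn` w.r.t. the first `m` entries of vec
fd_grad <- function(fn, vec, m = length(vec), eps = 1e-6) {
  g <- numeric(m)
  for (i in seq_len(m)) {
    vp <- vec; vp[i] <- vp[i] + eps
    vm <- vec; vm[i] <- vm[i] - eps
    g[i] <- (fn(vp) - fn(vm)) / (2 * eps)
  }
  g
}
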