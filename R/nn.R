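# Minimal CNN framework with manual backpropagation.
#
# Tensors are plain 3-D arrays [H, W, C] (single sample). A network is a
# list of layer specs; convolutions are evaluated as im2col matrix products
# so the heavy lifting happens in BLAS. Every layer has an exact backward
# pass; gradients are verified against finite differences in the test
# suite. This is deliberately small: the models trained here are
# desk-scale, CPU-only.

nn_conv <- function(in_ch, out_ch, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  list(type = "conv", in_ch = as.integer(in_ch), out_ch = as.integer(out_ch),
       k = as.integer(k), stride = as.integer(stride), pad = as.integer(pad),
       W = NULL, b = NULL)
}
nn_inorm <- function(ch) list(type = "inorm", ch = as.integer(ch),
                              gamma = NULL, beta = NULL)
nn_relu <- function() list(type = "relu")
nn_lrelu <- function(slope = 0.2) list(type = "lrelu", slope = slope)
nn_tanh <- function() list(type = "tanh")
nn_upsample <- function() list(type = "upsample")
nn_res_begin <- function() list(type = "res_begin")
nn_res_end <- function() list(type = "res_end")

# standard DCGAN-style init: N(0, 0.02) weights, zero bias, unit gain norm
nn_init <- function(layers) {
  lapply(layers, function(l) {
    if (l$type == "conv") {
      l$W <- matrix(stats::rnorm(l$k * l$k * l$in_ch * l$out_ch, 0, 0.02),
                    l$k * l$k * l$in_ch, l$out_ch)
      l$b <- numeric(l$out_ch)
    } else if (l$type == "inorm") {
      l$gamma <- rep(1, l$ch)
      l$beta <- rep(0, l$ch)
    }
    l
  })
}

nn_n_params <- function(layers) {
  sum(vapply(layers, function(l) {
    switch(l$type,
           conv = length(l$W) + length(l$b),
           inorm = length(l$gamma) + length(l$beta),
           0L)
  }, numeric(1)))
}

conv_im2col <- function(xp, k, s, Ho, Wo, C) {
  M <- matrix(0, Ho * Wo, k * k * C)
  col <- 1L
  for (ch in seq_len(C)) {
    for (dj in seq_len(k)) {
      for (di in seq_len(k)) {
        ri <- seq.int(di, by = s, length.out = Ho)
        ci <- seq.int(dj, by = s, length.out = Wo)
        M[, col] <- xp[ri, ci, ch]
        col <- col + 1L
      }
    }
  }
  M
}

conv_forward <- function(l, x) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  stopifnot(C == l$in_ch)
  p <- l$pad
  xp <- array(0, c(H + 2L * p, W + 2L * p, C))
  xp[(p + 1):(p + H), (p + 1):(p + W), ] <- x
  Ho <- (H + 2L * p - l$k) %/% l$stride + 1L
  Wo <- (W + 2L * p - l$k) %/% l$stride + 1L
  M <- conv_im2col(xp, l$k, l$stride, Ho, Wo, C)
  Y <- M %*% l$W + matrix(l$b, Ho * Wo, l$out_ch, byrow = TRUE)
  list(out = array(Y, c(Ho, Wo, l$out_ch)),
       cache = list(M = M, xdim = d, Ho = Ho, Wo = Wo))
}

conv_backward <- function(l, cache, dout) {
  Ho <- cache$Ho; Wo <- cache$Wo
  dY <- matrix(dout, Ho * Wo, l$out_ch)
  dW <- crossprod(cache$M, dY)
  db <- colSums(dY)
  dM <- tcrossprod(dY, l$W)
  d <- cache$xdim; H <- d[1]; W <- d[2]; C <- d[3]
  p <- l$pad
  dxp <- array(0, c(H + 2L * p, W + 2L * p, C))
  col <- 1L
  for (ch in seq_len(C)) {
    for (dj in seq_len(l$k)) {
      for (di in seq_len(l$k)) {
        ri <- seq.int(di, by = l$stride, length.out = Ho)
        ci <- seq.int(dj, by = l$stride, length.out = Wo)
        dxp[ri, ci, ch] <- dxp[ri, ci, ch] + matrix(dM[, col], Ho, Wo)
        col <- col + 1L
      }
    }
  }
  list(dx = dxp[(p + 1):(p + H), (p + 1):(p + W), , drop = FALSE],
       grads = list(W = dW, b = db))
}

inorm_forward <- function(l, x, eps = 1e-5) {
  d <- dim(x); n <- d[1] * d[2]
  xhat <- x
  inv_sd <- numeric(d[3])
  for (c in seq_len(d[3])) {
    xc <- x[, , c]
    mu <- mean(xc)
    v <- sum((xc - mu)^2) / n
    inv_sd[c] <- 1 / sqrt(v + eps)
    xhat[, , c] <- (xc - mu) * inv_sd[c]
  }
  out <- xhat
  for (c in seq_len(d[3])) out[, , c] <- l$gamma[c] * xhat[, , c] + l$beta[c]
  list(out = out, cache = list(xhat = xhat, inv_sd = inv_sd, n = n))
}

inorm_backward <- function(l, cache, dout) {
  d <- dim(dout); n <- cache$n
  dx <- dout
  dgamma <- numeric(d[3]); dbeta <- numeric(d[3])
  for (c in seq_len(d[3])) {
    dy <- dout[, , c]
    xh <- cache$xhat[, , c]
    dgamma[c] <- sum(dy * xh)
    dbeta[c] <- sum(dy)
    dxh <- dy * l$gamma[c]
    dx[, , c] <- (cache$inv_sd[c] / n) *
      (n * dxh - sum(dxh) - xh * sum(dxh * xh))
  }
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

upsample_forward <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), ,
    drop = FALSE]
}

upsample_backward <- function(dout) {
  d <- dim(dout)
  dd <- dout[seq.int(1L, d[1], 2L), , , drop = FALSE] +
    dout[seq.int(2L, d[1], 2L), , , drop = FALSE]
  dd[, seq.int(1L, d[2], 2L), , drop = FALSE] +
    dd[, seq.int(2L, d[2], 2L), , drop = FALSE]
}

# 2x average pooling (used to feed the coarse discriminator scale)
avgpool2 <- function(x) {
  d <- dim(x)
  H2 <- d[1] %/% 2L; W2 <- d[2] %/% 2L
  x <- x[seq_len(2L * H2), seq_len(2L * W2), , drop = FALSE]
  dd <- (x[seq.int(1L, 2L * H2, 2L), , , drop = FALSE] +
         x[seq.int(2L, 2L * H2, 2L), , , drop = FALSE])
  (dd[, seq.int(1L, 2L * W2, 2L), , drop = FALSE] +
   dd[, seq.int(2L, 2L * W2, 2L), , drop = FALSE]) / 4
}

avgpool2_backward <- function(dout, in_dim) {
  d <- dim(dout)
  up <- dout[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), ,
             drop = FALSE] / 4
  full <- array(0, in_dim)
  full[seq_len(2L * d[1]), seq_len(2L * d[2]), ] <- up
  full
}

# Forward pass through a layer list. Residual skips are handled with a
# stack: res_begin pushes its input, res_end adds the popped value.
nn_forward <- function(layers, x) {
  caches <- vector("list", length(layers))
  skips <- list()
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "conv") {
      r <- conv_forward(l, x); x <- r$out; caches[[i]] <- r$cache
    } else if (l$type == "inorm") {
      r <- inorm_forward(l, x); x <- r$out; caches[[i]] <- r$cache
    } else if (l$type == "relu") {
      caches[[i]] <- x > 0; x <- x * (x > 0)
    } else if (l$type == "lrelu") {
      caches[[i]] <- x > 0; x <- ifelse(caches[[i]], x, l$slope * x)
    } else if (l$type == "tanh") {
      x <- tanh(x); caches[[i]] <- x
    } else if (l$type == "upsample") {
      caches[[i]] <- dim(x); x <- upsample_forward(x)
    } else if (l$type == "res_begin") {
      skips[[length(skips) + 1L]] <- x
    } else if (l$type == "res_end") {
      x <- x + skips[[length(skips)]]
      skips[[length(skips)]] <- NULL
    } else stop("unknown layer type: ", l$type)
  }
  list(out = x, caches = caches)
}

# Backward pass. `inject` optionally adds extra gradient at the *output* of
# given layer indices (used for feature-matching losses on intermediate
# discriminator activations).
nn_backward <- function(layers, caches, dout, inject = NULL) {
  grads <- vector("list", length(layers))
  d <- dout
  skip_stack <- list()
  for (i in rev(seq_along(layers))) {
    if (!is.null(inject) && !is.null(inject[[as.character(i)]]))
      d <- d + inject[[as.character(i)]]
    l <- layers[[i]]
    if (l$type == "conv") {
      r <- conv_backward(l, caches[[i]], d); d <- r$dx; grads[[i]] <- r$grads
    } else if (l$type == "inorm") {
      r <- inorm_backward(l, caches[[i]], d); d <- r$dx; grads[[i]] <- r$grads
    } else if (l$type == "relu") {
      d <- d * caches[[i]]
    } else if (l$type == "lrelu") {
      d <- ifelse(caches[[i]], d, l$slope * d)
    } else if (l$type == "tanh") {
      d <- d * (1 - caches[[i]]^2)
    } else if (l$type == "upsample") {
      d <- upsample_backward(d)
    } else if (l$type == "res_end") {
      skip_stack[[length(skip_stack) + 1L]] <- d
    } else if (l$type == "res_begin") {
      d <- d + skip_stack[[length(skip_stack)]]
      skip_stack[[length(skip_stack)]] <- NULL
    }
  }
  list(dx = d, grads = grads)
}

nn_zero_grads <- function(layers) {
  lapply(layers, function(l) {
    switch(l$type,
           conv = list(W = l$W * 0, b = l$b * 0),
           inorm = list(gamma = l$gamma * 0, beta = l$beta * 0),
           NULL)
  })
}

nn_add_grads <- function(a, b) {
  for (i in seq_along(a)) {
    if (!is.null(b[[i]])) {
      for (nm in names(b[[i]])) a[[i]][[nm]] <- a[[i]][[nm]] + b[[i]][[nm]]
    }
  }
  a
}

nn_scale_grads <- function(a, f) {
  lapply(a, function(g) if (is.null(g)) NULL else lapply(g, function(p) p * f))
}

# ---- Adam optimizer --------------------------------------------------------

adam_init <- function(layers) {
  list(t = 0L, m = nn_zero_grads(layers), v = nn_zero_grads(layers))
}

adam_step <- function(layers, grads, state, lr,
                      beta1 = 0.5, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (nm in names(g)) {
      state$m[[i]][[nm]] <- beta1 * state$m[[i]][[nm]] + (1 - beta1) * g[[nm]]
      state$v[[i]][[nm]] <- beta2 * state$v[[i]][[nm]] +
        (1 - beta2) * g[[nm]]^2
      layers[[i]][[nm]] <- layers[[i]][[nm]] -
        lr * (state$m[[i]][[nm]] / bc1) /
          (sqrt(state$v[[i]][[nm]] / bc2) + eps)
    }
  }
  list(layers = layers, state = state)
}
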