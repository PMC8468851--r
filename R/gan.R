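#' Generator architecture configuration
#'
#' The generator is a single-resolution encoder/residual/decoder network in
#' the pix2pixHD family: a 7x7 input convolution, `n_downsample` stride-2
#' stages, `n_resblocks` residual blocks, `n_downsample` nearest-neighbor
#' upsampling stages, and a 7x7 output convolution with tanh. The trunk is
#' shared up to a branch point, after which all remaining layers are
#' duplicated into two heads: one producing the normalized (CLAHE)
#' fluorescence channel and one producing the histogram-equalized (HE)
#' channel.
#'
#' Branch candidates sit at decoder-stage boundaries: candidate 0 splits
#' before the first upsampling stage (everything in the decoder duplicated),
#' candidate `n_downsample` duplicates only the output convolution. The
#' default candidate 2 gives the heads their own final two decoder stages.
#'
#' @param base_width Feature depth after the first convolution.
#' @param n_downsample Number of stride-2 encoder stages (and matching
#'   decoder stages).
#' @param n_resblocks Number of residual blocks at the bottleneck.
#' @param branch_point Integer in `0..n_downsample`, see above.
#' @return A list of class `mx_gen_config`.
#' @export
generator_config <- function(base_width = 64L, n_downsample = 4L,
                             n_resblocks = 9L, branch_point = 2L) {
  stopifnot(base_width >= 1, n_downsample >= 1, n_resblocks >= 0)
  branch_point <- as.integer(branch_point)
  if (branch_point < 0L || branch_point > n_downsample)
    stop("invalid branch point ", branch_point,
         "; valid candidates are 0..", n_downsample,
         " (0 = before the first upsampling stage, ", n_downsample,
         " = duplicate only the output layers)")
  structure(list(in_channels = 1L, out_channels_per_head = 1L,
                 base_width = as.integer(base_width),
                 n_downsample = as.integer(n_downsample),
                 n_resblocks = as.integer(n_resblocks),
                 branch_point = branch_point),
            class = "mx_gen_config")
}

#' Discriminator configuration
#'
#' Multi-scale PatchGAN discriminators; each of the two heads gets an
#' independent set. A discriminator is conditioned on the concatenation of
#' the input phase-contrast image with the corresponding output channel
#' (2 input channels).
#'
#' @param base_width Feature depth of the first discriminator layer.
#' @param n_layers Number of convolutional blocks before the 1-channel
#'   output map.
#' @param n_scales Number of image scales (each coarser scale sees the
#'   2x average-pooled input of the previous one).
#' @return A list of class `mx_disc_config`.
#' @export
discriminator_config <- function(base_width = 64L, n_layers = 3L,
                                 n_scales = 2L) {
  stopifnot(base_width >= 1, n_layers >= 2, n_scales >= 1)
  structure(list(in_channels = 2L, base_width = as.integer(base_width),
                 n_layers = as.integer(n_layers),
                 n_scales = as.integer(n_scales)),
            class = "mx_disc_config")
}

#' Training configuration
#'
#' Adam with learning rate `5e-5` is the reference training schedule at full
#' scale (2000 epochs). The generator loss is
#' `w1(epoch) * L_head_CLAHE + w2 * L_head_HE`, where each head loss is its
#' least-squares adversarial loss plus `feature_matching_weight` times the
#' discriminator feature-matching loss. `w2` stays constant while `w1`
#' decays linearly from `g1_weight_initial` to `g1_weight_floor` over the
#' first `g1_decay_epochs` epochs and is constant thereafter.
#'
#' @param lr Adam learning rate.
#' @param epochs Total training epochs.
#' @param g1_decay_epochs Duration of the linear decay of the CLAHE-head
#'   weight.
#' @param g1_weight_initial,g1_weight_floor Start and end of the decayed
#'   weight.
#' @param g2_weight Constant HE-head weight.
#' @param feature_matching_weight Weight of the feature-matching loss.
#' @param batch_size Images per optimizer step.
#' @param seed RNG seed controlling initialization (and hence the full
#'   training trajectory, which is otherwise deterministic on CPU).
#' @return A list of class `mx_train_config`.
#' @export
train_config <- function(lr = 5e-5, epochs = 2000L,
                         g1_decay_epochs = min(500L, epochs),
                         g1_weight_initial = 1, g1_weight_floor = 0.5,
                         g2_weight = 1, feature_matching_weight = 10,
                         batch_size = 1L, seed = 1L) {
  stopifnot(lr >= 0, epochs >= 1, g1_decay_epochs >= 1,
            g1_decay_epochs <= epochs,
            g1_weight_initial > 0, g1_weight_floor > 0, g2_weight > 0,
            feature_matching_weight >= 0, batch_size >= 1)
  structure(list(lr = lr, epochs = as.integer(epochs),
                 g1_decay_epochs = as.integer(g1_decay_epochs),
                 g1_weight_initial = g1_weight_initial,
                 g1_weight_floor = g1_weight_floor,
                 g2_weight = g2_weight,
                 feature_matching_weight = feature_matching_weight,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "mx_train_config")
}

#' Linearly decayed CLAHE-head loss weight
#'
#' `w1(epoch)` interpolates from `g1_weight_initial` at epoch 0 to
#' `g1_weight_floor` at `g1_decay_epochs`, constant afterwards.
#'
#' @param epoch Zero-based epoch index.
#' @param cfg A [train_config()].
#' @return The weight at that epoch.
#' @export
g1_weight <- function(epoch, cfg) {
  f <- min(max(epoch, 0), cfg$g1_decay_epochs) / cfg$g1_decay_epochs
  cfg$g1_weight_initial + f * (cfg$g1_weight_floor - cfg$g1_weight_initial)
}

# ---- architectures ---------------------------------------------------------

gen_decoder_stage <- function(w_in, w_out) {
  list(nn_upsample(), nn_conv(w_in, w_out, 3L), nn_inorm(w_out), nn_relu())
}

gen_output_stage <- function(w) {
  list(nn_conv(w, 1L, 7L), nn_tanh())
}

#' Build the branched two-head generator
#'
#' Layers before the branch point are shared; layers at/after it exist twice
#' with independent parameters (a CLAHE head and an HE head, each ending in
#' a 1-channel tanh output). Parameters are initialized from the current
#' RNG state.
#'
#' @param cfg A [generator_config()].
#' @return A list of class `mx_generator` with `shared`, `head_clahe`,
#'   `head_he` layer stacks and the config.
#' @export
build_generator <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "mx_gen_config"))
  w <- cfg$base_width
  nd <- cfg$n_downsample
  trunk <- list(nn_conv(1L, w, 7L), nn_inorm(w), nn_relu())
  for (d in seq_len(nd)) {
    trunk <- c(trunk, list(nn_conv(w * 2^(d - 1L), w * 2^d, 3L, stride = 2L),
                           nn_inorm(w * 2^d), nn_relu()))
  }
  wb <- w * 2^nd
  for (r in seq_len(cfg$n_resblocks)) {
    trunk <- c(trunk, list(nn_res_begin(),
                           nn_conv(wb, wb, 3L), nn_inorm(wb), nn_relu(),
                           nn_conv(wb, wb, 3L), nn_inorm(wb),
                           nn_res_end()))
  }
  decoder <- list()
  for (d in rev(seq_len(nd))) {
    decoder <- c(decoder, list(gen_decoder_stage(w * 2^d, w * 2^(d - 1L))))
  }
  decoder <- c(decoder, list(gen_output_stage(w)))  # stage nd + 1

  bp <- cfg$branch_point
  shared <- c(trunk, unlist(decoder[seq_len(bp)], recursive = FALSE))
  head <- unlist(decoder[(bp + 1L):(nd + 1L)], recursive = FALSE)
  structure(list(cfg = cfg,
                 shared = nn_init(shared),
                 head_clahe = nn_init(head),
                 head_he = nn_init(head)),
            class = "mx_generator")
}

#' @export
print.mx_generator <- function(x, ...) {
  cat(sprintf(
    "<mx_generator> base %d, %d downsamples, %d resblocks, branch %d; %d parameters\n",
    x$cfg$base_width, x$cfg$n_downsample, x$cfg$n_resblocks,
    x$cfg$branch_point, generator_n_params(x)))
  invisible(x)
}

#' Number of trainable generator parameters
#'
#' @param gen An `mx_generator`.
#' @return Total parameter count (shared trunk plus both heads).
#' @export
generator_n_params <- function(gen) {
  nn_n_params(gen$shared) + nn_n_params(gen$head_clahe) +
    nn_n_params(gen$head_he)
}

generator_forward <- function(gen, x) {
  fs <- nn_forward(gen$shared, x)
  f1 <- nn_forward(gen$head_clahe, fs$out)
  f2 <- nn_forward(gen$head_he, fs$out)
  list(y1 = f1$out, y2 = f2$out,
       caches = list(shared = fs$caches, h1 = f1$caches, h2 = f2$caches))
}

generator_backward <- function(gen, caches, dy1, dy2) {
  b1 <- nn_backward(gen$head_clahe, caches$h1, dy1)
  b2 <- nn_backward(gen$head_he, caches$h2, dy2)
  bs <- nn_backward(gen$shared, caches$shared, b1$dx + b2$dx)
  list(shared = bs$grads, head_clahe = b1$grads, head_he = b2$grads,
       dx = bs$dx)
}

build_patch_disc <- function(cfg) {
  w <- cfg$base_width
  layers <- list(nn_conv(cfg$in_channels, w, 4L, stride = 2L, pad = 1L),
                 nn_lrelu())
  wc <- w
  for (i in seq_len(cfg$n_layers - 2L)) {
    layers <- c(layers, list(nn_conv(wc, 2L * wc, 4L, stride = 2L, pad = 1L),
                             nn_inorm(2L * wc), nn_lrelu()))
    wc <- 2L * wc
  }
  layers <- c(layers, list(nn_conv(wc, 2L * wc, 4L, stride = 1L, pad = 1L),
                           nn_inorm(2L * wc), nn_lrelu()))
  wc <- 2L * wc
  layers <- c(layers, list(nn_conv(wc, 1L, 4L, stride = 1L, pad = 1L)))
  layers <- nn_init(layers)
  feat_idx <- c(which(vapply(layers, function(l) l$type == "lrelu",
                             logical(1))), length(layers))
  list(layers = layers, feat_idx = feat_idx)
}

#' Build the pair of head discriminators
#'
#' One independent multi-scale patch discriminator per generator head
#' (CLAHE and HE); their parameter sets are disjoint. Each scale of a
#' discriminator is an independent PatchGAN operating on a 2x average-pooled
#' copy of the previous scale's input.
#'
#' @param cfg A [discriminator_config()].
#' @return A list of class `mx_discriminators` with elements `clahe` and
#'   `he`, each a list of per-scale networks.
#' @export
build_discriminators <- function(cfg = discriminator_config()) {
  stopifnot(inherits(cfg, "mx_disc_config"))
  one <- function() lapply(seq_len(cfg$n_scales), function(s) build_patch_disc(cfg))
  structure(list(cfg = cfg, clahe = one(), he = one()),
            class = "mx_discriminators")
}

disc_n_params <- function(d) {
  sum(vapply(d, function(sc) nn_n_params(sc$layers), numeric(1)))
}

# forward all scales, capturing the intermediate activations used by the
# feature-matching loss
disc_forward_feats <- function(scales, x) {
  res <- vector("list", length(scales))
  xin <- x
  for (s in seq_along(scales)) {
    layers <- scales[[s]]$layers
    caches <- vector("list", length(layers))
    feats <- list()
    h <- xin
    skips <- list()
    for (i in seq_along(layers)) {
      l <- layers[[i]]
      if (l$type == "conv") {
        r <- conv_forward(l, h); h <- r$out; caches[[i]] <- r$cache
      } else if (l$type == "inorm") {
        r <- inorm_forward(l, h); h <- r$out; caches[[i]] <- r$cache
      } else if (l$type == "lrelu") {
        caches[[i]] <- h > 0; h <- ifelse(caches[[i]], h, l$slope * h)
      } else stop("unexpected discriminator layer: ", l$type)
      if (i %in% scales[[s]]$feat_idx)
        feats[[as.character(i)]] <- h
    }
    res[[s]] <- list(out = h, caches = caches, feats = feats, input = xin)
    if (s < length(scales)) xin <- avgpool2(xin)
  }
  res
}

# least-squares GAN loss pieces
lsgan_d_loss <- function(out_real, out_fake) {
  0.5 * mean((out_real - 1)^2) + 0.5 * mean(out_fake^2)
}

concat_pair <- function(phase, channel) {
  d <- dim(phase)
  arr <- array(0, c(d[1], d[2], 2L))
  arr[, , 1] <- phase
  arr[, , 2] <- channel
  arr
}

as_chw <- function(m) array(m, c(nrow(m), ncol(m), 1L))

#' One adversarial training step
#'
#' Runs one optimizer step for the generator and both discriminators on a
#' batch of aligned `(phase, fluor_clahe, fluor_he)` triplets, all in
#' `[-1, 1]`. Discriminators are trained with the least-squares GAN loss on
#' real and (detached) generated pairs; the generator minimizes
#' `w1(epoch) * (adv + fm)_CLAHE + w2 * (adv + fm)_HE`, where `fm` is the
#' feature-matching loss over discriminator activations weighted by
#' `feature_matching_weight`. Generator gradients are computed through the
#' pre-update discriminators so a step is a deterministic function of the
#' incoming state.
#'
#' @param model A model state from [gan_init()] or a previous step.
#' @param batch List of triplets; each a list with matrices `phase`,
#'   `fluor_clahe`, `fluor_he`.
#' @param epoch Zero-based epoch index used for the weight schedule.
#' @param cfg A [train_config()].
#' @return The updated model with a `losses` element (named numerics:
#'   `g_total`, `g_head1`, `g_head2`, `d_head1`, `d_head2`, `w1`).
#' @export
training_step <- function(model, batch, epoch, cfg) {
  stopifnot(length(batch) >= 1)
  gen <- model$gen
  discs <- model$discs
  fmw <- cfg$feature_matching_weight
  w1 <- g1_weight(epoch, cfg)
  w2 <- cfg$g2_weight

  g_grads <- list(shared = nn_zero_grads(gen$shared),
                  head_clahe = nn_zero_grads(gen$head_clahe),
                  head_he = nn_zero_grads(gen$head_he))
  d_grads <- list(
    clahe = lapply(discs$clahe, function(sc) nn_zero_grads(sc$layers)),
    he = lapply(discs$he, function(sc) nn_zero_grads(sc$layers)))
  loss_acc <- c(g_total = 0, g_head1 = 0, g_head2 = 0,
                d_head1 = 0, d_head2 = 0)

  for (sample in batch) {
    x <- as_chw(sample$phase)
    gf <- generator_forward(gen, x)
    fakes <- list(gf$y1[, , 1], gf$y2[, , 1])
    reals <- list(sample$fluor_clahe, sample$fluor_he)
    head_names <- c("clahe", "he")
    dfake <- vector("list", 2L)
    for (h in 1:2) {
      scales <- discs[[head_names[h]]]
      real_pair <- concat_pair(sample$phase, reals[[h]])
      fake_pair <- concat_pair(sample$phase, fakes[[h]])

      # --- discriminator loss and gradients (fake detached) ---
      fr <- disc_forward_feats(scales, real_pair)
      ff <- disc_forward_feats(scales, fake_pair)
      d_loss <- 0
      for (s in seq_along(scales)) {
        o_r <- fr[[s]]$out; o_f <- ff[[s]]$out
        d_loss <- d_loss + lsgan_d_loss(o_r, o_f)
        br <- nn_backward(scales[[s]]$layers, fr[[s]]$caches,
                          (o_r - 1) / length(o_r))
        bf <- nn_backward(scales[[s]]$layers, ff[[s]]$caches,
                          o_f / length(o_f))
        d_grads[[head_names[h]]][[s]] <-
          nn_add_grads(nn_add_grads(d_grads[[head_names[h]]][[s]], br$grads),
                       bf$grads)
      }
      loss_acc[[paste0("d_head", h)]] <-
        loss_acc[[paste0("d_head", h)]] + d_loss

      # --- generator adversarial + feature-matching loss through D ---
      adv <- 0
      fm <- 0
      dpair_total <- array(0, dim(fake_pair))
      n_feats <- length(scales[[1]]$feat_idx)
      n_sc <- length(scales)
      for (s in seq_along(scales)) {
        o_f <- ff[[s]]$out
        adv <- adv + mean((o_f - 1)^2)
        inject <- list()
        for (fi in scales[[s]]$feat_idx) {
          f_f <- ff[[s]]$feats[[as.character(fi)]]
          f_r <- fr[[s]]$feats[[as.character(fi)]]
          fm <- fm + mean(abs(f_f - f_r)) / (n_sc * n_feats)
          inject[[as.character(fi)]] <-
            fmw * sign(f_f - f_r) / (length(f_f) * n_sc * n_feats)
        }
        # adversarial gradient enters at the final map; the final map is
        # also a matched feature, so its injection adds to this
        dout <- 2 * (o_f - 1) / length(o_f)
        bf <- nn_backward(scales[[s]]$layers, ff[[s]]$caches, dout,
                          inject = inject)
        dsc <- bf$dx
        # chain gradient of the pooled input back to full resolution
        if (s > 1) {
          for (p in seq_len(s - 1L)) {
            target_dim <- if (p == s - 1L) dim(fake_pair) else
              dim(ff[[s - p]]$input)
            dsc <- avgpool2_backward(dsc, target_dim)
          }
        }
        dpair_total <- dpair_total + dsc
      }
      head_loss <- adv + fmw * fm
      loss_acc[[paste0("g_head", h)]] <-
        loss_acc[[paste0("g_head", h)]] + head_loss
      dfake[[h]] <- dpair_total[, , 2, drop = FALSE]  # channel 2 = output
    }

    gb <- generator_backward(gen, gf$caches,
                             w1 * array(dfake[[1]], dim(gf$y1)),
                             w2 * array(dfake[[2]], dim(gf$y2)))
    g_grads$shared <- nn_add_grads(g_grads$shared, gb$shared)
    g_grads$head_clahe <- nn_add_grads(g_grads$head_clahe, gb$head_clahe)
    g_grads$head_he <- nn_add_grads(g_grads$head_he, gb$head_he)
  }

  nb <- length(batch)
  loss_acc <- loss_acc / nb
  loss_acc[["g_total"]] <- w1 * loss_acc[["g_head1"]] +
    w2 * loss_acc[["g_head2"]]

  # optimizer steps (gradients averaged over the batch)
  for (h in c("clahe", "he")) {
    for (s in seq_along(discs[[h]])) {
      r <- adam_step(discs[[h]][[s]]$layers,
                     nn_scale_grads(d_grads[[h]][[s]], 1 / nb),
                     model$opt_d[[h]][[s]], cfg$lr)
      discs[[h]][[s]]$layers <- r$layers
      model$opt_d[[h]][[s]] <- r$state
    }
  }
  r <- adam_step(gen$shared, nn_scale_grads(g_grads$shared, 1 / nb),
                 model$opt_g$shared, cfg$lr)
  gen$shared <- r$layers; model$opt_g$shared <- r$state
  r <- adam_step(gen$head_clahe, nn_scale_grads(g_grads$head_clahe, 1 / nb),
                 model$opt_g$head_clahe, cfg$lr)
  gen$head_clahe <- r$layers; model$opt_g$head_clahe <- r$state
  r <- adam_step(gen$head_he, nn_scale_grads(g_grads$head_he, 1 / nb),
                 model$opt_g$head_he, cfg$lr)
  gen$head_he <- r$layers; model$opt_g$head_he <- r$state

  if (any(!is.finite(loss_acc)))
    stop("non-finite loss encountered: ",
         paste(names(loss_acc), signif(loss_acc, 4), collapse = ", "))

  model$gen <- gen
  model$discs <- discs
  model$step <- model$step + 1L
  model$losses <- c(loss_acc, w1 = w1)
  model
}

#' Initialize a fresh model state
#'
#' Builds the generator and both discriminators (weights drawn under
#' `train_cfg$seed`) together with their Adam states.
#'
#' @param gen_cfg A [generator_config()].
#' @param disc_cfg A [discriminator_config()].
#' @param train_cfg A [train_config()].
#' @return A model-state list (class `mx_gan`) accepted by
#'   [training_step()], [train_gan()] and [translate_image()].
#' @export
gan_init <- function(gen_cfg = generator_config(),
                     disc_cfg = discriminator_config(),
                     train_cfg = train_config()) {
  with_seed(train_cfg$seed, {
    gen <- build_generator(gen_cfg)
    discs <- build_discriminators(disc_cfg)
    structure(list(
      gen = gen, discs = discs,
      opt_g = list(shared = adam_init(gen$shared),
                   head_clahe = adam_init(gen$head_clahe),
                   head_he = adam_init(gen$head_he)),
      opt_d = list(clahe = lapply(discs$clahe,
                                  function(sc) adam_init(sc$layers)),
                   he = lapply(discs$he, function(sc) adam_init(sc$layers))),
      gen_cfg = gen_cfg, disc_cfg = disc_cfg, train_cfg = train_cfg,
      epoch = 0L, step = 0L,
      arch_sig = arch_signature(gen_cfg, disc_cfg)),
      class = "mx_gan")
  })
}

arch_signature <- function(gen_cfg, disc_cfg) {
  paste(c(unlist(gen_cfg), unlist(disc_cfg)), collapse = "|")
}

#' Train the two-head conditional GAN
#'
#' Iterates [training_step()] over the dataset. One epoch is one pass over
#' `pairs` in order (deterministic given the seed, which only controls
#' initialization). Either a number of `epochs` (from `train_cfg`) or an
#' explicit number of `steps` can be requested; with `steps`, batches are
#' taken cyclically.
#'
#' @param pairs List of training triplets (`phase`, `fluor_clahe`,
#'   `fluor_he` matrices in `[-1, 1]`).
#' @param model An existing model state to continue from, or `NULL` to
#'   initialize one.
#' @param gen_cfg,disc_cfg,train_cfg Configurations used when `model` is
#'   `NULL`.
#' @param steps If given, run exactly this many optimizer steps instead of
#'   `train_cfg$epochs` full passes.
#' @return The trained model; `$log` holds a per-step data frame of losses.
#' @export
train_gan <- function(pairs, model = NULL,
                      gen_cfg = generator_config(),
                      disc_cfg = discriminator_config(),
                      train_cfg = train_config(), steps = NULL) {
  stopifnot(length(pairs) >= 1)
  if (is.null(model)) model <- gan_init(gen_cfg, disc_cfg, train_cfg)
  cfg <- if (is.null(model$train_cfg)) train_cfg else model$train_cfg
  bs <- cfg$batch_size
  n <- length(pairs)
  steps_per_epoch <- ceiling(n / bs)
  total_steps <- if (is.null(steps)) cfg$epochs * steps_per_epoch
                 else as.integer(steps)
  log <- vector("list", total_steps)
  pos <- 1L
  for (st in seq_len(total_steps)) {
    idx <- ((pos - 1L + seq_len(bs) - 1L) %% n) + 1L
    epoch <- model$epoch
    model <- training_step(model, pairs[idx], epoch, cfg)
    pos <- pos + bs
    while (pos > n) {   # completed a pass over the dataset
      pos <- pos - n
      model$epoch <- model$epoch + 1L
    }
    log[[st]] <- data.frame(step = model$step, epoch = epoch,
                            t(model$losses))
  }
  model$log <- rbind(model$log, do.call(rbind, log))
  model
}

#' Resume training from a checkpoint (transfer learning)
#'
#' Continues training with the previous model parameters as the starting
#' point — the mechanism used to adapt an aggregation-trained model to
#' rippling data with far fewer epochs than training from scratch. The
#' architecture must match the checkpoint. By default the epoch counter
#' (and with it the head-weight schedule) continues where it left off; set
#' `reset_schedule = TRUE` to restart both.
#'
#' @param model A model state (e.g. from [load_checkpoint()]).
#' @param pairs New training triplets.
#' @param steps Number of additional optimizer steps; 0 returns the model
#'   unchanged.
#' @param train_cfg Optional new [train_config()] (learning rate, weights);
#'   the architecture configs always come from the checkpoint.
#' @param reset_schedule Restart the epoch counter and weight schedule.
#' @return The updated model.
#' @export
resume_training <- function(model, pairs, steps, train_cfg = NULL,
                            reset_schedule = FALSE) {
  stopifnot(inherits(model, "mx_gan"))
  if (!identical(model$arch_sig,
                 arch_signature(model$gen_cfg, model$disc_cfg)))
    stop("checkpoint architecture signature mismatch")
  if (!is.null(train_cfg)) model$train_cfg <- train_cfg
  if (reset_schedule) model$epoch <- 0L
  if (steps == 0L) return(model)
  train_gan(pairs, model = model, steps = steps)
}

#' Translate a phase-contrast image into synthesized fluorescence channels
#'
#' Deterministic forward pass of the generator. The input must be
#' preprocessed to `[-1, 1]`; dimensions not divisible by
#' `2^n_downsample` are reflect-padded and the outputs cropped back.
#'
#' @param model An `mx_gan` model state.
#' @param phase An [mx_image()] with `intensity_range` `[-1, 1]`, or a
#'   matrix in `[-1, 1]`.
#' @return A list with `syn_fluor` and `syn_fluor_he` ([mx_image()] objects
#'   in `[-1, 1]`, same size as the input).
#' @export
translate_image <- function(model, phase) {
  stopifnot(inherits(model, "mx_gan"))
  psz <- if (is_mx_image(phase)) phase$pixel_size_um else 1
  v <- if (is_mx_image(phase)) phase$values else phase
  if (is_mx_image(phase) &&
      !isTRUE(all.equal(phase$intensity_range, c(-1, 1))))
    stop("phase image must be scaled to [-1, 1]; see scale_to_range()")
  m <- 2L^model$gen_cfg$n_downsample
  d <- dim(v)
  dp <- ceiling(d / m) * m
  ridx <- reflect_index(d[1], dp[1])
  cidx <- reflect_index(d[2], dp[2])
  vp <- v[ridx, cidx]
  gf <- generator_forward(model$gen, as_chw(vp))
  y1 <- gf$y1[seq_len(d[1]), seq_len(d[2]), 1]
  y2 <- gf$y2[seq_len(d[1]), seq_len(d[2]), 1]
  list(syn_fluor = mx_image(y1, psz, c(-1, 1)),
       syn_fluor_he = mx_image(y2, psz, c(-1, 1)))
}

reflect_index <- function(n, n_target) {
  if (n_target <= n) return(seq_len(n_target))
  pad <- n_target - n
  if (pad > n - 1) stop("image too small to reflect-pad to ", n_target)
  c(seq_len(n), seq.int(n - 1L, by = -1L, length.out = pad))
}

#' Save / load a model checkpoint
#'
#' Checkpoints are single-file RDS archives embedding generator and
#' discriminator parameters, optimizer state, epoch counter and the
#' architecture configuration; [load_checkpoint()] refuses files whose
#' architecture signature does not match their stored configs.
#'
#' @param model An `mx_gan` model state.
#' @param path Path to the checkpoint file.
#' @return `save_checkpoint()` returns `path` invisibly; `load_checkpoint()`
#'   returns the model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "mx_gan"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "mx_gan")) stop("not a model checkpoint: ", path)
  if (!identical(model$arch_sig,
                 arch_signature(model$gen_cfg, model$disc_cfg)))
    stop("checkpoint is corrupt: architecture signature mismatch")
  model
}
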