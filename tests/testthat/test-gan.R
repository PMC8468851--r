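nn <- asNamespace("myxopix")

test_that("generator emits two same-size tanh-bounded outputs", {
  set.seed(20)
  gen <- build_generator(tiny_gen_cfg())
  x <- array(runif(64 * 64, -1, 1), c(64, 64, 1))
  out <- nn$generator_forward(gen, x)
  expect_equal(dim(out$y1), c(64L, 64L, 1L))
  expect_equal(dim(out$y2), c(64L, 64L, 1L))
  expect_true(all(abs(out$y1) <= 1) && all(abs(out$y2) <= 1))
})

test_that("branch-point parameter counts follow exact layer arithmetic", {
  count_conv <- function(k, ci, co) k * k * ci * co + co
  count_in <- function(c) 2 * c
  w <- 8
  # tiny config: trunk = c7s1-8, d16, d32, 2 resblocks at 32
  trunk <- count_conv(7, 1, w) + count_in(w) +
    count_conv(3, w, 2 * w) + count_in(2 * w) +
    count_conv(3, 2 * w, 4 * w) + count_in(4 * w) +
    2 * (2 * (count_conv(3, 4 * w, 4 * w) + count_in(4 * w)))
  dec1 <- count_conv(3, 4 * w, 2 * w) + count_in(2 * w)
  dec2 <- count_conv(3, 2 * w, w) + count_in(w)
  outl <- count_conv(7, w, 1)

  # branch at the last candidate: only output layers duplicated
  g2 <- build_generator(tiny_gen_cfg(branch_point = 2L))
  expect_equal(generator_n_params(g2), trunk + dec1 + dec2 + 2 * outl)
  # branch before the decoder: everything after the trunk duplicated
  g0 <- build_generator(tiny_gen_cfg(branch_point = 0L))
  expect_equal(generator_n_params(g0), trunk + 2 * (dec1 + dec2 + outl))
  # earlier branching strictly increases the parameter count
  g1 <- build_generator(tiny_gen_cfg(branch_point = 1L))
  expect_gt(generator_n_params(g0), generator_n_params(g1))
  expect_gt(generator_n_params(g1), generator_n_params(g2))

  expect_error(generator_config(branch_point = 7), "valid candidates")
})

test_that("discriminators are independent with PatchGAN output geometry", {
  set.seed(21)
  ds <- build_discriminators(tiny_disc_cfg())
  w_clahe <- ds$clahe[[1]]$layers[[1]]$W
  w_he <- ds$he[[1]]$layers[[1]]$W
  expect_false(identical(w_clahe, w_he))  # separate initializations
  # mutating one head's weights must not touch the other (plain lists)
  ds$clahe[[1]]$layers[[1]]$W[] <- 0
  expect_false(all(ds$he[[1]]$layers[[1]]$W == 0))

  # conv shape arithmetic for a 64x64 input through k4 layers:
  # s2: 32, s2: 16, s1 p1: 15, s1 p1: 14
  x <- array(runif(64 * 64 * 2, -1, 1), c(64, 64, 2))
  res <- nn$disc_forward_feats(ds$clahe, x)
  expect_equal(dim(res[[1]]$out)[1:2], c(14L, 14L))
  expect_equal(dim(res[[2]]$out)[1:2], c(6L, 6L))  # 32 -> 16 -> 8 -> 7 -> 6
  expect_true(all(is.finite(res[[1]]$out)))
})

test_that("head-weight schedule is linear with a floor", {
  cfg <- train_config(g1_decay_epochs = 500, g1_weight_initial = 1,
                      g1_weight_floor = 0.5)
  expect_equal(g1_weight(0, cfg), 1)
  expect_equal(g1_weight(250, cfg), 0.75)
  expect_equal(g1_weight(500, cfg), 0.5)
  expect_equal(g1_weight(1500, cfg), 0.5)
})

test_that("a zero-learning-rate step leaves all parameters bit-identical", {
  pairs <- make_training_pairs(n = 2)
  cfg0 <- train_config(lr = 0, epochs = 1, g1_decay_epochs = 1, seed = 5)
  model <- gan_init(tiny_gen_cfg(), tiny_disc_cfg(), cfg0)
  before <- model$gen
  stepped <- training_step(model, pairs[1], epoch = 0, cfg = cfg0)
  expect_identical(stepped$gen$shared, before$shared)
  expect_identical(stepped$gen$head_clahe, before$head_clahe)
  expect_identical(stepped$discs$he[[1]]$layers,
                   model$discs$he[[1]]$layers)
  expect_true(all(is.finite(stepped$losses)))
})

test_that("HE-head gradients reach the shared trunk", {
  set.seed(22)
  gen <- build_generator(tiny_gen_cfg())
  x <- array(runif(32 * 32, -1, 1), c(32, 32, 1))
  f <- nn$generator_forward(gen, x)
  gb <- nn$generator_backward(gen, f$caches,
                              dy1 = array(0, dim(f$y1)),
                              dy2 = array(1, dim(f$y2)) / length(f$y2))
  trunk_norm <- sum(vapply(gb$shared, function(g) {
    if (is.null(g)) 0 else sum(vapply(g, function(p) sum(abs(p)), numeric(1)))
  }, numeric(1)))
  expect_gt(trunk_norm, 0)
  clahe_norm <- sum(vapply(gb$head_clahe, function(g) {
    if (is.null(g)) 0 else sum(vapply(g, function(p) sum(abs(p)), numeric(1)))
  }, numeric(1)))
  expect_equal(clahe_norm, 0)  # no gradient flowed into the CLAHE head
})

test_that("short seeded training is deterministic and finite", {
  pairs <- make_training_pairs(n = 4)
  cfg <- train_config(lr = 1e-3, epochs = 2, g1_decay_epochs = 1, seed = 9)
  m1 <- train_gan(pairs, gen_cfg = tiny_gen_cfg(), disc_cfg = tiny_disc_cfg(),
                  train_cfg = cfg, steps = 6)
  m2 <- train_gan(pairs, gen_cfg = tiny_gen_cfg(), disc_cfg = tiny_disc_cfg(),
                  train_cfg = cfg, steps = 6)
  expect_equal(m1$log$g_total, m2$log$g_total, tolerance = 1e-12)
  expect_true(all(is.finite(m1$log$g_total)))
  expect_equal(m1$epoch, 1L)  # 6 steps of batch 1 over 4 pairs
})

test_that("translation is deterministic and crops padded inputs back", {
  pairs <- make_training_pairs(n = 2)
  model <- gan_init(tiny_gen_cfg(), tiny_disc_cfg(),
                    train_config(seed = 30))
  img <- mx_image(pairs[[1]]$phase, intensity_range = c(-1, 1))
  o1 <- translate_image(model, img)
  o2 <- translate_image(model, img)
  expect_identical(o1$syn_fluor$values, o2$syn_fluor$values)
  expect_true(all(abs(o1$syn_fluor$values) <= 1))
  expect_true(all(abs(o1$syn_fluor_he$values) <= 1))

  odd <- mx_image(pairs[[1]]$phase[1:60, 1:60], intensity_range = c(-1, 1))
  oo <- translate_image(model, odd)
  expect_equal(dim(oo$syn_fluor), c(60L, 60L))
  expect_equal(dim(oo$syn_fluor_he), c(60L, 60L))

  raw <- mx_image(matrix(runif(64 * 64), 64, 64))  # [0,1] not allowed
  expect_error(translate_image(model, raw), "scaled")
})

test_that("checkpoints round-trip and refuse corrupt archives", {
  model <- gan_init(tiny_gen_cfg(), tiny_disc_cfg(), train_config(seed = 31))
  path <- tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  back <- load_checkpoint(path)
  expect_identical(back$gen$shared, model$gen$shared)
  expect_identical(back$discs$clahe[[1]]$layers,
                   model$discs$clahe[[1]]$layers)

  bad <- model
  bad$arch_sig <- "tampered"
  saveRDS(bad, path)
  expect_error(load_checkpoint(path), "signature")
  saveRDS(list(1, 2), path)
  expect_error(load_checkpoint(path), "not a model checkpoint")
})

test_that("resume with zero steps is the identity; schedule persists", {
  pairs <- make_training_pairs(n = 2)
  model <- gan_init(tiny_gen_cfg(), tiny_disc_cfg(),
                    train_config(lr = 1e-3, epochs = 4, g1_decay_epochs = 2,
                                 seed = 32))
  model <- train_gan(pairs, model = model, steps = 4)
  resumed <- resume_training(model, pairs, steps = 0)
  expect_identical(resumed$gen, model$gen)
  expect_equal(resumed$epoch, model$epoch)
  reset <- resume_training(model, pairs, steps = 0, reset_schedule = TRUE)
  expect_equal(reset$epoch, 0L)
})
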