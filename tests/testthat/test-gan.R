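tiny_gen_cfg <- function() generator_config(latent_dim = 8L, seed_spatial = 2L,
                                            stage_filters = c(12L, 8L, 6L, 4L))
tiny_disc_cfg <- function() discriminator_config(
  input_size = 32L, layer_filters = c(4L, 6L, 8L, 12L, 16L))

test_that("generator output shape/range contract holds and is deterministic", {
  set.seed(60)
  gen <- build_generator(tiny_gen_cfg())
  expect_equal(gen$config$output_size, 32L)
  imgs <- sample_images(gen, 5, seed = 2)
  expect_equal(dim(imgs), c(32L, 32L, 3L, 5L))
  expect_true(all(imgs >= 0 & imgs <= 1))
  expect_identical(imgs, sample_images(gen, 5, seed = 2))
  expect_equal(dim(sample_images(gen, 0))[4], 0L)
  expect_error(generator_config(stage_filters = c(64L, 128L)),
               class = "bad_config")
})

test_that("zeroed residual branches leave each stage an upsampling-only map", {
  set.seed(61)
  gen <- build_generator(tiny_gen_cfg())
  gen0 <- gen
  for (nm in grep("_r[0-9]+_conv", names(gen0$layers), value = TRUE)) {
    gen0$layers[[nm]]$params$w[] <- 0
    gen0$layers[[nm]]$params$b[] <- 0
  }
  # manual path: same weights, residual blocks deleted entirely
  z <- matrix(rnorm(3 * 8), 3, 8)
  full <- gen_forward(gen0, z)$y
  manual <- local({
    cfg <- gen0$config
    h <- array(t(layer_forward(gen0$layers$proj, z)$y), c(2, 2, 12, 3))
    for (i in seq_along(cfg$stage_filters)) {
      h <- .upsample2_fwd(h)
      h <- layer_forward(gen0$layers[[paste0("s", i, "_up")]], h)$y
      h <- layer_forward(gen0$layers[[paste0("s", i, "_upnorm")]], h)$y
      h <- pmax(h, 0)
    }
    (tanh(layer_forward(gen0$layers$out_conv, h)$y) + 1) / 2
  })
  expect_equal(full, manual, tolerance = 1e-12)
})

test_that("discriminator census: exactly 5 conv layers, increasing filters", {
  cfg <- discriminator_config()  # full-size schedule
  disc <- build_discriminator(cfg)
  convs <- Filter(function(l) l$type == "conv", disc$layers)
  expect_length(convs, 5L)
  expect_equal(unname(vapply(convs, `[[`, 0L, "cout")),
               c(32L, 64L, 128L, 256L, 512L))
  set.seed(62)
  d2 <- build_discriminator(tiny_disc_cfg())
  x <- array(runif(32 * 32 * 3 * 4), c(32, 32, 3, 4))
  p <- disc_forward(d2, x)$y
  expect_length(p, 4L)
  expect_true(all(p >= 0 & p <= 1))
  expect_error(discriminator_config(layer_filters = c(8L, 16L)),
               class = "bad_config")
  expect_error(disc_forward(d2, array(0, c(16, 16, 3, 1))),
               class = "shape_mismatch")
})

test_that("a short adversarial run stays numerically healthy", {
  spec <- phantom_spec(image_size = 32L, blur_sigma = 0.5)
  set.seed(63)
  ds <- generate_dataset(spec, c(abnormal = 40), seed = 63)
  imgs <- samples_to_x(ds$samples)
  set.seed(63)
  gen <- build_generator(tiny_gen_cfg())
  disc <- build_discriminator(tiny_disc_cfg())
  r <- train_gan(gen, disc, imgs,
                 gan_train_config(batch_size = 8L, steps = 15L, seed = 1L))
  expect_equal(nrow(r$history), 15L)
  expect_true(all(is.finite(r$history$d_loss)))
  expect_true(all(is.finite(r$history$g_loss)))
  # the trained discriminator separates real phantoms from frozen
  # untrained-generator noise better than chance
  fakes <- sample_images(build_generator(tiny_gen_cfg()), 40, seed = 9)
  pr <- disc_forward(r$discriminator, imgs[, , , 1:40])$y
  pf <- disc_forward(r$discriminator, fakes)$y
  acc <- (sum(pr >= 0.5) + sum(pf < 0.5)) / 80
  expect_gt(acc, 0.5)
  expect_error(train_gan(gen, disc, imgs[, , , 1:10],
                         gan_train_config(batch_size = 8L, steps = 2L)),
               class = "too_few_images")
})

test_that("Frechet distance has its metric properties", {
  set.seed(64)
  x <- matrix(rnorm(200 * 6), 200, 6)
  expect_lt(compute_fid(x, x)$value, 1e-6)
  y <- matrix(rnorm(200 * 6, 1), 200, 6)
  expect_equal(compute_fid(x, y)$value, compute_fid(y, x)$value,
               tolerance = 1e-8)
  expect_gte(compute_fid(x, y)$value, 0)
  # image pathway: identical sets score ~0 through the embedding
  imgs <- array(runif(32 * 32 * 3 * 8), c(32, 32, 3, 8))
  expect_lt(compute_fid(imgs, imgs)$value, 1e-6)
  expect_error(compute_fid(x[1, , drop = FALSE], y), class = "too_few_samples")
})

test_that("Frechet distance matches the univariate Gaussian closed form", {
  set.seed(65)
  n <- 2e5
  a <- matrix(rnorm(n, 0, 1), ncol = 1)
  b <- matrix(rnorm(n, 3, 1), ncol = 1)
  # (mu difference)^2 + (sd_r - sd_f)^2 = 9 + 0
  expect_equal(compute_fid(a, b)$value, 9, tolerance = 0.02 * 9)
})
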