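test_that("parameter accounting matches closed-form layer arithmetic", {
  conv <- nn_conv(3, 3, 64)
  expect_equal(unname(layer_n_params(conv)["trainable"]), 3 * 3 * 3 * 64 + 64)  # 1792
  bn <- nn_norm(64, "batch")
  expect_equal(unname(layer_n_params(bn)), c(128, 128))
  gn <- nn_norm(64, "group")
  expect_equal(unname(layer_n_params(gn)), c(128, 0))
})

test_that("model output contract holds for the improved configuration", {
  cfg <- seg_model_config(input_size = 32L, depth = 3L, base_filters = 4L)
  m <- unet_init(build_unet(cfg))
  set.seed(5)
  x <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  f <- unet_forward(m, x)
  expect_equal(dim(f$y), c(32L, 32L, 1L, 2L))
  expect_true(all(f$y >= 0 & f$y <= 1))
  expect_error(build_unet(seg_model_config(input_size = 30L, depth = 3L)),
               class = "bad_config")
})

test_that("norm swap moves counts between trainable and non-trainable only", {
  base <- function(norm, dil) seg_model_config(
    input_size = 64L, depth = 4L, base_filters = 8L, norm = norm,
    encoder_dilation = dil)
  pb <- count_parameters(build_unet(base("batch", 1L)))
  pg <- count_parameters(build_unet(base("group", 1L)))
  expect_equal(pb$trainable, pg$trainable)
  expect_equal(pg$non_trainable, 0)
  expect_gt(pb$non_trainable, 0)
  # dilation adds no parameters anywhere
  pd <- count_parameters(build_unet(base("group", 2L)))
  expect_identical(pg, pd)
})

test_that("architecture reconciliation recovers a planted configuration", {
  planted <- seg_model_config(input_size = 224L, depth = 4L,
                              base_filters = 32L, norm = "batch",
                              upsampling = "transposed_conv", up_kernel = 2L)
  target <- count_parameters(build_unet(planted))
  rec <- reconcile_architecture(target)
  expect_true(rec$matched)
  expect_equal(rec$config$depth, 4L)
  expect_equal(rec$config$base_filters, 32L)
  expect_equal(rec$config$upsampling, "transposed_conv")
  # non-trainable target pins the summed normalized channels (2 stats/channel)
  nt <- target$non_trainable
  surv <- rec$candidates[rec$candidates$non_trainable == nt, ]
  expect_true(all(surv$non_trainable / 2 == nt / 2))
  expect_error(reconcile_architecture(list(total = 1),
                                      search_space = data.frame()),
               class = "empty_search")
})

test_that("jaccard distance loss matches hand-derived values and bounds", {
  m <- matrix(c(1, 0, 1, 0), 2, 2)
  expect_equal(jaccard_distance_loss(m, m, smooth = 0), 0)
  a <- c(1, 0); b <- c(0, 1)
  expect_equal(jaccard_distance_loss(a, b, smooth = 0), 1)
  expect_equal(jaccard_distance_loss(c(1, 1, 0, 0), c(1, 0, 0, 0), smooth = 1),
               1 / 3, tolerance = 1e-12)
  set.seed(6)
  for (i in 1:50) {
    t <- rbinom(16, 1, 0.5)
    p <- runif(16)
    l <- jaccard_distance_loss(t, p, smooth = runif(1, 0, 100))
    expect_gte(l, 0); expect_lte(l, 1)
  }
  expect_error(jaccard_distance_loss(c(1, 0), c(0.5, 0.5, 0.5)),
               class = "shape_mismatch")
})

test_that("training is seed-deterministic and predictions are well-formed", {
  spec <- phantom_spec(image_size = 32L)
  set.seed(50)
  ds <- generate_dataset(spec, c(normal = 10, abnormal = 10), seed = 50)
  cfg <- seg_model_config(input_size = 32L, depth = 3L, base_filters = 2L)
  tcfg <- train_config(max_epochs = 2L, batch_size = 8L, seed = 77L)
  r1 <- train_segmenter(build_unet(cfg), ds$samples[1:14], ds$samples[15:20],
                        tcfg)
  r2 <- train_segmenter(build_unet(cfg), ds$samples[1:14], ds$samples[15:20],
                        tcfg)
  expect_identical(r1$history, r2$history)
  expect_named(r1$history, c("epoch", "train_loss", "val_loss", "val_dice"))
  p <- predict_mask(r1$model, ds$samples[1:3])
  expect_equal(dim(p), c(32L, 32L, 3L))
  expect_true(all(p >= 0 & p <= 1))
  expect_error(train_segmenter(build_unet(cfg), list(), list(), tcfg),
               class = "empty_data")
})

test_that("early stopping restores the best validation weights", {
  spec <- phantom_spec(image_size = 32L)
  set.seed(51)
  ds <- generate_dataset(spec, c(normal = 8, abnormal = 8), seed = 51)
  tcfg <- train_config(max_epochs = 6L, batch_size = 8L,
                       early_stop_patience = 2L, seed = 3L)
  r <- train_segmenter(build_unet(seg_model_config(input_size = 32L,
                                                   depth = 3L,
                                                   base_filters = 2L)),
                       ds$samples[1:12], ds$samples[13:16], tcfg)
  best_epoch <- which.min(r$history$val_loss)
  expect_lte(nrow(r$history), 6L)
  expect_lte(nrow(r$history) - best_epoch, 2L)
  # restored model reproduces the best recorded validation loss
  vl <- samples_to_xy(ds$samples[13:16])
  p <- unet_predict_array(r$model, vl$x)
  expect_equal(jaccard_distance_loss(vl$y, p, tcfg$smooth),
               min(r$history$val_loss), tolerance = 1e-9)
})
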