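test_that("single classifier outputs a probability simplex and sized head", {
  m2 <- build_single_classifier("ResNet50V2", 2L, 32L, seed = 1)
  m5 <- build_single_classifier("ResNet50V2", 5L, 32L, seed = 1)
  p2 <- count_parameters(m2)
  p5 <- count_parameters(m5)
  # only the final output layer changes with the class count
  fc2 <- layer_n_params(m2$head$layers$fc)["trainable"]
  fc5 <- layer_n_params(m5$head$layers$fc)["trainable"]
  expect_equal(p5$total - p2$total, unname(fc5 - fc2))
  expect_equal(p5$non_trainable, p2$non_trainable)
  set.seed(2)
  x <- array(runif(32 * 32 * 3 * 4), c(32, 32, 3, 4))
  m2$label_levels <- c("a", "b")
  probs <- predict_classifier(m2, x)
  expect_equal(dim(probs), c(4L, 2L))
  expect_equal(rowSums(probs), rep(1, 4), tolerance = 1e-6)
  expect_error(build_single_classifier("NoSuchNet", 2L),
               class = "unknown_backbone")
  expect_error(build_single_classifier("VGG16", 1L), class = "bad_config")
})

test_that("concat ensemble wires 8 backbones into the 256/64 head", {
  cfg <- concat_ensemble_config(n_classes = 3L, input_size = 32L)
  expect_length(cfg$backbones, 8L)
  ens <- build_concat_ensemble(cfg, seed = 3)
  D <- sum(vapply(ens$backbones, function(b)
    b$out_channels * b$out_spatial^2, 0))
  set.seed(4)
  x <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  f <- extract_features(ens, x)
  expect_equal(ncol(f), D)  # concatenated length = sum of flattened lengths
  # head-only closed-form accounting: D*256+256 + 2*256(affine) + 256*64+64
  # + 64*C+C trainable, plus 2*256 running stats non-trainable
  pc <- count_parameters(ens$head)
  expect_equal(pc$trainable,
               D * 256 + 256 + 2 * 256 + 256 * 64 + 64 + 64 * 3 + 3)
  expect_equal(pc$non_trainable, 2 * 256)
  # frozen backbones appear only in the non-trainable count
  full <- count_parameters(ens)
  bbp <- sum(vapply(ens$backbones, function(b)
    count_parameters(b)$total, 0))
  expect_equal(full$non_trainable, pc$non_trainable + bbp)
  expect_equal(full$trainable, pc$trainable)
  expect_error(concat_ensemble_config(backbones = list(backbone_spec("VGG16")),
                                      n_classes = 2L),
               class = "bad_config")
})

test_that("training never touches frozen backbone weights", {
  ds <- phantoms32(20L, seed = 8L)
  sp <- split_real(ds$samples, split_plan(seed = 8))
  ens <- build_concat_ensemble(concat_ensemble_config(n_classes = 2L,
                                                      input_size = 32L),
                               seed = 5)
  checksum <- function(m) sum(vapply(m$backbones, function(b)
    sum(vapply(b$layers, function(l)
      if (is.null(l$params)) 0 else sum(unlist(l$params)), 0)), 0))
  before <- checksum(ens)
  r <- train_classifier(ens, sp$train, sp$val,
                        clf_train_config(max_epochs = 3L, seed = 5L))
  expect_identical(checksum(r$model), before)
  # deterministic: identical seed, identical history
  r2 <- train_classifier(ens, sp$train, sp$val,
                         clf_train_config(max_epochs = 3L, seed = 5L))
  expect_identical(r$history, r2$history)
})

test_that("training errors are labeled for missing classes and empty data", {
  ds <- phantoms32(20L, seed = 8L)
  one_class <- Filter(function(s) s$label == "normal", ds$samples)
  m <- build_single_classifier("VGG16", 2L, 32L, seed = 1)
  expect_error(train_classifier(m, one_class[1:10], one_class[11:15],
                                clf_train_config(max_epochs = 1L)),
               class = "missing_class")
  expect_error(train_classifier(m, list(), list(), clf_train_config()),
               class = "empty_data")
})

test_that("majority vote matches a brute-force counter on all vote patterns", {
  expect_equal(majority_vote(matrix(c("A", "A", "B"), 1)), "A")
  expect_equal(majority_vote(matrix(c(0, 0, 1, 1, 1, 2, 2), 1)), 1)
  expect_equal(majority_vote(matrix(c(0, 0, 1, 1), 1)), 0)  # tie -> smallest
  # exhaustive 3-model, 3-class enumeration against an explicit counter
  grid <- expand.grid(m1 = 0:2, m2 = 0:2, m3 = 0:2)
  got <- majority_vote(as.matrix(grid))
  oracle <- apply(as.matrix(grid), 1, function(r) {
    counts <- sapply(0:2, function(k) sum(r == k))
    (0:2)[which(counts == max(counts))][1]  # first (= smallest) max
  })
  expect_equal(as.numeric(got), as.numeric(oracle))
  expect_error(majority_vote(matrix(numeric(0), 0, 0)), class = "empty_votes")
})

test_that("voting is permutation-invariant and unanimity-preserving", {
  set.seed(9)
  votes <- matrix(sample(0:3, 50 * 7, TRUE), 50, 7)
  base <- majority_vote(votes)
  perm <- votes[, sample(7)]
  expect_equal(majority_vote(perm), base)
  unan <- matrix(2, 10, 7)
  expect_true(all(majority_vote(unan) == 2))
})

test_that("argmax labels agree with a brute-force row maximum", {
  m <- build_single_classifier("Xception", 3L, 32L, seed = 11)
  m$label_levels <- c("x", "y", "z")
  set.seed(12)
  imgs <- array(runif(32 * 32 * 3 * 6), c(32, 32, 3, 6))
  p <- predict_classifier(m, imgs)
  lab <- predict_labels(m, imgs)
  for (i in 1:6)
    expect_equal(lab[i], c("x", "y", "z")[which.max(p[i, ])])
})
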