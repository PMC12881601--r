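test_that("real split sizes follow half-up rounding of the plan fractions", {
  s100 <- split_real(dummy_samples(100, rep(c("a", "b"), 50)), split_plan(seed = 1))
  expect_equal(vapply(s100, length, 0L),
               c(train = 64L, val = 16L, test = 20L))
  # cohort sizes whose test splits match the published confusion totals
  s419 <- split_real(dummy_samples(419, rep(c("a", "b"), length.out = 419)),
                     split_plan(seed = 2))
  expect_length(s419$test, 84L)  # 82 correct + 2 misclassified
  s4049 <- split_real(dummy_samples(4049, rep(c("a", "b"), length.out = 4049)),
                      split_plan(seed = 3))
  expect_length(s4049$test, 810L)  # 800 correct + 10 misclassified
})

test_that("splits are disjoint, exhaustive, stratified, and seed-deterministic", {
  labs <- rep(c("a", "b", "c"), times = c(30, 21, 9))
  samples <- dummy_samples(60, labs)
  a <- split_real(samples, split_plan(seed = 9))
  b <- split_real(samples, split_plan(seed = 9))
  expect_identical(a, b)
  ids <- function(part) vapply(part, function(s) s$meta$id, 0)
  all_ids <- sort(c(ids(a$train), ids(a$val), ids(a$test)))
  expect_identical(all_ids, as.numeric(1:60))  # exhaustive, disjoint
  # class proportions preserved within one sample per class
  for (part in a) {
    tab <- table(factor(vapply(part, `[[`, "", "label"), c("a", "b", "c")))
    expected <- length(part) * c(30, 21, 9) / 60
    expect_true(all(abs(tab - expected) <= 1))
  }
  expect_error(split_real(dummy_samples(8, c(rep("a", 6), "b", "b")),
                          split_plan(seed = 1)),
               class = "too_few_samples")
})

test_that("generated split is 80/20 half-up with no test partition", {
  g10 <- split_generated(dummy_samples(10), split_plan(seed = 1))
  expect_equal(vapply(g10, length, 0L), c(train = 8L, val = 2L))
  g0 <- split_generated(list(), split_plan(seed = 1))
  expect_equal(vapply(g0, length, 0L), c(train = 0L, val = 0L))
  g901 <- split_generated(dummy_samples(901), split_plan(seed = 1))
  expect_length(g901$train, 721L)  # round(0.8 * 901)
  expect_length(g901$val, 180L)
  expect_null(g901$test)
})

test_that("mixing follows the placement/stage table and protects the test set", {
  real <- split_real(dummy_samples(100, rep(c("a", "b"), 50)),
                     split_plan(seed = 4))
  gen <- split_generated(dummy_samples(100), split_plan(seed = 4))
  # none: passthrough
  m <- mix_for_stage(real, gen, mix_policy("none"), "segmentation")
  expect_identical(m, list(train = real$train, val = real$val,
                           test = real$test))
  # before segmentation: unions at the segmentation stage
  m <- mix_for_stage(real, gen, mix_policy("before_segmentation"),
                     "segmentation")
  expect_length(m$train, 144L)
  expect_length(m$val, 36L)
  expect_length(m$test, 20L)
  # before segmentation also augments downstream classification
  m2 <- mix_for_stage(real, gen, mix_policy("before_segmentation"),
                      "classification")
  expect_length(m2$train, 144L)
  # after segmentation: classification only
  expect_length(mix_for_stage(real, gen, mix_policy("after_segmentation"),
                              "segmentation")$train, 64L)
  expect_length(mix_for_stage(real, gen, mix_policy("after_segmentation"),
                              "classification")$train, 144L)
  # test hygiene: every mixed test set is the real test set
  for (pl in c("none", "before_segmentation", "after_segmentation"))
    for (st in c("segmentation", "classification")) {
      mm <- mix_for_stage(real, gen, mix_policy(pl), st)
      expect_identical(mm$test, real$test)
      expect_true(all(vapply(mm$test, function(s)
        is.null(s$origin) || s$origin == "real", TRUE)))
    }
  expect_error(mix_for_stage(real, list(test = dummy_samples(1)),
                             mix_policy("none"), "segmentation"),
               class = "generated_in_test")
})
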