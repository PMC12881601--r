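test_that("phantom generation is deterministic and respects the palette", {
  spec <- phantom_spec(image_size = 48L, noise_sd = 0, blur_sigma = 0)
  set.seed(7); a <- generate_cell_image(spec, "abnormal")
  set.seed(7); b <- generate_cell_image(spec, "abnormal")
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  # no noise, no blur: exactly the three palette colors appear
  cols <- unique(apply(matrix(a$image, ncol = 3), 1, paste, collapse = ","))
  expect_length(cols, 3L)
  expect_true(all(a$mask %in% c(0, 1)))
  expect_true(all(a$image >= 0 & a$image <= 1))
  # mask is exactly the union of cytoplasm and nucleus pixels
  expect_identical(a$mask, matrix(as.numeric(a$regions > 0), 48, 48))
})

test_that("measured nucleus-to-cell ratios stay inside their class intervals", {
  spec <- phantom_spec(image_size = 96L,
                       nc_ratio_by_class = list(normal = c(0.05, 0.15),
                                                abnormal = c(0.5, 0.7)))
  set.seed(11)
  for (cl in c("normal", "abnormal")) {
    iv <- spec$nc_ratio_by_class[[cl]]
    for (i in 1:50) {
      s <- generate_cell_image(spec, cl)
      measured <- sum(s$regions == 2) / sum(s$mask == 1)  # pixel-count oracle
      expect_gte(measured, iv[1])
      expect_lte(measured, iv[2])
    }
  }
})

test_that("disjoint ratio intervals make phantoms threshold-separable", {
  ds <- phantoms32(30L, seed = 5L)
  ratios <- vapply(ds$samples, function(s)
    sum(s$regions == 2) / sum(s$mask == 1), 0)
  labs <- vapply(ds$samples, `[[`, "", "label")
  pred <- ifelse(ratios > 0.3, "abnormal", "normal")
  expect_identical(pred, labs)  # 100% separable by a single threshold
})

test_that("generate_dataset conserves per-class counts and manifests", {
  spec <- phantom_spec(image_size = 32L)
  ds <- generate_dataset(spec, c(normal = 10, abnormal = 10), seed = 3)
  expect_length(ds$samples, 20L)
  expect_equal(unname(table(ds$manifest$label)["normal"]), 10,
               ignore_attr = TRUE)
  # Per-class counts mirroring a scaled-down three-class screening cohort
  spec3 <- phantom_spec(image_size = 32L, nc_ratio_by_class = list(
    HSIL = c(0.5, 0.7), LSIL = c(0.25, 0.4), NSIL = c(0.05, 0.15)))
  ds3 <- generate_dataset(spec3, c(HSIL = 12, LSIL = 6, NSIL = 24), seed = 4)
  expect_length(ds3$samples, 42L)
  expect_equal(as.vector(table(factor(ds3$manifest$label,
                                      c("HSIL", "LSIL", "NSIL")))),
               c(12, 6, 24))
  # empty class allowed; empty roster is not
  e <- generate_dataset(spec, c(normal = 0), seed = 1)
  expect_length(e$samples, 0L)
  expect_equal(nrow(e$manifest), 0L)
  expect_error(generate_dataset(spec, list(), seed = 1), class = "empty_counts")
  expect_error(generate_cell_image(spec, "nope"), class = "unknown_label")
})

test_that("identical (spec, counts, seed) give identical datasets", {
  spec <- phantom_spec(image_size = 32L)
  a <- generate_dataset(spec, c(normal = 4, abnormal = 4), seed = 12)
  b <- generate_dataset(spec, c(normal = 4, abnormal = 4), seed = 12)
  expect_identical(a$samples, b$samples)
  expect_identical(a$manifest, b$manifest)
})

test_that("color region masks round-trip to the binary mask", {
  spec <- phantom_spec(image_size = 32L)
  set.seed(20)
  for (i in 1:20) {
    s <- generate_cell_image(spec, sample(c("normal", "abnormal"), 1))
    cm <- write_herlev_style_mask(s)
    expect_identical(color_mask_to_binary(cm, c(0, 0, 0)), s$mask)
    ncol_distinct <- length(unique(apply(matrix(cm, ncol = 3), 1,
                                         paste, collapse = ",")))
    expect_equal(ncol_distinct, 3L)
  }
  expect_error(write_herlev_style_mask(s, list(background = c(1, 2, 3),
                                               cytoplasm = c(1, 2, 3),
                                               nucleus = c(0, 0, 0))),
               class = "palette_collision")
})
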