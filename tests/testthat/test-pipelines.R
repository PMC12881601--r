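tiny_cfg <- function(name, seed = 9L, clf_modes = "single_resnet") {
  pipeline_config(
    name, input_size = 32L,
    seg = seg_model_config(input_size = 32L, depth = 3L, base_filters = 4L),
    seg_train = train_config(max_epochs = 2L, batch_size = 8L, seed = seed),
    gan = if (grepl("RES_DCGAN", name))
      gan_settings(image_size = 32L, per_class = 8L, steps = 8L,
                   batch_size = 8L),
    clf_modes = clf_modes,
    clf_train = clf_train_config(max_epochs = 6L, seed = seed),
    split = split_plan(seed = seed), seed = seed)
}

test_that("a pipeline run produces a complete report on 60 phantoms", {
  ds <- phantoms32(30L, seed = 9L)  # 60 samples
  rep <- run_pipeline(tiny_cfg("ROI"), ds)
  expect_s3_class(rep, "run_report")
  expect_equal(rep$pipeline, "ROI")
  expect_s3_class(rep$seg, "seg_metric_report")
  expect_true(all(unlist(rep$seg[c("accuracy", "dice", "iou")]) >= 0))
  expect_named(rep$clf, "single_resnet")
  expect_s3_class(rep$clf$single_resnet, "clf_metric_report")
  expect_true(all(c("seed", "n_real", "seg_config", "manifest_hash") %in%
                    names(rep$provenance)))
  expect_equal(unname(rep$provenance$n_real["test"]), 12L)  # 20% of 60
})

test_that("config/pipeline mismatches and missing masks are labeled errors", {
  expect_error(tiny_cfg("Normal", clf_modes = "nope"), class = "bad_config")
  expect_error(pipeline_config("Mystery", input_size = 32L),
               class = "bad_pipeline")
  expect_error(pipeline_config("Normal", input_size = 32L,
                               seg = seg_model_config(input_size = 32L,
                                                      depth = 3L),
                               gan = gan_settings()),
               class = "bad_config")
  expect_error(pipeline_config("RES_DCGAN_Nor", input_size = 32L,
                               seg = seg_model_config(input_size = 32L,
                                                      depth = 3L)),
               class = "bad_config")
  ds <- phantoms32(30L, seed = 9L)
  nomask <- lapply(ds$samples, function(s) { s$mask <- NULL; s })
  expect_error(run_pipeline(tiny_cfg("Normal"), nomask),
               class = "missing_masks")
})

test_that("pipelines sharing a segmentation stage report identical seg scores", {
  ds <- phantoms32(30L, seed = 10L)
  cache <- new.env()
  r1 <- run_pipeline(tiny_cfg("Normal", seed = 4L), ds, cache = cache)
  r2 <- run_pipeline(tiny_cfg("ROI", seed = 4L), ds, cache = cache)
  expect_identical(unclass(r1$seg), unclass(r2$seg))
  # and the comparison table deduplicates the shared row
  cmp <- compare_pipelines(list(tiny_cfg("Normal", seed = 4L),
                                tiny_cfg("ROI", seed = 4L)), ds)
  expect_equal(nrow(cmp$table), 2L)
  expect_false(is.na(cmp$table$seg_dice[1]))
  expect_true(is.na(cmp$table$seg_dice[2]))
  expect_true(all(c("single_resnet_acc", "single_resnet_f1") %in%
                    names(cmp$table)))
})

test_that("reruns with the same seed reproduce the comparison table", {
  ds <- phantoms32(30L, seed = 11L)
  t1 <- compare_pipelines(list(tiny_cfg("Normal", seed = 6L)), ds)$table
  t2 <- compare_pipelines(list(tiny_cfg("Normal", seed = 6L)), ds)$table
  expect_identical(t1, t2)
})

test_that("the CLI covers simulate / pipeline / compare round trips", {
  d <- withr::local_tempdir()
  dsdir <- file.path(d, "ds")
  cfgf <- file.path(d, "tiny.yaml")
  yaml::write_yaml(list(
    input_size = 32L,
    seg = list(depth = 3L, base_filters = 4L),
    seg_train = list(max_epochs = 1L, batch_size = 8L),
    clf_train = list(max_epochs = 4L),
    gan = list(steps = 6L, per_class = 6L, batch_size = 8L),
    clf_modes = "single_resnet"), cfgf)
  expect_equal(cli_entry(c("simulate", "--out", dsdir, "--classes",
                           "normal:20,abnormal:20", "--size", "32",
                           "--seed", "1")), 0L, ignore_attr = TRUE)
  expect_true(file.exists(file.path(dsdir, "manifest.csv")))
  # identical seeds give identical datasets
  ds2 <- file.path(d, "ds2")
  cli_entry(c("simulate", "--out", ds2, "--classes",
              "normal:20,abnormal:20", "--size", "32", "--seed", "1"))
  f <- "normal_0003.png"
  expect_identical(readBin(file.path(dsdir, f), "raw", 1e6),
                   readBin(file.path(ds2, f), "raw", 1e6))
  run <- file.path(d, "run")
  expect_equal(cli_entry(c("pipeline", "--name", "Normal", "--data", dsdir,
                           "--config", cfgf, "--seed", "7", "--out", run)),
               0L, ignore_attr = TRUE)
  rep <- jsonlite::read_json(file.path(run, "run_report.json"))
  expect_equal(rep$pipeline, "Normal")
  expect_true(file.exists(file.path(run, "config_snapshot.yaml")))
  cmp <- file.path(d, "cmp")
  expect_equal(cli_entry(c("compare", "--pipelines", "Normal,ROI", "--data",
                           dsdir, "--config", cfgf, "--seed", "7", "--out",
                           cmp)), 0L, ignore_attr = TRUE)
  tab <- read.csv(file.path(cmp, "comparison.csv"))
  expect_equal(tab$pipeline, c("Normal", "ROI"))
  # unknown commands and missing flags exit non-zero
  expect_equal(suppressMessages(cli_entry(c("frobnicate"))), 1L,
               ignore_attr = TRUE)
  expect_equal(suppressMessages(cli_entry(c("simulate"))), 1L,
               ignore_attr = TRUE)
})
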