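# The six end-to-end pipelines and their comparison table.
#
#   Normal          segment, then classify the (non-masked) stage images
#   Nor_RES_DCGAN   segment; GAN-augment the classification train/val sets
#   ROI             segment; classify mask x image products
#   ROI_RES_DCGAN   segment; GAN-augment the ROI classification sets
#   RES_DCGAN_Nor   GAN-augment the segmentation train/val sets (generated
#                   images receive automatic pseudo-masks), segment, classify
#   RES_DCGAN_ROI   same augmented segmentation stage, classify ROI products
#
# Augmentation placed before segmentation also reaches the downstream
# classification training sets; the test split is always real-only, and
# pipelines differing only downstream of segmentation reuse the identical
# trained segmenter for the same seed.

PIPELINE_NAMES <- c("Normal", "Nor_RES_DCGAN", "ROI", "ROI_RES_DCGAN",
                    "RES_DCGAN_Nor", "RES_DCGAN_ROI")

pipeline_placement <- function(name) {
  switch(name,
         Normal = , ROI = "none",
         Nor_RES_DCGAN = , ROI_RES_DCGAN = "after_segmentation",
         RES_DCGAN_Nor = , RES_DCGAN_ROI = "before_segmentation")
}

pipeline_clf_input <- function(name) {
  if (name %in% c("ROI", "ROI_RES_DCGAN", "RES_DCGAN_ROI")) "roi" else "original"
}

#' Pipeline configuration
#'
#' Bundles every stage configuration under one master seed. GAN settings are
#' required exactly for the RES_DCGAN pipelines. All stage seeds are derived
#' from `seed`, so a report is reproducible from its recorded configuration
#' alone.
#'
#' @param pipeline one of the six pipeline names.
#' @param input_size working image size for segmentation/classification.
#' @param seg a [seg_model_config()] (built at `input_size`).
#' @param seg_train a [train_config()].
#' @param gan list with generator/discriminator/training settings:
#'   `latent_dim`, `seed_spatial`, `stage_filters`, `disc_filters`,
#'   `steps`, `batch_size`, `per_class` (generated images per class).
#' @param clf_modes classifier modes to run: subset of
#'   `"single_resnet"`, `"voting"`, `"concat_ensemble"`.
#' @param clf_train a [clf_train_config()].
#' @param split a [split_plan()].
#' @param normal_input classification input of the non-ROI pipelines:
#'   `"original"` (default), `"predicted_mask"` or `"overlay"`.
#' @param seed master seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(pipeline, input_size = 224L,
                            seg = NULL, seg_train = train_config(),
                            gan = NULL, clf_modes = "single_resnet",
                            clf_train = clf_train_config(),
                            split = split_plan(),
                            normal_input = c("original", "predicted_mask",
                                             "overlay"),
                            seed = 1L) {
  if (!pipeline %in% PIPELINE_NAMES)
    dc_stop("bad_pipeline", "unknown pipeline: ", pipeline)
  needs_gan <- grepl("RES_DCGAN", pipeline)
  if (needs_gan && is.null(gan))
    dc_stop("bad_config", "pipeline ", pipeline, " requires gan settings")
  if (!needs_gan && !is.null(gan))
    dc_stop("bad_config", "pipeline ", pipeline, " takes no gan settings")
  if (is.null(seg)) seg <- seg_model_config(input_size = input_size)
  if (seg$input_size != input_size)
    dc_stop("bad_config", "seg config input_size must equal input_size")
  bad <- setdiff(clf_modes, c("single_resnet", "voting", "concat_ensemble"))
  if (length(bad)) dc_stop("bad_config", "unknown clf mode: ", bad[1])
  structure(list(pipeline = pipeline, input_size = as.integer(input_size),
                 seg = seg, seg_train = seg_train, gan = gan,
                 clf_modes = clf_modes, clf_train = clf_train, split = split,
                 normal_input = match.arg(normal_input),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Desk-scale GAN settings for pipeline runs
#'
#' @param image_size GAN working size (divisible by 32).
#' @param per_class generated images per class.
#' @param steps adversarial steps per class.
#' @param batch_size,latent_dim scalars.
#' @return list consumable by [pipeline_config()]'s `gan` argument.
#' @export
gan_settings <- function(image_size = 32L, per_class = 40L, steps = 60L,
                         batch_size = 16L, latent_dim = 32L) {
  stages <- as.integer(log2(image_size / 2))
  list(latent_dim = as.integer(latent_dim), seed_spatial = 2L,
       stage_filters = as.integer(8L * 2^((stages - 1):0)),
       disc_filters = c(8L, 16L, 24L, 32L, 48L),
       image_size = as.integer(image_size),
       per_class = as.integer(per_class), steps = as.integer(steps),
       batch_size = as.integer(batch_size))
}

resize_sample <- function(s, target) {
  s$image <- resize_normalize(s$image, target)
  if (!is.null(s$mask)) s$mask <- resize_mask(s$mask, target)
  s
}

resize_samples <- function(samples, target)
  lapply(samples, resize_sample, target = target)

# Train per-class GANs on `samples` and return generated labeled samples
# (with pseudo-masks) plus per-class Frechet scores.
gan_augment <- function(samples, gan, seed, input_size) {
  labs <- sample_labels(samples)
  classes <- sort(unique(labs))
  gen_samples <- list()
  fid <- setNames(numeric(length(classes)), classes)
  emb <- fid_embedding()
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    imgs <- samples_to_x(resize_samples(samples[labs == cl], gan$image_size))
    gcfg <- generator_config(latent_dim = gan$latent_dim,
                             seed_spatial = gan$seed_spatial,
                             stage_filters = gan$stage_filters)
    dcfg <- discriminator_config(input_size = gan$image_size,
                                 layer_filters = gan$disc_filters)
    set.seed(seed + ci)
    gen <- build_generator(gcfg)
    disc <- build_discriminator(dcfg)
    tr <- train_gan(gen, disc, imgs,
                    gan_train_config(batch_size = gan$batch_size,
                                     steps = gan$steps, seed = seed + ci))
    out <- sample_images(tr$generator, gan$per_class, seed = seed + 100L + ci)
    fid[cl] <- compute_fid(imgs, out, emb)$value
    for (k in seq_len(dim(out)[4])) {
      img <- resize_normalize(out[, , , k], input_size)
      msk <- suppressWarnings(threshold_mask_from_image(img))
      gen_samples[[length(gen_samples) + 1L]] <-
        structure(list(image = img, mask = msk, label = cl,
                       origin = "generated",
                       meta = list(pseudo_mask = TRUE, class = cl)),
                  class = "labeled_sample")
    }
  }
  list(samples = gen_samples, fid = fid)
}

roi_transform <- function(samples, seg_model) {
  if (length(samples) == 0) return(samples)
  x <- samples_to_x(samples)
  p <- unet_predict_array(seg_model, x)
  for (i in seq_along(samples)) {
    m <- binarize_prediction(matrix(p[, , 1, i], dim(p)[1], dim(p)[2]))
    samples[[i]]$image <- apply_roi(samples[[i]]$image, m)
  }
  samples
}

normal_transform <- function(samples, seg_model, mode) {
  if (mode == "original" || length(samples) == 0) return(samples)
  x <- samples_to_x(samples)
  p <- unet_predict_array(seg_model, x)
  for (i in seq_along(samples)) {
    m <- binarize_prediction(matrix(p[, , 1, i], dim(p)[1], dim(p)[2]))
    if (mode == "predicted_mask") {
      samples[[i]]$image <- array(rep(m, 3), c(dim(m), 3))
    } else {  # overlay: keep the image, brighten the predicted cell region
      samples[[i]]$image <- pmin(samples[[i]]$image * (0.5 + 0.5 *
        array(rep(m, 3), c(dim(m), 3))) + 0, 1)
    }
  }
  samples
}

#' Run one pipeline end-to-end
#'
#' Splits the data, optionally trains per-class GAN augmentors, trains the
#' segmenter and the requested classifiers, and evaluates everything on the
#' real test split only. Pipelines sharing an identical segmentation stage
#' and seed reuse the cached trained segmenter when a shared `cache`
#' environment is supplied (as [compare_pipelines()] does).
#'
#' @param cfg a [pipeline_config()].
#' @param data list of labeled samples, or a list with `$samples`.
#' @param cache optional environment for cross-pipeline stage reuse.
#' @param verbose print stage progress.
#' @return a `run_report`: pipeline name, `seg` metric report, `clf` reports
#'   per mode, per-class `fid` (GAN pipelines), and `provenance`.
#' @export
run_pipeline <- function(cfg, data, cache = NULL, verbose = FALSE) {
  samples <- if (!is.null(data$samples)) data$samples else data
  if (length(samples) == 0) dc_stop("empty_data", "no samples")
  if (is.null(samples[[1]]$mask)) dc_stop("missing_masks", "samples lack masks")
  say <- function(...) if (verbose) message("[", cfg$pipeline, "] ", ...)
  samples <- resize_samples(samples, cfg$input_size)
  real <- split_real(samples, cfg$split)
  policy <- mix_policy(pipeline_placement(cfg$pipeline))
  fid <- NULL
  gen_split <- list(train = list(), val = list())

  if (policy$placement == "before_segmentation") {
    say("training per-class GANs (pre-segmentation augmentation)")
    aug <- gan_augment(c(real$train, real$val), cfg$gan, cfg$seed + 20L,
                       cfg$input_size)
    fid <- aug$fid
    gen_split <- split_generated(aug$samples, cfg$split)
  }

  seg_sets <- mix_for_stage(real, gen_split, policy, "segmentation")
  seg_key <- paste0("seg|", policy$placement == "before_segmentation", "|",
                    cfg$seed, "|", cfg$seg$norm, "|", cfg$seg$base_filters,
                    "|", cfg$seg$depth, "|", length(seg_sets$train))
  seg_model <- if (!is.null(cache) && !is.null(cache[[seg_key]])) {
    say("reusing cached segmenter")
    cache[[seg_key]]
  } else {
    say("training segmenter on ", length(seg_sets$train), " samples")
    scfg <- cfg$seg_train; scfg$seed <- cfg$seed + 1L
    m <- train_segmenter(build_unet(cfg$seg), seg_sets$train, seg_sets$val,
                         scfg)$model
    if (!is.null(cache)) cache[[seg_key]] <- m
    m
  }

  te <- samples_to_xy(real$test)
  pr <- unet_predict_array(seg_model, te$x)
  seg_rep <- seg_metrics(pixel_confusion(te$y, binarize_prediction(pr)))
  say(sprintf("segmentation test dice %.3f", seg_rep$dice))

  if (policy$placement == "after_segmentation") {
    base <- if (pipeline_clf_input(cfg$pipeline) == "roi")
      roi_transform(c(real$train, real$val), seg_model)
    else c(real$train, real$val)
    say("training per-class GANs (post-segmentation augmentation)")
    aug <- gan_augment(base, cfg$gan, cfg$seed + 20L, cfg$input_size)
    fid <- aug$fid
    gen_split <- split_generated(aug$samples, cfg$split)
  }

  transform_clf <- function(ss, generated = FALSE) {
    if (pipeline_clf_input(cfg$pipeline) == "roi") {
      # post-segmentation generated images are already ROI products
      if (generated && policy$placement == "after_segmentation") ss
      else roi_transform(ss, seg_model)
    } else normal_transform(ss, seg_model, cfg$normal_input)
  }
  real_clf <- list(train = transform_clf(real$train),
                   val = transform_clf(real$val),
                   test = transform_clf(real$test))
  gen_clf <- list(train = transform_clf(gen_split$train, generated = TRUE),
                  val = transform_clf(gen_split$val, generated = TRUE))
  clf_sets <- mix_for_stage(real_clf, gen_clf, policy, "classification")
  stopifnot(all(vapply(clf_sets$test,
                       function(s) (s$origin %||% "real") == "real", TRUE)))

  n_classes <- length(unique(sample_labels(samples)))
  true_test <- sample_labels(clf_sets$test)
  clf <- list()
  for (mode in cfg$clf_modes) {
    say("training classifier: ", mode)
    ccfg <- cfg$clf_train; ccfg$seed <- cfg$seed + 3L
    pred <- switch(mode,
      single_resnet = {
        m <- build_single_classifier("ResNet50V2", n_classes, cfg$input_size,
                                     seed = cfg$seed + 4L)
        m <- train_classifier(m, clf_sets$train, clf_sets$val, ccfg)$model
        predict_labels(m, clf_sets$test)
      },
      voting = {
        v <- train_voting_ensemble(voting_config(), n_classes, cfg$input_size,
                                   clf_sets$train, clf_sets$val, ccfg)
        predict_voting(v, clf_sets$test)
      },
      concat_ensemble = {
        m <- build_concat_ensemble(
          concat_ensemble_config(n_classes = n_classes,
                                 input_size = cfg$input_size),
          seed = cfg$seed + 4L)
        m <- train_classifier(m, clf_sets$train, clf_sets$val, ccfg)$model
        predict_labels(m, clf_sets$test)
      })
    clf[[mode]] <- clf_metrics(true_test, pred)
    say(sprintf("%s test accuracy %.3f", mode, clf[[mode]]$accuracy))
  }

  structure(list(
    pipeline = cfg$pipeline, seg = seg_rep, clf = clf, fid = fid,
    seg_key = seg_key,
    provenance = list(
      seed = cfg$seed, input_size = cfg$input_size,
      n_total = length(samples),
      n_real = c(train = length(real$train), val = length(real$val),
                 test = length(real$test)),
      n_generated = c(train = length(gen_split$train),
                      val = length(gen_split$val)),
      seg_config = unclass(cfg$seg), seg_train = unclass(cfg$seg_train),
      clf_train = unclass(cfg$clf_train), split = unclass(cfg$split),
      manifest_hash = sprintf("%d:%.6f", length(samples),
                              sum(vapply(samples, function(s)
                                mean(s$image), 0))))),
    class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline:", x$pipeline, "\n")
  print(x$seg)
  for (m in names(x$clf)) { cat(sprintf("%-16s ", m)); print(x$clf[[m]]) }
  if (!is.null(x$fid))
    cat("FID per class:", paste(sprintf("%s=%.3f", names(x$fid), x$fid),
                                collapse = "  "), "\n")
  invisible(x)
}

#' Compare pipelines on one dataset
#'
#' Runs every configuration (sharing trained segmentation stages across
#' pipelines with identical stage + seed) and assembles the comparison
#' table: one row per pipeline, segmentation columns (Acc/Pre/Rec/Dice/IoU)
#' and one classification column group (Acc/Pre/Rec/F1) per classifier mode.
#' Segmentation scores of pipelines sharing a stage are reported once
#' (subsequent rows carry NA), mirroring how such tables are usually
#' deduplicated.
#'
#' @param cfgs list of [pipeline_config()]s.
#' @param data labeled samples.
#' @param verbose print stage progress.
#' @return list with `table` (data frame) and `reports` (run reports).
#' @export
compare_pipelines <- function(cfgs, data, verbose = FALSE) {
  if (length(cfgs) == 0) dc_stop("bad_config", "need at least one config")
  cache <- new.env(parent = emptyenv())
  reports <- lapply(cfgs, run_pipeline, data = data, cache = cache,
                    verbose = verbose)
  seen <- character(0)
  rows <- lapply(reports, function(r) {
    first <- !(r$seg_key %in% seen)
    seen <<- c(seen, r$seg_key)
    row <- data.frame(pipeline = r$pipeline,
                      seg_acc = if (first) 100 * r$seg$accuracy else NA,
                      seg_pre = if (first) 100 * r$seg$precision else NA,
                      seg_rec = if (first) 100 * r$seg$recall else NA,
                      seg_dice = if (first) 100 * r$seg$dice else NA,
                      seg_iou = if (first) 100 * r$seg$iou else NA)
    for (m in names(r$clf)) {
      cr <- r$clf[[m]]
      row[[paste0(m, "_acc")]] <- 100 * cr$accuracy
      row[[paste0(m, "_pre")]] <- 100 * cr$precision
      row[[paste0(m, "_rec")]] <- 100 * cr$recall
      row[[paste0(m, "_f1")]] <- 100 * cr$f1
    }
    row
  })
  list(table = do.call(rbind, rows), reports = reports)
}
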