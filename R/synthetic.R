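# Synthetic Pap-smear-like phantoms: one stained cell per frame, an elliptical
# cytoplasm with an interior elliptical nucleus, a pixel-aligned binary
# whole-cell mask, and a class label driven by the nucleus-to-cytoplasm (N/C)
# area ratio. Elevated N/C is the morphological hallmark of abnormality, so
# disjoint per-class ratio intervals give every downstream stage a learnable,
# verifiable signal.

#' Phantom generation specification
#'
#' @param image_size pixels per side (>= 32).
#' @param cytoplasm_radius_range semi-major axis range as a fraction of the
#'   image size; must keep the whole cell inside the frame.
#' @param nc_ratio_by_class named list mapping class label to a
#'   nucleus-to-cell area-ratio interval, each inside (0,1).
#' @param stain_palette named list of RGB triples in \[0,1\] for `background`,
#'   `cytoplasm`, `nucleus`; defaults imitate a Papanicolaou-stained crop
#'   (pale background, cyan-pink cytoplasm, dark purple nucleus).
#' @param noise_sd additive Gaussian noise standard deviation (\[0,1\] units).
#' @param blur_sigma Gaussian blur sigma in pixels (0 disables).
#' @param seed default seed used by [generate_dataset()].
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(image_size = 96L,
                         cytoplasm_radius_range = c(0.24, 0.40),
                         nc_ratio_by_class = list(normal = c(0.05, 0.15),
                                                  abnormal = c(0.50, 0.70)),
                         stain_palette = list(
                           background = c(0.93, 0.92, 0.95),
                           cytoplasm = c(0.55, 0.76, 0.86),
                           nucleus = c(0.26, 0.16, 0.44)),
                         noise_sd = 0.03, blur_sigma = 0.8, seed = 1L) {
  image_size <- as.integer(image_size)
  if (image_size < 32L) dc_stop("bad_spec", "image_size must be >= 32")
  if (cytoplasm_radius_range[2] > 0.45)
    dc_stop("bad_spec", "cytoplasm radius range must keep the cell in frame")
  if (length(nc_ratio_by_class) == 0)
    dc_stop("bad_spec", "at least one class interval required")
  for (cl in names(nc_ratio_by_class)) {
    iv <- nc_ratio_by_class[[cl]]
    if (iv[1] <= 0 || iv[2] >= 1 || iv[1] >= iv[2])
      dc_stop("bad_spec", "nc interval for class '", cl, "' must be inside (0,1)")
  }
  structure(list(image_size = image_size,
                 cytoplasm_radius_range = cytoplasm_radius_range,
                 nc_ratio_by_class = nc_ratio_by_class,
                 stain_palette = stain_palette,
                 noise_sd = noise_sd, blur_sigma = blur_sigma,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate one labeled phantom cell image
#'
#' Draws a rotated elliptical cytoplasm with an interior elliptical nucleus
#' whose area is a class-specific fraction of the cell area, paints the three
#' regions with the stain palette, then optionally blurs and adds noise.
#' Deterministic given the R random stream state (use `set.seed()`); the
#' emitted mask is exactly the union of cytoplasm and nucleus pixels.
#'
#' @param spec a [phantom_spec()].
#' @param label class label; must be a key of `spec$nc_ratio_by_class`.
#' @return a `labeled_sample`: list with `image` (H x W x 3, \[0,1\]), `mask`
#'   (H x W, \{0,1\}), `regions` (0 = background, 1 = cytoplasm, 2 = nucleus),
#'   `label`, and `meta` (the parameters actually drawn).
#' @export
generate_cell_image <- function(spec, label) {
  iv <- spec$nc_ratio_by_class[[label]]
  if (is.null(iv)) dc_stop("unknown_label", "unknown class label: ", label)
  S <- spec$image_size
  rr <- spec$cytoplasm_radius_range
  a <- runif(1, rr[1], rr[2]) * S
  b <- a * runif(1, 0.75, 1)
  theta <- runif(1, 0, pi)
  cx <- S / 2 + runif(1, -0.04, 0.04) * S
  cy <- S / 2 + runif(1, -0.04, 0.04) * S
  # draw the target ratio away from the interval edges so that pixelation
  # cannot push the measured ratio outside the class interval
  m <- 0.15 * (iv[2] - iv[1])
  ratio <- runif(1, iv[1] + m, iv[2] - m)
  s <- sqrt(ratio)
  q <- runif(1, 0.96, 1.04)           # mild nucleus aspect jitter, area-exact
  a1 <- s * a * q; b1 <- s * b / q
  if (a1 >= a || b1 >= b)
    dc_stop("infeasible_geometry",
            "nc interval forces the nucleus outside the cytoplasm")
  u <- runif(1, -1, 1) * 0.6 * (a - a1)
  v <- runif(1, -1, 1) * 0.6 * (b - b1)
  xg <- matrix(rep(seq_len(S) - 0.5, each = S), S, S)   # column coord
  yg <- matrix(rep(seq_len(S) - 0.5, times = S), S, S)  # row coord
  dx <- xg - cx; dy <- yg - cy
  xr <- cos(theta) * dx + sin(theta) * dy
  yr <- -sin(theta) * dx + cos(theta) * dy
  in_cyt <- (xr / a)^2 + (yr / b)^2 <= 1
  in_nuc <- ((xr - u) / a1)^2 + ((yr - v) / b1)^2 <= 1
  regions <- matrix(0L, S, S)
  regions[in_cyt] <- 1L
  regions[in_cyt & in_nuc] <- 2L
  pal <- spec$stain_palette
  img <- array(0, c(S, S, 3))
  for (ch in 1:3) {
    plane <- matrix(pal$background[ch], S, S)
    plane[regions == 1L] <- pal$cytoplasm[ch]
    plane[regions == 2L] <- pal$nucleus[ch]
    img[, , ch] <- plane
  }
  if (spec$blur_sigma > 0)
    img <- blur_rgb(img, spec$blur_sigma)
  if (spec$noise_sd > 0)
    img <- img + array(rnorm(length(img), 0, spec$noise_sd), dim(img))
  img <- pmin(pmax(img, 0), 1)
  dim(img) <- c(S, S, 3)
  mask <- matrix(as.numeric(regions > 0L), S, S)
  structure(list(image = img, mask = mask, regions = regions, label = label,
                 meta = list(label = label, ratio = ratio,
                             measured_nc = sum(regions == 2L) / max(sum(regions > 0L), 1),
                             axes = c(a = a, b = b), nucleus_axes = c(a1, b1),
                             center = c(cx, cy), theta = theta,
                             nucleus_offset = c(u, v))),
            class = "labeled_sample")
}

blur_rgb <- function(img, sigma) {
  for (ch in seq_len(dim(img)[3]))
    img[, , ch] <- as.matrix(EBImage::gblur(img[, , ch], sigma = sigma))
  img
}

#' Generate a phantom dataset
#'
#' Emits exactly `sum(class_counts)` samples, class by class, together with a
#' manifest (filename, mask filename, label, per-sample seed). Each sample is
#' drawn under its own recorded seed, so any row of the manifest can be
#' regenerated independently; identical `(spec, class_counts, seed)` give
#' bit-identical datasets.
#'
#' @param spec a [phantom_spec()].
#' @param class_counts named integer vector/list, class -> count (>= 0).
#' @param seed master seed (defaults to `spec$seed`).
#' @return list with `samples` (list of labeled samples) and `manifest`
#'   (data frame).
#' @export
generate_dataset <- function(spec, class_counts, seed = spec$seed) {
  if (length(class_counts) == 0)
    dc_stop("empty_counts", "class_counts must name at least one class")
  counts <- unlist(class_counts)
  if (any(counts < 0)) dc_stop("bad_counts", "counts must be >= 0")
  for (cl in names(counts))
    if (is.null(spec$nc_ratio_by_class[[cl]]))
      dc_stop("unknown_label", "unknown class label: ", cl)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, sum(counts), replace = FALSE)
  samples <- vector("list", sum(counts))
  man <- data.frame(filename = character(0), mask_filename = character(0),
                    label = character(0), seed = integer(0))
  k <- 0L
  for (cl in names(counts)) {
    for (i in seq_len(counts[[cl]])) {
      k <- k + 1L
      set.seed(seeds[k])
      samples[[k]] <- generate_cell_image(spec, cl)
      man <- rbind(man, data.frame(
        filename = sprintf("%s_%04d.png", cl, i),
        mask_filename = sprintf("%s_%04d_mask.png", cl, i),
        label = cl, seed = seeds[k]))
    }
  }
  list(samples = samples, manifest = man)
}

#' Write a dataset to disk
#'
#' Images and masks as 8-bit PNG (masks single channel, 0 = background,
#' 255 = cell) plus the manifest as CSV.
#'
#' @param dataset result of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(dataset$samples)) {
    s <- dataset$samples[[i]]
    png::writePNG(s$image, file.path(dir, dataset$manifest$filename[i]))
    png::writePNG(s$mask, file.path(dir, dataset$manifest$mask_filename[i]))
  }
  p <- file.path(dir, "manifest.csv")
  write.csv(dataset$manifest, p, row.names = FALSE)
  invisible(p)
}

#' Render a color (Herlev-style) region mask
#'
#' Paints background / cytoplasm / nucleus with distinct colors, mirroring
#' datasets that ship color masks which are later converted to binary
#' whole-cell masks. Round-tripping through [color_mask_to_binary()] with the
#' background color reproduces `sample$mask` exactly.
#'
#' @param sample a labeled sample from [generate_cell_image()].
#' @param region_palette named list of 8-bit RGB triples (0..255) for
#'   `background`, `cytoplasm`, `nucleus`; colors must be pairwise distinct.
#' @return H x W x 3 integer array (0..255).
#' @export
write_herlev_style_mask <- function(sample,
                                    region_palette = list(
                                      background = c(0L, 0L, 0L),
                                      cytoplasm = c(0L, 255L, 0L),
                                      nucleus = c(255L, 0L, 0L))) {
  pal <- region_palette
  key <- vapply(pal, paste, "", collapse = ",")
  if (anyDuplicated(key))
    dc_stop("palette_collision", "two regions share the same color")
  S <- dim(sample$regions)
  out <- array(0L, c(S[1], S[2], 3))
  for (ch in 1:3) {
    plane <- matrix(pal$background[ch], S[1], S[2])
    plane[sample$regions == 1L] <- pal$cytoplasm[ch]
    plane[sample$regions == 2L] <- pal$nucleus[ch]
    out[, , ch] <- plane
  }
  storage.mode(out) <- "integer"
  out
}
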