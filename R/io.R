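# Image/mask I/O and the preprocessing steps applied before segmentation and
# classification: resizing to a square target, [0,1] normalization, affine
# brightness/contrast adjustment, color-to-binary mask conversion, automatic
# intensity-threshold mask creation, prediction binarization, and ROI
# extraction (mask x image product). In-memory conventions: row-major arrays,
# origin top-left; raw images are 8-bit integer (H, W, 3); normalized images
# are real (H, W, 3) in [0,1]; masks are numeric (H, W) over {0,1} in memory
# and 0/255 single-channel PNG on disk.

#' Load a raster image
#'
#' Reads PNG/JPEG/TIFF into an 8-bit RGB array (H, W, 3). Grayscale inputs
#' are replicated to three channels, an alpha channel is dropped.
#'
#' @param path file path.
#' @return integer array (H, W, 3), values 0..255, with attribute
#'   `source_path`.
#' @export
load_image <- function(path) {
  if (!file.exists(path))
    dc_stop("io_error", "cannot read image: no such file: ", path)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e)
                    dc_stop("io_error", "failed to read image '", path,
                            "': ", conditionMessage(e)))
  a <- unclass(EBImage::imageData(img))
  # EBImage stores (x = width, y = height[, channels]); convert to (H, W, C)
  if (length(dim(a)) == 2L) {
    a <- aperm(a, c(2, 1))
    a <- array(rep(a, 3L), c(dim(a), 3L))
  } else {
    a <- aperm(a, c(2, 1, 3))
    if (dim(a)[3] >= 4L) a <- a[, , 1:3, drop = FALSE]
    if (dim(a)[3] == 1L) a <- array(rep(a, 3L), c(dim(a)[1:2], 3L))
    if (dim(a)[3] == 2L) a <- array(rep(a[, , 1], 3L), c(dim(a)[1:2], 3L))
  }
  out <- array(as.integer(round(a * 255)), dim(a))
  attr(out, "source_path") <- path
  out
}

#' Resize to a square target and normalize to \[0,1\]
#'
#' Bilinear interpolation for images (masks go through
#' [resize_mask()] with nearest neighbour so they stay binary). A constant
#' input stays constant.
#'
#' @param img integer raw image (0..255) or real image in \[0,1\], (H, W, 3).
#' @param target output side in pixels (>= 8).
#' @return real array (target, target, 3) in \[0,1\].
#' @export
resize_normalize <- function(img, target = 224L) {
  if (target < 8L) dc_stop("bad_config", "target size must be >= 8")
  x <- if (is.integer(img) || max(img) > 1) img / 255 else img
  d <- dim(x)
  if (d[1] == target && d[2] == target) return(pmin(pmax(x, 0), 1))
  out <- array(0, c(target, target, 3))
  for (ch in 1:3) {
    e <- EBImage::resize(EBImage::as.Image(t(x[, , ch])), w = target, h = target)
    out[, , ch] <- t(as.matrix(e))
  }
  pmin(pmax(out, 0), 1)
}

#' Resize a binary mask with nearest-neighbour interpolation
#'
#' @param mask numeric (H, W) over \{0,1\}.
#' @param target output side in pixels.
#' @return numeric (target, target) over \{0,1\}.
#' @export
resize_mask <- function(mask, target = 224L) {
  d <- dim(mask)
  if (d[1] == target && d[2] == target) return(mask)
  ri <- pmin(pmax(ceiling((seq_len(target) - 0.5) * d[1] / target), 1L), d[1])
  ci <- pmin(pmax(ceiling((seq_len(target) - 0.5) * d[2] / target), 1L), d[2])
  mask[ri, ci, drop = FALSE]
}

#' Affine brightness/contrast adjustment
#'
#' `out = clip(gain * in + bias, 0, 1)` per pixel per channel.
#'
#' @param img normalized image in \[0,1\].
#' @param gain multiplicative contrast factor (> 0).
#' @param bias additive brightness offset.
#' @return adjusted image, same shape.
#' @export
adjust_brightness_contrast <- function(img, gain = 1, bias = 0) {
  if (gain <= 0) dc_stop("bad_config", "gain must be > 0")
  pmin(pmax(gain * img + bias, 0), 1)
}

#' Convert a color region mask to a binary whole-cell mask
#'
#' A pixel is background (0) iff every channel is within `tolerance` of the
#' background color; anything else is cell (1).
#'
#' @param color_mask 8-bit RGB array (H, W, 3).
#' @param background_color RGB triple, 0..255.
#' @param tolerance per-channel absolute distance (>= 0).
#' @return numeric (H, W) mask over \{0,1\}.
#' @export
color_mask_to_binary <- function(color_mask, background_color = c(0, 0, 0),
                                 tolerance = 0) {
  if (tolerance < 0) dc_stop("bad_config", "tolerance must be >= 0")
  d <- dim(color_mask)
  bg <- abs(color_mask[, , 1] - background_color[1]) <= tolerance &
    abs(color_mask[, , 2] - background_color[2]) <= tolerance &
    abs(color_mask[, , 3] - background_color[3]) <= tolerance
  matrix(as.numeric(!bg), d[1], d[2])
}

#' Automatic whole-cell mask from image intensity
#'
#' Automated stand-in for manual mask annotation: foreground is every pixel
#' whose luminance differs from the modal (background) luminance by more than
#' `threshold`; only the largest connected component is kept and its holes
#' are filled. When nothing exceeds the threshold an all-zero mask is
#' returned with attribute `warning_empty = TRUE`.
#'
#' @param img normalized image (H, W, 3) in \[0,1\].
#' @param threshold luminance difference in (0,1).
#' @return numeric (H, W) mask over \{0,1\}.
#' @export
threshold_mask_from_image <- function(img, threshold = 0.1) {
  if (threshold <= 0 || threshold >= 1)
    dc_stop("bad_config", "threshold must be in (0,1)")
  lum <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  lv <- round(lum * 255)
  mode_lum <- as.numeric(names(which.max(table(lv)))) / 255
  fg <- abs(lum - mode_lum) > threshold
  if (!any(fg)) {
    out <- matrix(0, nrow(lum), ncol(lum))
    attr(out, "warning_empty") <- TRUE
    warning("threshold_mask_from_image: empty foreground")
    return(out)
  }
  lab <- EBImage::bwlabel(fg)
  tab <- tabulate(lab[lab > 0])
  keep <- which.max(tab)
  comp <- matrix(as.numeric(lab == keep), nrow(lum), ncol(lum))
  filled <- as.matrix(EBImage::fillHull(comp))
  matrix(as.numeric(filled > 0), nrow(lum), ncol(lum))
}

#' Binarize a probability map
#'
#' Pixel = 1 iff probability >= threshold.
#'
#' @param prob_map real array in \[0,1\].
#' @param threshold decision threshold.
#' @return numeric mask over \{0,1\}, same shape.
#' @export
binarize_prediction <- function(prob_map, threshold = 0.5) {
  if (any(prob_map < -1e-9) || any(prob_map > 1 + 1e-9))
    dc_stop("bad_input", "probabilities outside [0,1]")
  out <- (prob_map >= threshold) * 1
  if (!is.null(dim(prob_map))) dim(out) <- dim(prob_map)
  out
}

#' Region-of-interest extraction
#'
#' Multiplies every channel of the image by the binary mask, zeroing the
#' background; the classification stages of the ROI pipelines consume this
#' product. Idempotent for a fixed mask.
#'
#' @param img normalized image (H, W, 3).
#' @param mask binary mask (H, W).
#' @return masked image, same shape as `img`.
#' @export
apply_roi <- function(img, mask) {
  d <- dim(img)
  if (d[1] != nrow(mask) || d[2] != ncol(mask))
    dc_stop("shape_mismatch", "image and mask shapes differ")
  out <- img
  for (ch in seq_len(d[3])) out[, , ch] <- img[, , ch] * mask
  out
}
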