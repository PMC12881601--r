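# Evaluation metrics: pixel-level segmentation scores (accuracy, precision,
# recall, Dice, IoU) pooled micro over all evaluated pixels, and label-level
# classification scores (accuracy, precision, recall, F1) with confusion
# matrices and macro / weighted / micro averaging.

#' Pixel confusion counts
#'
#' Pools true/false positives/negatives over every pixel of every mask pair
#' (micro pooling).
#'
#' @param y_true,y_pred binary masks: matrices, arrays or lists of matrices
#'   with matching shapes.
#' @return a `pixel_confusion` list with fields `tp`, `fp`, `tn`, `fn`.
#' @export
pixel_confusion <- function(y_true, y_pred) {
  t <- unlist(y_true); p <- unlist(y_pred)
  if (length(t) != length(p))
    dc_stop("shape_mismatch", "mask shapes differ")
  if (!all(t %in% c(0, 1)) || !all(p %in% c(0, 1)))
    dc_stop("bad_input", "masks must be binary (values in {0,1})")
  tp <- sum(t == 1 & p == 1)
  fp <- sum(t == 0 & p == 1)
  tn <- sum(t == 0 & p == 0)
  fn <- sum(t == 1 & p == 0)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn),
            class = "pixel_confusion")
}

ratio0 <- function(num, denom, err) {
  if (denom > 0) return(num / denom)
  if (err == 0) 1 else 0
}

#' Segmentation metric report from pixel confusion counts
#'
#' accuracy = (tp+tn)/N, precision = tp/(tp+fp), recall = tp/(tp+fn),
#' dice = 2tp/(2tp+fp+fn), iou = tp/(tp+fp+fn). A ratio with zero denominator
#' is reported as 1 when the corresponding error count is also 0, else 0,
#' so degenerate inputs never produce NaN. Dice and IoU always satisfy
#' `dice = 2 iou / (1 + iou)`.
#'
#' @param conf a [pixel_confusion()].
#' @return a `seg_metric_report` list with fields in \[0,1\].
#' @export
seg_metrics <- function(conf) {
  n <- conf$tp + conf$fp + conf$tn + conf$fn
  if (n == 0) dc_stop("empty_confusion", "no evaluated pixels")
  structure(list(
    accuracy = (conf$tp + conf$tn) / n,
    precision = ratio0(conf$tp, conf$tp + conf$fp, conf$fp),
    recall = ratio0(conf$tp, conf$tp + conf$fn, conf$fn),
    dice = ratio0(2 * conf$tp, 2 * conf$tp + conf$fp + conf$fn,
                  conf$fp + conf$fn),
    iou = ratio0(conf$tp, conf$tp + conf$fp + conf$fn, conf$fp + conf$fn)),
    class = "seg_metric_report")
}

#' @export
print.seg_metric_report <- function(x, ...) {
  cat(sprintf("Seg  Acc %.2f%%  Pre %.2f%%  Rec %.2f%%  Dice %.2f%%  IoU %.2f%%\n",
              100 * x$accuracy, 100 * x$precision, 100 * x$recall,
              100 * x$dice, 100 * x$iou))
  invisible(x)
}

#' Classification metric report
#'
#' Builds the confusion matrix (rows = true classes, columns = predicted) and
#' aggregates per-class precision/recall/F1 under the requested averaging.
#' All three averagings are always emitted in `$all`; for single-label tasks
#' micro precision = micro recall = accuracy.
#'
#' @param y_true,y_pred label vectors: integers in `[0, n_classes)` or a
#'   common set of character/factor labels.
#' @param n_classes number of classes (inferred from labels when `NULL`).
#' @param averaging headline averaging: `"weighted"`, `"macro"` or `"micro"`.
#' @return a `clf_metric_report` list: accuracy, precision, recall, f1,
#'   confusion matrix, per-class table, and `all` (one row per averaging).
#' @export
clf_metrics <- function(y_true, y_pred, n_classes = NULL,
                        averaging = c("weighted", "macro", "micro")) {
  averaging <- match.arg(averaging)
  if (length(y_true) != length(y_pred))
    dc_stop("shape_mismatch", "label vectors differ in length")
  if (is.numeric(y_true) || is.integer(y_true)) {
    if (is.null(n_classes)) n_classes <- max(y_true, y_pred) + 1
    if (any(c(y_true, y_pred) < 0) || any(c(y_true, y_pred) >= n_classes))
      dc_stop("bad_label", "labels must lie in [0, n_classes)")
    lev <- as.character(0:(n_classes - 1))
    y_true <- factor(y_true, levels = 0:(n_classes - 1))
    y_pred <- factor(y_pred, levels = 0:(n_classes - 1))
  } else {
    lev <- sort(unique(c(as.character(y_true), as.character(y_pred))))
    if (!is.null(n_classes) && length(lev) > n_classes)
      dc_stop("bad_label", "more labels than n_classes")
    y_true <- factor(as.character(y_true), levels = lev)
    y_pred <- factor(as.character(y_pred), levels = lev)
  }
  cm <- table(true = y_true, pred = y_pred)
  n <- sum(cm)
  tp <- diag(cm)
  support <- rowSums(cm)
  predn <- colSums(cm)
  prec <- ifelse(predn > 0, tp / predn, 0)
  rec <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  acc <- sum(tp) / n
  agg <- function(kind) {
    w <- switch(kind,
                macro = rep(1 / length(tp), length(tp)),
                weighted = support / n,
                micro = NULL)
    if (kind == "micro") c(precision = acc, recall = acc, f1 = acc)
    else c(precision = sum(w * prec), recall = sum(w * rec), f1 = sum(w * f1))
  }
  all <- do.call(rbind, lapply(c("macro", "weighted", "micro"), function(k)
    data.frame(averaging = k, t(agg(k)))))
  hl <- agg(averaging)
  structure(list(accuracy = acc, precision = unname(hl["precision"]),
                 recall = unname(hl["recall"]), f1 = unname(hl["f1"]),
                 confusion = cm,
                 per_class = data.frame(class = names(tp) %||% lev,
                                        support = as.numeric(support),
                                        precision = as.numeric(prec),
                                        recall = as.numeric(rec),
                                        f1 = as.numeric(f1)),
                 averaging = averaging, all = all),
            class = "clf_metric_report")
}

#' @export
print.clf_metric_report <- function(x, ...) {
  cat(sprintf("Clf  Acc %.2f%%  Pre %.2f%%  Rec %.2f%%  F1 %.2f%%  (%s)\n",
              100 * x$accuracy, 100 * x$precision, 100 * x$recall,
              100 * x$f1, x$averaging))
  invisible(x)
}

#' Write a metric report as JSON
#'
#' @param report a seg or clf metric report.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metric_report <- function(report, path) {
  obj <- unclass(report)
  obj$confusion <- if (!is.null(obj$confusion)) unclass(obj$confusion)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
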