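# Partitioning of real and generated data, and the augmentation mixing
# policy. Real data go to train/validation/test (64/16/20); GAN-generated
# data only ever to train/validation (80/20). The central hygiene rule,
# asserted at every mixing step: generated images never reach a test split.

half_up <- function(x) floor(x + 0.5)

#' Split plan
#'
#' @param real_fractions named vector `(train, val, test)` summing to 1.
#' @param generated_fractions named vector `(train, val)` summing to 1.
#' @param stratified stratify the real split by class label.
#' @param seed integer seed driving every shuffle.
#' @return a `split_plan` list.
#' @export
split_plan <- function(real_fractions = c(train = 0.64, val = 0.16, test = 0.20),
                       generated_fractions = c(train = 0.80, val = 0.20),
                       stratified = TRUE, seed = 1L) {
  if (abs(sum(real_fractions) - 1) > 1e-9)
    dc_stop("bad_plan", "real fractions must sum to 1")
  if (abs(sum(generated_fractions) - 1) > 1e-9)
    dc_stop("bad_plan", "generated fractions must sum to 1")
  structure(list(real_fractions = real_fractions,
                 generated_fractions = generated_fractions,
                 stratified = stratified, seed = as.integer(seed)),
            class = "split_plan")
}

sample_labels <- function(samples)
  vapply(samples, function(s) as.character(s$label %||% "NA"), "")

# Largest-remainder apportionment of `size` items over class counts `nc`.
apportion <- function(nc, size) {
  quota <- size * nc / sum(nc)
  base <- floor(quota)
  rem <- size - sum(base)
  if (rem > 0) {
    ord <- order(quota - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  base
}

#' Split real samples into train/validation/test
#'
#' Test and validation sizes are rounded half-up from the plan fractions
#' (`test = round(0.20 n)`, `val = round(0.16 n)`); training takes the
#' remainder. With stratification, per-class allocations follow largest-
#' remainder apportionment, keeping class proportions within one sample per
#' class while the global sizes stay exact. Deterministic given the plan
#' seed; partitions are disjoint and exhaustive.
#'
#' @param samples list of labeled samples.
#' @param plan a [split_plan()].
#' @return list with `train`, `val`, `test` sample lists.
#' @export
split_real <- function(samples, plan = split_plan()) {
  n <- length(samples)
  fr <- plan$real_fractions
  n_test <- half_up(fr[["test"]] * n)
  n_val <- half_up(fr[["val"]] * n)
  set.seed(plan$seed)
  if (plan$stratified) {
    labs <- sample_labels(samples)
    tab <- table(labs)
    if (any(tab < 5))
      dc_stop("too_few_samples",
              "stratified split needs >= 5 samples per class")
    cls <- names(tab)
    t_alloc <- apportion(as.numeric(tab), n_test)
    v_alloc <- apportion(as.numeric(tab), n_val)
    tr_i <- va_i <- te_i <- integer(0)
    for (j in seq_along(cls)) {
      idx <- sample(which(labs == cls[j]))
      te_i <- c(te_i, idx[seq_len(t_alloc[j])])
      va_i <- c(va_i, idx[t_alloc[j] + seq_len(v_alloc[j])])
      tr_i <- c(tr_i, idx[-(seq_len(t_alloc[j] + v_alloc[j]))])
    }
  } else {
    idx <- sample.int(n)
    te_i <- idx[seq_len(n_test)]
    va_i <- idx[n_test + seq_len(n_val)]
    tr_i <- idx[-(seq_len(n_test + n_val))]
  }
  list(train = samples[sort(tr_i)], val = samples[sort(va_i)],
       test = samples[sort(te_i)])
}

#' Split generated samples into train/validation
#'
#' `train = round(0.8 n)` (half-up), validation takes the remainder;
#' deterministic given the plan seed. Generated data never receive a test
#' partition.
#'
#' @param samples list of samples.
#' @param plan a [split_plan()].
#' @return list with `train` and `val` sample lists.
#' @export
split_generated <- function(samples, plan = split_plan()) {
  n <- length(samples)
  if (n == 0) return(list(train = list(), val = list()))
  n_train <- half_up(plan$generated_fractions[["train"]] * n)
  set.seed(plan$seed + 1L)
  idx <- sample.int(n)
  list(train = samples[sort(idx[seq_len(n_train)])],
       val = samples[sort(idx[-seq_len(n_train)])])
}

#' Augmentation mixing policy
#'
#' @param placement `"before_segmentation"`, `"after_segmentation"` or
#'   `"none"`.
#' @return a `mix_policy` list.
#' @export
mix_policy <- function(placement = c("none", "before_segmentation",
                                     "after_segmentation")) {
  structure(list(placement = match.arg(placement)), class = "mix_policy")
}

#' Mix generated data into the splits of a pipeline stage
#'
#' Applies the placement table: augmentation placed before segmentation
#' reaches both the segmentation and the downstream classification
#' training/validation sets; placed after segmentation it reaches only the
#' classification sets. When the policy does not apply to the stage, the real
#' split passes through unchanged. The test set is always the real test set;
#' any attempt to smuggle generated samples into test is an error.
#'
#' @param real_split result of [split_real()].
#' @param gen_split result of [split_generated()].
#' @param policy a [mix_policy()].
#' @param stage `"segmentation"` or `"classification"`.
#' @return list with `train`, `val`, `test`.
#' @export
mix_for_stage <- function(real_split, gen_split, policy,
                          stage = c("segmentation", "classification")) {
  stage <- match.arg(stage)
  if (length(gen_split$test %||% list()) > 0)
    dc_stop("generated_in_test", "generated samples may never enter a test set")
  applies <- switch(policy$placement,
                    none = FALSE,
                    before_segmentation = TRUE,
                    after_segmentation = stage == "classification")
  if (!applies)
    return(list(train = real_split$train, val = real_split$val,
                test = real_split$test))
  tag <- function(s) { s$origin <- s$origin %||% "generated"; s }
  list(train = c(real_split$train, lapply(gen_split$train, tag)),
       val = c(real_split$val, lapply(gen_split$val, tag)),
       test = real_split$test)
}

#' Write a split manifest
#'
#' CSV with columns (filename, class, split, origin).
#'
#' @param splits named list of sample lists (e.g. train/val/test).
#' @param path output CSV path.
#' @return the manifest data frame, invisibly.
#' @export
write_split_manifest <- function(splits, path) {
  rows <- list()
  for (sp in names(splits)) {
    ss <- splits[[sp]]
    if (length(ss) == 0) next
    rows[[sp]] <- data.frame(
      filename = vapply(seq_along(ss), function(i)
        ss[[i]]$meta$filename %||% sprintf("%s_%04d.png", sp, i), ""),
      class = sample_labels(ss), split = sp,
      origin = vapply(ss, function(s) s$origin %||% "real", ""))
  }
  man <- do.call(rbind, rows)
  write.csv(man, path, row.names = FALSE)
  invisible(man)
}
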