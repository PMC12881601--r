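# Classification stage: a single-backbone classifier, a 7-member majority
# voting ensemble, and an 8-backbone feature-concatenation ensemble with a
# 256/64 dense head (normalization after the 256 layer, dropout 0.5, softmax
# out). Backbone names come from the closed set of well-known CNN families;
# offline they are instantiated as registered tiny stand-in CNNs with frozen
# random weights of the same interface — features in, logits out — so the
# ensemble logic is testable without pretrained weights.

BACKBONE_NAMES <- c("ResNet50V2", "VGG16", "VGG19", "Xception", "InceptionV3",
                    "DenseNet121", "EfficientNetB2", "MobileNetV2")
VOTING_MEMBERS <- c("ResNet50V2", "VGG19", "VGG16", "Xception", "DenseNet121",
                    "EfficientNetB2", "MobileNetV2")

#' Backbone specification
#'
#' @param name one of the supported backbone family names:
#'   `r paste(BACKBONE_NAMES, collapse = ", ")`.
#' @param weights `"random"` (seeded stand-in weights) or `"pretrained"`
#'   (reserved; pretrained weights are never a test dependency).
#' @param frozen whether the backbone weights are excluded from training.
#' @return a `backbone_spec` list.
#' @export
backbone_spec <- function(name, weights = c("random", "pretrained"),
                          frozen = TRUE) {
  if (!name %in% BACKBONE_NAMES)
    dc_stop("unknown_backbone", "unknown backbone: ", name)
  structure(list(name = name, weights = match.arg(weights), frozen = frozen),
            class = "backbone_spec")
}

# Tiny stand-in architectures: stride-2 conv stacks whose depth/filters vary
# per family so ensemble members see genuinely different features.
backbone_arch <- function(name) {
  switch(name,
    ResNet50V2 = list(filters = c(12, 24, 32, 40), seed_off = 1L),
    VGG16 = list(filters = c(8, 16, 24, 32), seed_off = 2L),
    VGG19 = list(filters = c(8, 16, 32, 40), seed_off = 3L),
    Xception = list(filters = c(10, 20, 28, 36), seed_off = 4L),
    InceptionV3 = list(filters = c(14, 28, 36, 44), seed_off = 5L),
    DenseNet121 = list(filters = c(12, 20, 28, 36), seed_off = 6L),
    EfficientNetB2 = list(filters = c(10, 24, 32, 40), seed_off = 7L),
    MobileNetV2 = list(filters = c(8, 12, 20, 28), seed_off = 8L))
}

build_backbone <- function(spec, input_size, seed = 100L) {
  arch <- backbone_arch(spec$name)
  set.seed(seed + arch$seed_off)
  L <- list()
  cin <- 3L
  for (i in seq_along(arch$filters)) {
    L[[paste0("conv", i)]] <- nn_conv(3, cin, arch$filters[i], stride = 2L)
    L[[paste0("act", i)]] <- nn_act("relu")
    cin <- arch$filters[i]
  }
  net <- nn_init(nn_network(L))
  if (spec$frozen) net <- mark_frozen(net)
  net$out_channels <- cin
  net$out_spatial <- input_size %/% 2^length(arch$filters)
  net$name <- spec$name
  net
}

#' Classifier training configuration
#'
#' Adam + categorical cross-entropy, batch size 32, up to 100 epochs with
#' early stopping on validation loss.
#'
#' @param learning_rate,batch_size,max_epochs,early_stop_patience,seed scalars.
#' @return a `clf_train_config` list.
#' @export
clf_train_config <- function(learning_rate = 1e-3, batch_size = 32L,
                             max_epochs = 100L, early_stop_patience = 5L,
                             seed = 42L) {
  if (batch_size < 1L) dc_stop("bad_config", "batch_size must be >= 1")
  structure(list(optimizer = "adam", loss = "categorical_crossentropy",
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = as.integer(seed)),
            class = "clf_train_config")
}

#' Build a single-backbone classifier
#'
#' Backbone, global average pooling, and a softmax output layer sized to the
#' task; only the output layer changes with the class count.
#'
#' @param backbone a [backbone_spec()] or backbone name.
#' @param n_classes number of classes (>= 2).
#' @param input_size input image side.
#' @param seed seed for weight initialization.
#' @return a `dc_classifier` model (mode `"single"`).
#' @export
build_single_classifier <- function(backbone = "ResNet50V2", n_classes,
                                    input_size = 224L, seed = 100L) {
  if (n_classes < 2L) dc_stop("bad_config", "n_classes must be >= 2")
  if (is.character(backbone)) backbone <- backbone_spec(backbone)
  bb <- build_backbone(backbone, input_size, seed)
  set.seed(seed + 50L)
  head <- nn_init(nn_network(list(
    fc = nn_dense(bb$out_channels, n_classes))))
  structure(list(mode = "single", backbones = list(bb), head = head,
                 n_classes = as.integer(n_classes),
                 input_size = as.integer(input_size),
                 feature_pool = "gap", label_levels = NULL),
            class = "dc_classifier")
}

#' Concatenation-ensemble configuration
#'
#' @param backbones exactly eight [backbone_spec()]s (default: the seven
#'   voting members plus InceptionV3, all frozen).
#' @param n_classes number of classes.
#' @param input_size input image side.
#' @param head_dims dense head widths (fixed 256/64).
#' @param dropout head dropout rate.
#' @return a `concat_ensemble_config` list.
#' @export
concat_ensemble_config <- function(backbones = NULL, n_classes = 2L,
                                   input_size = 224L,
                                   head_dims = c(256L, 64L), dropout = 0.5) {
  if (is.null(backbones))
    backbones <- lapply(c(VOTING_MEMBERS, "InceptionV3"), backbone_spec)
  if (length(backbones) != 8L)
    dc_stop("bad_config", "the concatenation ensemble uses exactly 8 backbones")
  structure(list(backbones = backbones, n_classes = as.integer(n_classes),
                 input_size = as.integer(input_size),
                 head_dims = as.integer(head_dims), dropout = dropout),
            class = "concat_ensemble_config")
}

#' Build the 8-backbone feature-concatenation ensemble
#'
#' Per-backbone feature maps are flattened (no pooling) and concatenated
#' into one vector feeding the dense 256 / normalization / dropout /
#' dense 64 / softmax head. Frozen backbone parameters appear only in the
#' non-trainable count.
#'
#' @param cfg a [concat_ensemble_config()].
#' @param seed weight-initialization seed.
#' @return a `dc_classifier` model (mode `"concat"`).
#' @export
build_concat_ensemble <- function(cfg, seed = 100L) {
  bbs <- lapply(cfg$backbones, build_backbone, input_size = cfg$input_size,
                seed = seed)
  D <- sum(vapply(bbs, function(b) b$out_channels * b$out_spatial^2, 0))
  set.seed(seed + 50L)
  head <- nn_init(nn_network(list(
    fc1 = nn_dense(D, cfg$head_dims[1]),
    bn1 = nn_norm1d(cfg$head_dims[1]),
    act1 = nn_act("relu"),
    drop1 = nn_dropout(cfg$dropout),
    fc2 = nn_dense(cfg$head_dims[1], cfg$head_dims[2]),
    act2 = nn_act("relu"),
    fc3 = nn_dense(cfg$head_dims[2], cfg$n_classes))))
  structure(list(mode = "concat", backbones = bbs, head = head,
                 n_classes = cfg$n_classes, input_size = cfg$input_size,
                 feature_pool = "flatten", label_levels = NULL,
                 networks = NULL),
            class = "dc_classifier")
}

#' Voting-ensemble configuration
#'
#' @param members exactly seven backbone names (the fixed voting roster).
#' @param tie_break tie rule; `"lowest_index"` picks the smallest class index.
#' @return a `voting_config` list.
#' @export
voting_config <- function(members = VOTING_MEMBERS,
                          tie_break = "lowest_index") {
  if (length(members) != 7L)
    dc_stop("bad_config", "the voting ensemble uses exactly 7 members")
  for (m in members) if (!m %in% BACKBONE_NAMES)
    dc_stop("unknown_backbone", "unknown backbone: ", m)
  structure(list(members = members, tie_break = tie_break),
            class = "voting_config")
}


extract_features <- function(model, x) {
  n <- dim(x)[4]
  feats <- lapply(model$backbones, function(bb) {
    y <- net_forward(bb, x, training = FALSE)$y
    if (model$feature_pool == "gap") {
      d <- dim(y)
      m <- apply(array(y, c(d[1] * d[2], d[3], d[4])), c(2, 3), mean)
      t(matrix(m, d[3], d[4]))
    } else {
      t(matrix(y, length(y) / n, n))
    }
  })
  do.call(cbind, feats)
}

#' Train a classifier
#'
#' Trains the trainable part of the model (the dense head; backbones are
#' frozen) with Adam and categorical cross-entropy, early stopping on
#' validation loss with best-weight restoration. Frozen-backbone features
#' are extracted once. Deterministic given `cfg$seed`.
#'
#' @param model a `dc_classifier`.
#' @param train,val lists of labeled samples (fields `image`, `label`).
#' @param cfg a [clf_train_config()].
#' @return list with `model` (trained, label levels attached) and `history`.
#' @export
train_classifier <- function(model, train, val, cfg = clf_train_config()) {
  if (length(train) == 0 || length(val) == 0)
    dc_stop("empty_data", "training and validation sets must be non-empty")
  labs <- sample_labels(train)
  lev <- sort(unique(labs))
  if (length(lev) < model$n_classes)
    dc_stop("missing_class", "a class is absent from the training set")
  if (length(lev) > model$n_classes)
    dc_stop("bad_label", "more classes in data than model outputs")
  model$label_levels <- lev
  set.seed(cfg$seed)
  ftr <- extract_features(model, samples_to_x(train))
  # z-score the frozen features on the training set; the affine map is part
  # of the model so prediction uses the same scaling
  model$feat_mean <- colMeans(ftr)
  model$feat_sd <- pmax(apply(ftr, 2, sd), 1e-6)
  ftr <- scale_features(ftr, model)
  fvl <- scale_features(extract_features(model, samples_to_x(val)), model)
  ytr <- onehot(match(labs, lev) - 1L, model$n_classes)
  yvl <- onehot(match(sample_labels(val), lev) - 1L, model$n_classes)
  head <- model$head
  st <- adam_state()
  hist <- data.frame()
  best <- list(loss = Inf, layers = NULL)
  wait <- 0L
  n <- nrow(ftr)
  for (epoch in seq_len(cfg$max_epochs)) {
    idx <- sample.int(n)
    tl <- 0; nb <- 0
    for (b in split(idx, ceiling(seq_along(idx) / cfg$batch_size))) {
      fwd <- net_forward(head, ftr[b, , drop = FALSE], training = TRUE)
      head <- fwd$net
      l <- softmax_ce(fwd$y, ytr[b, , drop = FALSE])
      bwd <- net_backward(head, fwd$caches, l$grad)
      up <- adam_step(head, bwd$grads, st, lr = cfg$learning_rate)
      head <- up$net; st <- up$state
      tl <- tl + l$loss; nb <- nb + 1
    }
    vf <- net_forward(head, fvl, training = FALSE)
    vl_ <- softmax_ce(vf$y, yvl)
    vacc <- mean(max.col(vl_$probs) == max.col(yvl))
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = tl / nb,
                                   val_loss = vl_$loss, val_acc = vacc))
    if (vl_$loss < best$loss - 1e-6) {
      best <- list(loss = vl_$loss, layers = head$layers)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$early_stop_patience) break
    }
  }
  if (!is.null(best$layers)) head$layers <- best$layers
  model$head <- head
  list(model = model, history = hist)
}

scale_features <- function(f, model) {
  if (is.null(model$feat_mean)) return(f)
  sweep(sweep(f, 2, model$feat_mean), 2, model$feat_sd, "/")
}

onehot <- function(idx0, k) {
  y <- matrix(0, length(idx0), k)
  y[cbind(seq_along(idx0), idx0 + 1L)] <- 1
  y
}

#' Class-probability predictions
#'
#' @param model a trained `dc_classifier`.
#' @param images array `(H, W, 3, N)` or list of samples.
#' @return `N x n_classes` probability matrix (rows sum to 1); column names
#'   are the label levels when known.
#' @export
predict_classifier <- function(model, images) {
  if (is.list(images)) images <- samples_to_x(images)
  if (length(dim(images)) == 3L) dim(images) <- c(dim(images), 1L)
  if (dim(images)[1] != model$input_size)
    dc_stop("shape_mismatch", "image size does not match classifier input")
  f <- scale_features(extract_features(model, images), model)
  p <- row_softmax(net_forward(model$head, f, training = FALSE)$y)
  if (!is.null(model$label_levels)) colnames(p) <- model$label_levels
  p
}

#' Predicted labels
#'
#' @param model a trained `dc_classifier`.
#' @param images images as in [predict_classifier()].
#' @return character (or integer index) vector of predicted labels.
#' @export
predict_labels <- function(model, images) {
  p <- predict_classifier(model, images)
  i <- max.col(p, ties.method = "first")
  if (!is.null(model$label_levels)) model$label_levels[i] else i - 1L
}

#' Majority vote over model predictions
#'
#' Per sample, the modal label across models; ties resolved by the smallest
#' class index (ordering of sorted unique labels). Permutation-invariant in
#' the model axis and the identity on unanimous votes.
#'
#' @param votes `n_samples x n_models` matrix of class labels.
#' @param tie_break only `"lowest_index"` is defined.
#' @return vector of `n_samples` winning labels.
#' @export
majority_vote <- function(votes, tie_break = "lowest_index") {
  votes <- as.matrix(votes)
  if (length(votes) == 0) dc_stop("empty_votes", "empty vote matrix")
  lev <- sort(unique(as.vector(votes)))
  apply(votes, 1, function(r) {
    counts <- table(factor(r, levels = lev))
    lev[which.max(counts)]  # first max = smallest class index
  })
}

#' Build and train the 7-member voting ensemble
#'
#' Each member is an independently seeded single-backbone classifier trained
#' on the same data; predictions are combined with [majority_vote()].
#'
#' @param vcfg a [voting_config()].
#' @param n_classes,input_size task shape.
#' @param train,val sample lists.
#' @param cfg a [clf_train_config()].
#' @return list with `members` (trained models) and `predict` helper fields.
#' @export
train_voting_ensemble <- function(vcfg, n_classes, input_size, train, val,
                                  cfg = clf_train_config()) {
  members <- vector("list", length(vcfg$members))
  for (i in seq_along(vcfg$members)) {
    m <- build_single_classifier(vcfg$members[i], n_classes, input_size,
                                 seed = cfg$seed + 1000L * i)
    mcfg <- cfg; mcfg$seed <- cfg$seed + i
    members[[i]] <- train_classifier(m, train, val, mcfg)$model
  }
  structure(list(members = members, tie_break = vcfg$tie_break),
            class = "dc_voting")
}

#' Voting-ensemble label predictions
#'
#' @param ensemble a trained [train_voting_ensemble()].
#' @param images images as in [predict_classifier()].
#' @return vector of winning labels.
#' @export
predict_voting <- function(ensemble, images) {
  votes <- vapply(ensemble$members, function(m) predict_labels(m, images),
                  character(if (is.list(images)) length(images)
                            else dim(images)[4]))
  majority_vote(as.matrix(votes), ensemble$tie_break)
}
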