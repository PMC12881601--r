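# Sequential container, Adam optimizer and parameter accounting shared by the
# segmenter, the GAN and the classifiers. A "network" is list(layers = <named
# list of layers>, initialized = flag); model objects embed one or more
# networks but always expose their layers under $layers (possibly nested one
# level, e.g. model$layers$enc1_conv1).

nn_network <- function(layers) {
  if (is.null(names(layers)) || any(names(layers) == ""))
    names(layers) <- sprintf("layer%02d", seq_along(layers))
  structure(list(layers = layers, initialized = FALSE), class = "dc_network")
}

nn_init <- function(net) {
  if (net$initialized) return(net)
  net$layers <- lapply(net$layers, layer_init)
  net$initialized <- TRUE
  net
}

net_forward <- function(net, x, training = FALSE) {
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    r <- layer_forward(net$layers[[i]], x, training)
    x <- r$y
    caches[[i]] <- r$cache
    if (!is.null(r$layer)) net$layers[[i]] <- r$layer  # running stats
  }
  list(y = x, caches = caches, net = net)
}

net_backward <- function(net, caches, dy) {
  grads <- vector("list", length(net$layers))
  names(grads) <- names(net$layers)
  for (i in rev(seq_along(net$layers))) {
    r <- layer_backward(net$layers[[i]], caches[[i]], dy)
    dy <- r$dx
    grads[[i]] <- r$grads
  }
  list(dx = dy, grads = grads)
}

# ---- parameter accounting ----------------------------------------------------

#' Count model parameters
#'
#' Walks every layer of a model and returns the exact integer parameter
#' accounting: trainable weights (convolution/dense kernels and biases,
#' normalization scale/shift) and non-trainable terms (the running mean and
#' variance pair kept by batch normalization; group normalization keeps
#' none). Layers carried by a model with `trainable = FALSE` (frozen
#' backbones) are counted as non-trainable.
#'
#' @param model a model built by [build_unet()], [build_generator()],
#'   [build_discriminator()], [build_single_classifier()],
#'   [build_concat_ensemble()] or a raw layer list.
#' @return list with integer fields `total`, `trainable`, `non_trainable`.
#' @export
count_parameters <- function(model) {
  layers <- collect_layers(model)
  tr <- 0; nt <- 0
  for (l in layers) {
    p <- layer_n_params(l)
    if (isTRUE(l$frozen)) {
      nt <- nt + p["trainable"] + p["non_trainable"]
    } else {
      tr <- tr + p["trainable"]
      nt <- nt + p["non_trainable"]
    }
  }
  list(total = unname(tr + nt), trainable = unname(tr), non_trainable = unname(nt))
}

collect_layers <- function(model) {
  if (!is.null(model$type) && !is.null(model$param_shapes)) return(list(model))
  out <- list()
  pools <- list()
  if (!is.null(model$layers)) pools <- c(pools, list(model$layers))
  if (!is.null(model$head)) pools <- c(pools, list(model$head$layers))
  if (!is.null(model$backbones))
    for (bb in model$backbones) pools <- c(pools, list(bb$layers))
  if (!is.null(model$networks))
    for (nw in model$networks) pools <- c(pools, list(nw$layers))
  if (length(pools) == 0 && is.list(model)) pools <- list(model)
  for (pl in pools)
    for (l in pl)
      if (is.list(l) && !is.null(l$type)) out <- c(out, list(l))
  out
}

mark_frozen <- function(net, frozen = TRUE) {
  net$layers <- lapply(net$layers, function(l) { l$frozen <- frozen; l })
  net
}

# ---- Adam --------------------------------------------------------------------

adam_state <- function() list(t = 0L, m = list(), v = list())

# grads: named list (layer name -> named list of gradient arrays). Updates the
# layer params in place and advances the moment estimates.
adam_step <- function(net, grads, st, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (ln in names(grads)) {
    g <- grads[[ln]]
    if (is.null(g) || isTRUE(net$layers[[ln]]$frozen)) next
    for (pn in names(g)) {
      key <- paste0(ln, ".", pn)
      gv <- g[[pn]]
      m <- st$m[[key]] %||% (gv * 0)
      v <- st$v[[key]] %||% (gv * 0)
      m <- beta1 * m + (1 - beta1) * gv
      v <- beta2 * v + (1 - beta2) * gv^2
      st$m[[key]] <- m
      st$v[[key]] <- v
      net$layers[[ln]]$params[[pn]] <-
        net$layers[[ln]]$params[[pn]] - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    }
  }
  list(net = net, state = st)
}

# ---- shared losses -----------------------------------------------------------

# Binary cross-entropy on probabilities, mean over elements; returns loss and
# gradient wrt the probability.
bce_loss <- function(p, target, eps = 1e-7) {
  p <- pmin(pmax(p, eps), 1 - eps)
  n <- length(p)
  loss <- -mean(target * log(p) + (1 - target) * log(1 - p))
  grad <- (-(target / p) + (1 - target) / (1 - p)) / n
  list(loss = loss, grad = grad)
}

# Softmax + categorical cross-entropy on logits (N x C); y one-hot (N x C).
softmax_ce <- function(logits, y) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  p <- e / rowSums(e)
  n <- nrow(logits)
  loss <- -mean(rowSums(y * log(pmax(p, 1e-12))))
  grad <- (p - y) / n
  list(loss = loss, grad = grad, probs = p)
}

row_softmax <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# ---- batching helpers --------------------------------------------------------

#' Stack labeled samples into image/mask arrays
#'
#' @param samples list of labeled samples with `image` (H x W x 3) and
#'   `mask` (H x W) fields.
#' @return list with `x` (H, W, 3, N) and `y` (H, W, 1, N) arrays.
#' @export
samples_to_xy <- function(samples) {
  n <- length(samples)
  d <- dim(samples[[1]]$image)
  x <- array(0, c(d[1], d[2], 3, n))
  y <- array(0, c(d[1], d[2], 1, n))
  for (i in seq_len(n)) {
    x[, , , i] <- samples[[i]]$image
    y[, , 1, i] <- samples[[i]]$mask
  }
  list(x = x, y = y)
}

#' Stack labeled samples into an image array
#'
#' @param samples list of labeled samples with `image` fields.
#' @return array (H, W, 3, N).
#' @export
samples_to_x <- function(samples) {
  n <- length(samples)
  d <- dim(samples[[1]]$image)
  x <- array(0, c(d[1], d[2], 3, n))
  for (i in seq_len(n)) x[, , , i] <- samples[[i]]$image
  x
}

slab <- function(x, idx) x[, , , idx, drop = FALSE]
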