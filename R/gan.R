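# Residual DCGAN augmentor. The generator projects a latent noise vector to a
# small spatial seed grid and maps it through up-sampling stages (each a 2x
# nearest-neighbour upsample + 3x3 convolution followed by one or more
# residual blocks with identity skips) down a decreasing filter schedule to an
# RGB image; the discriminator is exactly five stride-2 convolutions with an
# increasing filter schedule and a single real-vs-fake probability output.
# Generated image quality is scored with the Frechet distance between
# Gaussian fits of real and fake feature embeddings.

#' Generator configuration
#'
#' Defaults follow the published architecture: noise reshaped to a 6x6 seed,
#' four up-sampling stages with filters decreasing 512 to 64, 96x96x3 output.
#' Reduced configurations (smaller seed/filters) are supported for desk-scale
#' training; the output side is always `seed_spatial * 2^n_stages`.
#'
#' @param latent_dim noise vector length.
#' @param seed_spatial side of the spatial seed grid the projected noise is
#'   reshaped to.
#' @param stage_filters strictly decreasing filter counts, one per
#'   up-sampling stage.
#' @param residual_blocks_per_stage residual blocks after each up-sampling.
#' @param output_channels image channels.
#' @return a `generator_config` list (field `output_size` is derived).
#' @export
generator_config <- function(latent_dim = 128L, seed_spatial = 6L,
                             stage_filters = c(512L, 256L, 128L, 64L),
                             residual_blocks_per_stage = 1L,
                             output_channels = 3L) {
  if (length(stage_filters) < 1L)
    dc_stop("bad_config", "at least one up-sampling stage required")
  if (any(diff(stage_filters) >= 0))
    dc_stop("bad_config", "stage_filters must be strictly decreasing")
  structure(list(latent_dim = as.integer(latent_dim),
                 seed_spatial = as.integer(seed_spatial),
                 stage_filters = as.integer(stage_filters),
                 residual_blocks_per_stage = as.integer(residual_blocks_per_stage),
                 output_channels = as.integer(output_channels),
                 output_size = as.integer(seed_spatial * 2^length(stage_filters))),
            class = "generator_config")
}

#' Discriminator configuration
#'
#' Exactly five stride-2 convolutions; filters increase along the schedule.
#'
#' @param input_size image side; must be divisible by 32 (five halvings).
#' @param layer_filters five increasing filter counts.
#' @return a `discriminator_config` list.
#' @export
discriminator_config <- function(input_size = 96L,
                                 layer_filters = c(32L, 64L, 128L, 256L, 512L)) {
  if (length(layer_filters) != 5L)
    dc_stop("bad_config", "the discriminator uses exactly 5 conv layers")
  if (any(diff(layer_filters) <= 0))
    dc_stop("bad_config", "layer_filters must be increasing")
  if (input_size %% 32L != 0L)
    dc_stop("bad_config", "input_size must be divisible by 32")
  structure(list(input_size = as.integer(input_size),
                 layer_filters = as.integer(layer_filters)),
            class = "discriminator_config")
}

#' GAN training configuration
#'
#' Non-saturating binary cross-entropy losses, Adam (2e-4, beta1 = 0.5),
#' optional one-sided label smoothing on real targets.
#'
#' @param batch_size,steps,learning_rate,beta1,seed scalars.
#' @param label_smoothing real targets become 0.9 when `TRUE`.
#' @return a `gan_train_config` list.
#' @export
gan_train_config <- function(batch_size = 32L, steps = 300L,
                             learning_rate = 2e-4, beta1 = 0.5,
                             label_smoothing = TRUE, seed = 42L) {
  if (steps < 1L) dc_stop("bad_config", "steps must be >= 1")
  structure(list(batch_size = as.integer(batch_size), steps = as.integer(steps),
                 learning_rate = learning_rate, beta1 = beta1,
                 label_smoothing = label_smoothing, seed = as.integer(seed)),
            class = "gan_train_config")
}

#' Build the residual generator
#'
#' @param cfg a [generator_config()].
#' @return a `dc_generator` model (weights allocated immediately).
#' @export
build_generator <- function(cfg) {
  f <- cfg$stage_filters
  L <- list()
  L[["proj"]] <- nn_dense(cfg$latent_dim, cfg$seed_spatial^2 * f[1])
  cin <- f[1]
  for (i in seq_along(f)) {
    L[[paste0("s", i, "_up")]] <- nn_conv(3, cin, f[i])
    L[[paste0("s", i, "_upnorm")]] <- nn_norm(f[i], kind = "group", groups = 8)
    for (j in seq_len(cfg$residual_blocks_per_stage)) {
      p <- paste0("s", i, "_r", j, "_")
      L[[paste0(p, "conv1")]] <- nn_conv(3, f[i], f[i])
      L[[paste0(p, "norm1")]] <- nn_norm(f[i], kind = "group", groups = 8)
      L[[paste0(p, "conv2")]] <- nn_conv(3, f[i], f[i])
      L[[paste0(p, "norm2")]] <- nn_norm(f[i], kind = "group", groups = 8)
    }
    cin <- f[i]
  }
  L[["out_conv"]] <- nn_conv(3, cin, cfg$output_channels)
  m <- structure(list(config = cfg, layers = lapply(L, layer_init),
                      initialized = TRUE), class = "dc_generator")
  m
}

gen_forward <- function(model, z, training = FALSE) {
  cfg <- model$config
  cs <- new.env(parent = emptyenv())
  r <- layer_forward(model$layers[["proj"]], z, training)
  assign("proj", r$cache, envir = cs)
  n <- nrow(z)
  h <- array(t(r$y), c(cfg$seed_spatial, cfg$seed_spatial,
                       cfg$stage_filters[1], n))
  for (i in seq_along(cfg$stage_filters)) {
    h <- .upsample2_fwd(h)
    rr <- run_seq_fwd(model, c(paste0("s", i, "_up"), paste0("s", i, "_upnorm"),
                               paste0("s", i, "_relu0")), h, training, cs)
    model <- rr$model; h <- rr$y
    for (j in seq_len(cfg$residual_blocks_per_stage)) {
      p <- paste0("s", i, "_r", j, "_")
      skip <- h
      rr <- run_seq_fwd(model, c(paste0(p, "conv1"), paste0(p, "norm1"),
                                 paste0(p, "relu1"), paste0(p, "conv2"),
                                 paste0(p, "norm2")), h, training, cs)
      model <- rr$model
      h <- rr$y + skip
      assign(paste0(p, "post"), h > 0, envir = cs)
      h <- pmax(h, 0)
    }
  }
  r <- layer_forward(model$layers[["out_conv"]], h, training)
  assign("out_conv", r$cache, envir = cs)
  y <- (tanh(r$y) + 1) / 2
  list(y = y, cache = cs, model = model)
}

gen_backward <- function(model, fwd, dy) {
  cfg <- model$config
  cs <- fwd$cache
  gs <- new.env(parent = emptyenv())
  dz <- dy * (1 - (2 * fwd$y - 1)^2) / 2
  r <- layer_backward(model$layers[["out_conv"]], get("out_conv", envir = cs), dz)
  assign("out_conv", r$grads, envir = gs)
  dh <- r$dx
  for (i in rev(seq_along(cfg$stage_filters))) {
    for (j in rev(seq_len(cfg$residual_blocks_per_stage))) {
      p <- paste0("s", i, "_r", j, "_")
      dh <- dh * get(paste0(p, "post"), envir = cs)
      dres <- run_seq_bwd(model, c(paste0(p, "conv1"), paste0(p, "norm1"),
                                   paste0(p, "relu1"), paste0(p, "conv2"),
                                   paste0(p, "norm2")), dh, cs, gs)
      dh <- dh + dres
    }
    dh <- run_seq_bwd(model, c(paste0("s", i, "_up"), paste0("s", i, "_upnorm"),
                               paste0("s", i, "_relu0")), dh, cs, gs)
    dh <- .upsample2_bwd(dh)
  }
  n <- dim(dh)[4]
  dflat <- t(matrix(dh, length(dh) / n, n))
  r <- layer_backward(model$layers[["proj"]], get("proj", envir = cs), dflat)
  assign("proj", r$grads, envir = gs)
  as.list(gs)
}

#' Build the 5-layer convolutional discriminator
#'
#' @param cfg a [discriminator_config()].
#' @return a `dc_discriminator` model.
#' @export
build_discriminator <- function(cfg) {
  L <- list()
  cin <- 3L
  for (i in 1:5) {
    L[[paste0("conv", i)]] <- nn_conv(3, cin, cfg$layer_filters[i], stride = 2L)
    L[[paste0("act", i)]] <- nn_act("lrelu")
    cin <- cfg$layer_filters[i]
  }
  fs <- cfg$input_size / 32L
  L[["flatten"]] <- nn_flatten()
  L[["fc"]] <- nn_dense(fs * fs * cin, 1L)
  L[["out"]] <- nn_act("sigmoid")
  net <- nn_init(nn_network(L))
  structure(list(config = cfg, layers = net$layers, initialized = TRUE),
            class = "dc_discriminator")
}

disc_forward <- function(model, x, training = FALSE) {
  d <- dim(x)
  if (d[1] != model$config$input_size)
    dc_stop("shape_mismatch", "discriminator expects ",
            model$config$input_size, "px input")
  r <- net_forward(model, x, training)
  r$y <- as.numeric(r$y)
  r
}

#' Adversarial training
#'
#' Alternating discriminator/generator updates with non-saturating BCE and
#' Adam; per-step history of both losses. Deterministic given `cfg$seed`.
#'
#' @param gen a [build_generator()] model.
#' @param disc a [build_discriminator()] model.
#' @param images real images: array `(H, W, 3, N)` or list of samples,
#'   already at the generator output size.
#' @param cfg a [gan_train_config()].
#' @return list with `generator`, `discriminator`, `history`.
#' @export
train_gan <- function(gen, disc, images, cfg = gan_train_config()) {
  if (is.list(images)) images <- samples_to_x(images)
  n <- dim(images)[4]
  if (n < 2L * cfg$batch_size)
    dc_stop("too_few_images", "need at least 2 x batch_size real images")
  set.seed(cfg$seed)
  std <- adam_state(); stg <- adam_state()
  real_t <- if (cfg$label_smoothing) 0.9 else 1
  hist <- data.frame()
  for (step in seq_len(cfg$steps)) {
    # --- discriminator update
    ridx <- sample.int(n, cfg$batch_size)
    z <- matrix(rnorm(cfg$batch_size * gen$config$latent_dim),
                cfg$batch_size)
    gf <- gen_forward(gen, z, training = TRUE)
    gen <- gf$model
    xb <- cat_batch(slab(images, ridx), gf$y)
    tb <- c(rep(real_t, cfg$batch_size), rep(0, cfg$batch_size))
    df <- disc_forward(disc, xb, training = TRUE)
    disc <- df$net
    l <- bce_loss(df$y, tb)
    db <- net_backward(disc, df$caches, matrix(l$grad, ncol = 1))
    up <- adam_step(disc, db$grads, std, lr = cfg$learning_rate,
                    beta1 = cfg$beta1)
    disc <- up$net; std <- up$state
    d_loss <- l$loss
    # --- generator update (non-saturating: push fakes toward "real")
    z <- matrix(rnorm(cfg$batch_size * gen$config$latent_dim),
                cfg$batch_size)
    gf <- gen_forward(gen, z, training = TRUE)
    gen <- gf$model
    df <- disc_forward(disc, gf$y, training = TRUE)
    l <- bce_loss(df$y, rep(1, cfg$batch_size))
    db <- net_backward(disc, df$caches, matrix(l$grad, ncol = 1))
    gg <- gen_backward(gen, gf, db$dx)
    up <- adam_step(gen, gg, stg, lr = cfg$learning_rate, beta1 = cfg$beta1)
    gen <- up$net; stg <- up$state
    hist <- rbind(hist, data.frame(step = step, d_loss = d_loss,
                                   g_loss = l$loss))
  }
  list(generator = gen, discriminator = disc, history = hist)
}

cat_batch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  y <- array(0, c(da[1], da[2], da[3], da[4] + db[4]))
  y[, , , seq_len(da[4])] <- a
  y[, , , da[4] + seq_len(db[4])] <- b
  y
}

#' Sample images from a generator
#'
#' @param gen a generator model.
#' @param n number of images (>= 0).
#' @param seed seed for the latent draws.
#' @return array `(H, W, 3, n)` with values in \[0,1\].
#' @export
sample_images <- function(gen, n, seed = 1L) {
  s <- gen$config$output_size
  if (n == 0) return(array(0, c(s, s, 3, 0)))
  set.seed(seed)
  z <- matrix(rnorm(n * gen$config$latent_dim), n)
  out <- array(0, c(s, s, 3, n))
  for (b in split(seq_len(n), ceiling(seq_len(n) / 32)))
    out[, , , b] <- gen_forward(gen, z[b, , drop = FALSE])$y
  out
}

#' Fixed random-projection feature embedding for Frechet scoring
#'
#' Average-pools images to an 8x8 grid, flattens, and projects through a
#' fixed seeded Gaussian matrix. A deterministic, training-free embedding:
#' the Frechet formula itself is embedding-agnostic.
#'
#' @param dim embedding dimension.
#' @param seed seed fixing the projection.
#' @return function mapping an image array `(H, W, 3, N)` to an `N x dim`
#'   feature matrix; carries attribute `name`.
#' @export
fid_embedding <- function(dim = 48L, seed = 7L) {
  rs <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  proj <- matrix(rnorm(8 * 8 * 3 * dim, 0, 1 / sqrt(8 * 8 * 3)),
                 8 * 8 * 3, dim)
  if (!is.null(rs)) assign(".Random.seed", rs, envir = globalenv())
  f <- function(images) {
    d <- dim(images)
    pooled <- block_mean(images, 8L)
    t(matrix(pooled, 8 * 8 * d[3], d[4])) %*% proj
  }
  attr(f, "name") <- sprintf("randproj%d_seed%d", dim, seed)
  f
}

block_mean <- function(images, out) {
  d <- dim(images)
  ri <- ceiling(seq_len(d[1]) * out / d[1])
  ci <- ceiling(seq_len(d[2]) * out / d[2])
  res <- array(0, c(out, out, d[3], d[4]))
  cnt <- tabulate(ri, out) %o% tabulate(ci, out)
  for (n in seq_len(d[4]))
    for (ch in seq_len(d[3])) {
      acc <- rowsum(t(rowsum(images[, , ch, n], ri)), ci)
      res[, , ch, n] <- t(acc) / cnt
    }
  res
}

sqrtm_psd <- function(m, jitter = 1e-10) {
  m <- (m + t(m)) / 2 + diag(jitter, nrow(m))
  e <- eigen(m, symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% (sqrt(v) * t(e$vectors))
}

#' Frechet distance between real and generated feature distributions
#'
#' `FID = ||mu_r - mu_f||^2 + Tr(S_r + S_f - 2 (S_r S_f)^(1/2))` with sample
#' means/covariances; the matrix square root is computed on the symmetrized
#' product `S_r^(1/2) S_f S_r^(1/2)` with a small diagonal jitter. Symmetric
#' in its arguments, non-negative up to numerical tolerance, and zero when
#' both sets coincide.
#'
#' @param real,fake image arrays `(H, W, 3, N)` or feature matrices `N x d`.
#' @param embedding feature extractor used when images are passed
#'   (default [fid_embedding()]).
#' @return a `fid_score` list: `value`, `embedding_name`, `n_real`, `n_fake`.
#' @export
compute_fid <- function(real, fake, embedding = fid_embedding()) {
  emb_name <- "features"
  if (length(dim(real)) == 4L) {
    emb_name <- attr(embedding, "name") %||% "embedding"
    real <- embedding(real)
    fake <- embedding(fake)
  }
  real <- as.matrix(real); fake <- as.matrix(fake)
  if (nrow(real) < 2L || nrow(fake) < 2L)
    dc_stop("too_few_samples", "need >= 2 samples per set")
  mur <- colMeans(real); muf <- colMeans(fake)
  sr <- cov(real); sf <- cov(fake)
  sr_h <- sqrtm_psd(sr)
  cross <- sqrtm_psd(sr_h %*% sf %*% sr_h)
  val <- sum((mur - muf)^2) + sum(diag(sr)) + sum(diag(sf)) -
    2 * sum(diag(cross))
  structure(list(value = max(val, 0), embedding_name = emb_name,
                 n_real = nrow(real), n_fake = nrow(fake)),
            class = "fid_score")
}

#' @export
print.fid_score <- function(x, ...) {
  cat(sprintf("FID %.4f  (%s; n_real %d, n_fake %d)\n", x$value,
              x$embedding_name, x$n_real, x$n_fake))
  invisible(x)
}
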