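# Neural-network layer primitives.
#
# Every layer is a plain list with a `type`, its hyper-parameters, a
# `param_shapes` description (so models can be counted without allocating
# weights) and, once initialised, a `params` list of arrays. Tensors are
# column-major R arrays with dim (H, W, C, N); dense activations are
# (N x D) matrices. Forward passes return list(y, cache); backward passes
# take the cache and dL/dy and return list(dx, grads).

nn_conv <- function(k, cin, cout, stride = 1L, dilation = 1L,
                    pad = c("same", "valid"), bias = TRUE) {
  pad <- match.arg(pad)
  list(type = "conv", k = as.integer(k), cin = as.integer(cin),
       cout = as.integer(cout), stride = as.integer(stride),
       dilation = as.integer(dilation), pad = pad, bias = bias,
       param_shapes = c(list(w = c(k, k, cin, cout)),
                        if (bias) list(b = cout)),
       params = NULL, trainable = TRUE)
}

# Transposed convolution, stride 2: zero-interleave the input to 2H x 2W
# then run an ordinary convolution ('same' output size 2H).
nn_tconv <- function(k, cin, cout, bias = TRUE) {
  l <- nn_conv(k, cin, cout, bias = bias)
  l$type <- "tconv"
  l
}

nn_dense <- function(din, dout, bias = TRUE) {
  list(type = "dense", din = as.integer(din), dout = as.integer(dout),
       bias = bias,
       param_shapes = c(list(w = c(din, dout)), if (bias) list(b = dout)),
       params = NULL, trainable = TRUE)
}

# Group or batch normalization over feature maps. Group norm normalizes each
# (sample, channel-group) cell over space; batch norm normalizes each channel
# over (space x batch) and keeps running statistics (the non-trainable pair).
nn_norm <- function(channels, kind = c("group", "batch"), groups = 32L,
                    eps = 1e-5, momentum = 0.9) {
  kind <- match.arg(kind)
  channels <- as.integer(channels)
  groups <- min(as.integer(groups), channels)
  while (channels %% groups != 0L) groups <- groups - 1L
  list(type = "norm", kind = kind, channels = channels, groups = groups,
       eps = eps, momentum = momentum,
       param_shapes = list(gamma = channels, beta = channels),
       params = NULL, trainable = TRUE,
       state = if (kind == "batch")
         list(mean = numeric(channels), var = rep(1, channels)) else NULL)
}

# 1-D variant of batch norm for dense activations (N x D matrices).
nn_norm1d <- function(dim, eps = 1e-5, momentum = 0.9) {
  l <- nn_norm(dim, kind = "batch", eps = eps, momentum = momentum)
  l$type <- "norm1d"
  l
}

nn_act <- function(fun = c("relu", "lrelu", "sigmoid", "tanh01", "linear")) {
  list(type = "act", fun = match.arg(fun), param_shapes = list(), params = NULL)
}

nn_maxpool <- function() list(type = "maxpool", param_shapes = list(), params = NULL)
nn_upsample <- function() list(type = "upsample", param_shapes = list(), params = NULL)
nn_flatten <- function() list(type = "flatten", param_shapes = list(), params = NULL)
nn_reshape <- function(dim) list(type = "reshape", dim = as.integer(dim),
                                 param_shapes = list(), params = NULL)
nn_gap <- function() list(type = "gap", param_shapes = list(), params = NULL)

# Spatial dropout zeroes whole channels per sample (rate = drop probability).
nn_spatial_dropout <- function(rate) {
  list(type = "sdrop", rate = rate, param_shapes = list(), params = NULL)
}
nn_dropout <- function(rate) {
  list(type = "drop", rate = rate, param_shapes = list(), params = NULL)
}

layer_n_params <- function(layer) {
  tr <- sum(vapply(layer$param_shapes, prod, 0))
  nt <- 0
  if (layer$type %in% c("norm", "norm1d") && layer$kind == "batch")
    nt <- 2 * layer$channels
  c(trainable = tr, non_trainable = nt)
}

layer_init <- function(layer) {
  if (length(layer$param_shapes) == 0) return(layer)
  ps <- list()
  if (layer$type %in% c("conv", "tconv")) {
    fan_in <- layer$k * layer$k * layer$cin
    ps$w <- array(rnorm(prod(layer$param_shapes$w), 0, sqrt(2 / fan_in)),
                  dim = layer$param_shapes$w)
    if (layer$bias) ps$b <- numeric(layer$cout)
  } else if (layer$type == "dense") {
    ps$w <- matrix(rnorm(layer$din * layer$dout, 0, sqrt(2 / layer$din)),
                   layer$din, layer$dout)
    if (layer$bias) ps$b <- numeric(layer$dout)
  } else if (layer$type %in% c("norm", "norm1d")) {
    ps$gamma <- rep(1, layer$channels)
    ps$beta <- numeric(layer$channels)
  }
  layer$params <- ps
  layer
}

conv_pad <- function(in_sz, k, dilation, stride, pad) {
  if (pad == "valid") return(c(0L, 0L))
  eff <- (k - 1L) * dilation + 1L
  out <- ceiling(in_sz / stride)
  tot <- max((out - 1L) * stride + eff - in_sz, 0L)
  lo <- tot %/% 2L
  c(lo, tot - lo)
}

layer_forward <- function(layer, x, training = FALSE) {
  switch(layer$type,
    conv = {
      d <- dim(x)
      ph <- conv_pad(d[1], layer$k, layer$dilation, layer$stride, layer$pad)
      pw <- conv_pad(d[2], layer$k, layer$dilation, layer$stride, layer$pad)
      y <- .conv2d_fwd(x, layer$params$w,
                       if (layer$bias) layer$params$b else numeric(0),
                       layer$stride, layer$dilation, ph[1], ph[2], pw[1], pw[2])
      list(y = y, cache = list(x = x, ph = ph, pw = pw))
    },
    tconv = {
      dx0 <- dim(x)
      d <- c(2L * dx0[1], 2L * dx0[2], dx0[3], dx0[4])
      xs <- array(0, dim = d)  # zero-interleaved upsampling
      xs[seq(1, d[1], 2), seq(1, d[2], 2), , ] <- x
      ph <- conv_pad(d[1], layer$k, 1L, 1L, "same")
      pw <- conv_pad(d[2], layer$k, 1L, 1L, "same")
      y <- .conv2d_fwd(xs, layer$params$w,
                       if (layer$bias) layer$params$b else numeric(0),
                       1L, 1L, ph[1], ph[2], pw[1], pw[2])
      list(y = y, cache = list(xs = xs, ph = ph, pw = pw))
    },
    dense = {
      y <- x %*% layer$params$w
      if (layer$bias) y <- sweep(y, 2, layer$params$b, "+")
      list(y = y, cache = list(x = x))
    },
    norm = norm_forward(layer, x, training),
    norm1d = norm1d_forward(layer, x, training),
    act = {
      y <- switch(layer$fun,
        relu = pmax(x, 0),
        lrelu = ifelse(x > 0, x, 0.2 * x),
        sigmoid = 1 / (1 + exp(-x)),
        tanh01 = (tanh(x) + 1) / 2,
        linear = x)
      if (!is.null(dim(x))) dim(y) <- dim(x)
      list(y = y, cache = list(x = x, y = y))
    },
    maxpool = {
      r <- .maxpool2_fwd(x)
      list(y = r$y, cache = list(idx = r$idx, xdim = dim(x)))
    },
    upsample = list(y = .upsample2_fwd(x), cache = NULL),
    flatten = {
      d <- dim(x)
      y <- t(matrix(x, prod(d[1:3]), d[4]))
      list(y = y, cache = list(xdim = d))
    },
    reshape = {
      n <- if (is.matrix(x)) nrow(x) else dim(x)[length(dim(x))]
      y <- array(if (is.matrix(x)) t(x) else x, dim = c(layer$dim, n))
      list(y = y, cache = list(xdim = dim(x), was_mat = is.matrix(x)))
    },
    gap = {
      d <- dim(x)
      y <- t(apply(array(x, c(d[1] * d[2], d[3], d[4])), c(2, 3), mean))
      if (d[3] == 1L) y <- matrix(y, ncol = 1L)
      list(y = y, cache = list(xdim = d))
    },
    sdrop = {
      if (!training || layer$rate <= 0) return(list(y = x, cache = list(mask = NULL)))
      d <- dim(x)
      keep <- array(runif(d[3] * d[4]) >= layer$rate, c(d[3], d[4]))
      m <- array(rep(as.numeric(keep), each = d[1] * d[2]), d) / (1 - layer$rate)
      list(y = x * m, cache = list(mask = m))
    },
    drop = {
      if (!training || layer$rate <= 0) return(list(y = x, cache = list(mask = NULL)))
      m <- array(as.numeric(runif(length(x)) >= layer$rate), dim = dim(x) %||% length(x)) /
        (1 - layer$rate)
      list(y = x * m, cache = list(mask = m))
    },
    dc_stop("bad_layer", "unknown layer type: ", layer$type))
}

layer_backward <- function(layer, cache, dy) {
  switch(layer$type,
    conv = {
      g <- .conv2d_bwd(cache$x, layer$params$w, dy, layer$stride, layer$dilation,
                       cache$ph[1], cache$ph[2], cache$pw[1], cache$pw[2],
                       layer$bias)
      list(dx = g$dx,
           grads = c(list(w = g$dw), if (layer$bias) list(b = g$db)))
    },
    tconv = {
      g <- .conv2d_bwd(cache$xs, layer$params$w, dy, 1L, 1L,
                       cache$ph[1], cache$ph[2], cache$pw[1], cache$pw[2],
                       layer$bias)
      d <- dim(g$dx)
      dx <- g$dx[seq(1, d[1], 2), seq(1, d[2], 2), , , drop = FALSE]
      list(dx = dx, grads = c(list(w = g$dw), if (layer$bias) list(b = g$db)))
    },
    dense = {
      list(dx = dy %*% t(layer$params$w),
           grads = c(list(w = t(cache$x) %*% dy),
                     if (layer$bias) list(b = colSums(dy))))
    },
    norm = norm_backward(layer, cache, dy),
    norm1d = norm1d_backward(layer, cache, dy),
    act = {
      dx <- switch(layer$fun,
        relu = dy * (cache$x > 0),
        lrelu = dy * ifelse(cache$x > 0, 1, 0.2),
        sigmoid = dy * cache$y * (1 - cache$y),
        tanh01 = dy * (1 - (2 * cache$y - 1)^2) / 2,
        linear = dy)
      if (!is.null(dim(cache$x))) dim(dx) <- dim(cache$x)
      list(dx = dx, grads = NULL)
    },
    maxpool = list(dx = .maxpool2_bwd(dy, cache$idx, cache$xdim), grads = NULL),
    upsample = list(dx = .upsample2_bwd(dy), grads = NULL),
    flatten = {
      dx <- array(t(dy), dim = cache$xdim)
      list(dx = dx, grads = NULL)
    },
    reshape = {
      dx <- if (cache$was_mat) {
        n <- dim(dy)[length(dim(dy))]
        t(matrix(dy, length(dy) / n, n))
      } else array(dy, dim = cache$xdim)
      list(dx = dx, grads = NULL)
    },
    gap = {
      d <- cache$xdim
      dx <- array(rep(t(dy), each = d[1] * d[2]) / (d[1] * d[2]), d)
      list(dx = dx, grads = NULL)
    },
    sdrop = ,
    drop = {
      if (is.null(cache$mask)) list(dx = dy, grads = NULL)
      else list(dx = dy * cache$mask, grads = NULL)
    },
    dc_stop("bad_layer", "unknown layer type: ", layer$type))
}

# ---- normalization internals -------------------------------------------------

norm_forward <- function(layer, x, training) {
  d <- dim(x)
  C <- layer$channels
  if (d[3] != C) dc_stop("norm_mismatch", "norm layer expects ", C, " channels")
  gamma <- layer$params$gamma; beta <- layer$params$beta
  if (layer$kind == "group") {
    G <- layer$groups; cs <- C / G
    xr <- array(x, c(d[1] * d[2] * cs, G, d[4]))
    mu <- apply(xr, c(2, 3), mean)
    v <- apply(xr, c(2, 3), function(z) mean((z - mean(z))^2))
    mu_b <- array(rep(mu, each = d[1] * d[2] * cs), dim = d)
    sd_b <- array(rep(sqrt(v + layer$eps), each = d[1] * d[2] * cs), dim = d)
    xhat <- (x - mu_b) / sd_b
  } else {
    if (training) {
      xr <- array(aperm(x, c(1, 2, 4, 3)), c(d[1] * d[2] * d[4], C))
      mu <- colMeans(xr)
      v <- colMeans(sweep(xr, 2, mu)^2)
      layer$state$mean <- layer$momentum * layer$state$mean + (1 - layer$momentum) * mu
      layer$state$var <- layer$momentum * layer$state$var + (1 - layer$momentum) * v
    } else {
      mu <- layer$state$mean; v <- layer$state$var
    }
    mu_b <- array(rep(rep(mu, each = d[1] * d[2]), d[4]), dim = d)
    sd_b <- array(rep(rep(sqrt(v + layer$eps), each = d[1] * d[2]), d[4]), dim = d)
    xhat <- (x - mu_b) / sd_b
  }
  gm <- array(rep(rep(gamma, each = d[1] * d[2]), d[4]), dim = d)
  bt <- array(rep(rep(beta, each = d[1] * d[2]), d[4]), dim = d)
  list(y = gm * xhat + bt,
       cache = list(xhat = xhat, sd_b = sd_b, d = d, training = training),
       layer = layer)
}

norm_backward <- function(layer, cache, dy) {
  d <- cache$d
  C <- layer$channels
  gamma <- layer$params$gamma
  gm <- array(rep(rep(gamma, each = d[1] * d[2]), d[4]), dim = d)
  dxhat <- dy * gm
  xhat <- cache$xhat
  per_ch <- function(a) apply(array(a, c(d[1] * d[2], C, d[4])), 2, sum)
  dgamma <- per_ch(dy * xhat)
  dbeta <- per_ch(dy)
  if (layer$kind == "group" || cache$training) {
    if (layer$kind == "group") {
      G <- layer$groups; cs <- C / G; m <- d[1] * d[2] * cs
      rs <- function(a) array(a, c(m, G, d[4]))
      s1 <- apply(rs(dxhat), c(2, 3), sum)
      s2 <- apply(rs(dxhat * xhat), c(2, 3), sum)
      s1b <- array(rep(s1, each = m), dim = d)
      s2b <- array(rep(s2, each = m), dim = d)
    } else {
      m <- d[1] * d[2] * d[4]
      s1 <- per_ch(dxhat)
      s2 <- per_ch(dxhat * xhat)
      s1b <- array(rep(rep(s1, each = d[1] * d[2]), d[4]), dim = d)
      s2b <- array(rep(rep(s2, each = d[1] * d[2]), d[4]), dim = d)
    }
    dx <- (dxhat - s1b / m - xhat * s2b / m) / cache$sd_b
  } else {
    dx <- dxhat / cache$sd_b  # inference-mode batch norm: fixed statistics
  }
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

norm1d_forward <- function(layer, x, training) {
  C <- layer$channels
  if (ncol(x) != C) dc_stop("norm_mismatch", "norm1d expects ", C, " columns")
  if (training && nrow(x) > 1) {
    mu <- colMeans(x)
    v <- colMeans(sweep(x, 2, mu)^2)
    layer$state$mean <- layer$momentum * layer$state$mean + (1 - layer$momentum) * mu
    layer$state$var <- layer$momentum * layer$state$var + (1 - layer$momentum) * v
  } else {
    mu <- layer$state$mean; v <- layer$state$var
  }
  sdv <- sqrt(v + layer$eps)
  xhat <- sweep(sweep(x, 2, mu), 2, sdv, "/")
  y <- sweep(sweep(xhat, 2, layer$params$gamma, "*"), 2, layer$params$beta, "+")
  list(y = y, cache = list(xhat = xhat, sdv = sdv, training = training && nrow(x) > 1),
       layer = layer)
}

norm1d_backward <- function(layer, cache, dy) {
  xhat <- cache$xhat
  dxhat <- sweep(dy, 2, layer$params$gamma, "*")
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  if (cache$training) {
    m <- nrow(dy)
    dx <- sweep(dxhat - matrix(colSums(dxhat), m, ncol(dy), byrow = TRUE) / m -
                  xhat * matrix(colSums(dxhat * xhat), m, ncol(dy), byrow = TRUE) / m,
                2, cache$sdv, "/")
  } else {
    dx <- sweep(dxhat, 2, cache$sdv, "/")
  }
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}
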