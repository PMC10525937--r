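# Minimal 1-D neural-network layer engine on base-R matrix operations.
#
# Tensor convention: hidden activations are 3-D arrays (batch n, time T,
# channels C); dense-stack activations are matrices (n, features). Each layer
# is a list with a `type`, weight tensors in `params`, non-trainable state in
# `state`, and static shape info. Forward passes return the output plus a
# cache consumed by the matching backward pass; backward passes return the
# input gradient and per-parameter gradients in the order of `params`.

glorot_ <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -lim, lim), dim = dims)
}

layer_conv1d <- function(in_channels, filters, kernel = 3L,
                         padding = c("same", "valid")) {
  padding <- match.arg(padding)
  list(type = "conv1d", kernel = as.integer(kernel),
       in_channels = as.integer(in_channels), filters = as.integer(filters),
       padding = padding,
       params = list(W = glorot_(kernel * in_channels, filters,
                                 c(kernel * in_channels, filters)),
                     b = numeric(filters)))
}

layer_dense <- function(n_in, n_out) {
  list(type = "dense", n_in = as.integer(n_in), n_out = as.integer(n_out),
       params = list(W = glorot_(n_in, n_out, c(n_in, n_out)),
                     b = numeric(n_out)))
}

layer_batchnorm <- function(channels, momentum = 0.9, eps = 1e-3) {
  list(type = "batchnorm", channels = as.integer(channels),
       momentum = momentum, eps = eps,
       params = list(gamma = rep(1, channels), beta = numeric(channels)),
       state = list(mean = numeric(channels), var = rep(1, channels)))
}

layer_relu <- function() list(type = "relu", params = list())

layer_pool1d <- function(kind = c("max", "average"), size = 2L) {
  stopifnot(size == 2L)  # the architecture family fixes the pool size at 2
  list(type = "pool1d", kind = match.arg(kind), size = as.integer(size),
       params = list())
}

layer_gap <- function() list(type = "gap", params = list())

layer_flatten <- function() list(type = "flatten", params = list())

layer_dropout <- function(rate = 0.5)
  list(type = "dropout", rate = rate, params = list())

layer_lstm <- function(input_dim, units, return_sequences = FALSE) {
  d <- as.integer(input_dim); u <- as.integer(units)
  b <- numeric(4L * u)
  b[(u + 1L):(2L * u)] <- 1   # forget-gate bias init
  list(type = "lstm", input_dim = d, units = u,
       return_sequences = return_sequences,
       params = list(W = glorot_(d + u, 4L * u, c(d + u, 4L * u)), b = b))
}

layer_softmax <- function() list(type = "softmax", params = list())

# ---------------------------------------------------------------------------
# forward passes

# (n, T, C) -> (n*T, C) view; column-major layout keeps (batch, time) order
# consistent across taps.
flat2_ <- function(x) { d <- dim(x); dim(x) <- c(d[1] * d[2], d[3]); x }

im2col_ <- function(x, kernel, padding) {
  d <- dim(x); n <- d[1]; T <- d[2]; C <- d[3]
  if (padding == "same") {
    l <- (kernel - 1L) %/% 2L
    xp <- array(0, c(n, T + kernel - 1L, C))
    xp[, (l + 1L):(l + T), ] <- x
    Tout <- T
  } else {
    xp <- x
    Tout <- T - kernel + 1L
    if (Tout < 1L)
      abort_("locomode_temporal_collapse",
             "input of length %d too short for kernel %d", T, kernel)
  }
  cols <- matrix(0, n * Tout, kernel * C)
  for (j in seq_len(kernel)) {
    sl <- xp[, j:(j + Tout - 1L), , drop = FALSE]
    dim(sl) <- c(n * Tout, C)
    cols[, ((j - 1L) * C + 1L):(j * C)] <- sl
  }
  list(cols = cols, n = n, T = T, Tout = Tout, C = C)
}

fw_conv1d <- function(ly, x, training) {
  ic <- im2col_(x, ly$kernel, ly$padding)
  y <- ic$cols %*% ly$params$W
  y <- y + rep(ly$params$b, each = nrow(y))
  dim(y) <- c(ic$n, ic$Tout, ly$filters)
  list(out = y, cache = if (training) ic else NULL, layer = ly)
}

bw_conv1d <- function(ly, cache, dy) {
  n <- cache$n; Tout <- cache$Tout; C <- cache$C; k <- ly$kernel
  dim(dy) <- c(n * Tout, ly$filters)
  dW <- crossprod(cache$cols, dy)
  db <- colSums(dy)
  dcols <- dy %*% t(ly$params$W)
  if (ly$padding == "same") {
    l <- (k - 1L) %/% 2L
    Tp <- cache$T + k - 1L
  } else {
    l <- 0L
    Tp <- cache$T
  }
  dxp <- array(0, c(n, Tp, C))
  for (j in seq_len(k)) {
    dsl <- dcols[, ((j - 1L) * C + 1L):(j * C), drop = FALSE]
    dim(dsl) <- c(n, Tout, C)
    dxp[, j:(j + Tout - 1L), ] <- dxp[, j:(j + Tout - 1L), , drop = FALSE] + dsl
  }
  dx <- dxp[, (l + 1L):(l + cache$T), , drop = FALSE]
  list(dx = dx, grads = list(W = dW, b = db))
}

fw_dense <- function(ly, x, training) {
  y <- x %*% ly$params$W
  y <- y + rep(ly$params$b, each = nrow(y))
  list(out = y, cache = if (training) x else NULL, layer = ly)
}

bw_dense <- function(ly, cache, dy) {
  list(dx = dy %*% t(ly$params$W),
       grads = list(W = crossprod(cache, dy), b = colSums(dy)))
}

# column-wise broadcast helpers (cheaper than sweep for (N, C) matrices)
brd_ <- function(v, N) rep(v, each = N)

fw_batchnorm <- function(ly, x, training) {
  d3 <- length(dim(x)) == 3L
  xm <- if (d3) flat2_(x) else x
  N <- nrow(xm)
  if (training) {
    mu <- colMeans(xm)
    xc <- xm - brd_(mu, N)
    v <- colMeans(xc * xc)
    ly$state$mean <- ly$momentum * ly$state$mean + (1 - ly$momentum) * mu
    ly$state$var <- ly$momentum * ly$state$var + (1 - ly$momentum) * v
  } else {
    mu <- ly$state$mean
    v <- ly$state$var
    xc <- xm - brd_(mu, N)
  }
  ivar <- 1 / sqrt(v + ly$eps)
  xhat <- xc * brd_(ivar, N)
  y <- xhat * brd_(ly$params$gamma, N) + brd_(ly$params$beta, N)
  if (d3) dim(y) <- dim(x)
  list(out = y,
       cache = if (training) list(xhat = xhat, ivar = ivar, d3 = d3,
                                  dims = dim(x)) else NULL,
       layer = ly)
}

bw_batchnorm <- function(ly, cache, dy) {
  dym <- if (cache$d3) flat2_(dy) else dy
  N <- nrow(dym)
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  # dx = gamma*ivar/N * (N*dy - sum(dy) - xhat * sum(dy*xhat))
  t1 <- N * dym - brd_(dbeta, N) - cache$xhat * brd_(dgamma, N)
  dx <- t1 * brd_(ly$params$gamma * cache$ivar / N, N)
  if (cache$d3) dim(dx) <- cache$dims
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

fw_relu <- function(ly, x, training) {
  y <- x * (x > 0)
  list(out = y, cache = if (training) (x > 0) else NULL, layer = ly)
}

bw_relu <- function(ly, cache, dy) list(dx = dy * cache, grads = list())

fw_pool1d <- function(ly, x, training) {
  d <- dim(x); n <- d[1]; T <- d[2]; C <- d[3]
  Tout <- T %/% ly$size
  if (Tout < 1L)
    abort_("locomode_temporal_collapse",
           "input of length %d too short for pool size %d", T, ly$size)
  a <- x[, seq.int(1L, 2L * Tout, by = 2L), , drop = FALSE]
  b <- x[, seq.int(2L, 2L * Tout, by = 2L), , drop = FALSE]
  if (ly$kind == "max") {
    y <- pmax(a, b)
    cache <- if (training) list(mask = (a >= b), T = T, Tout = Tout) else NULL
  } else {
    y <- (a + b) / 2
    cache <- if (training) list(mask = NULL, T = T, Tout = Tout) else NULL
  }
  list(out = y, cache = cache, layer = ly)
}

bw_pool1d <- function(ly, cache, dy) {
  d <- dim(dy); n <- d[1]; C <- d[3]
  dx <- array(0, c(n, cache$T, C))
  io <- seq.int(1L, 2L * cache$Tout, by = 2L)
  ie <- seq.int(2L, 2L * cache$Tout, by = 2L)
  if (ly$kind == "max") {
    dx[, io, ] <- dy * cache$mask
    dx[, ie, ] <- dy * !cache$mask
  } else {
    dx[, io, ] <- dy / 2
    dx[, ie, ] <- dy / 2
  }
  list(dx = dx, grads = list())
}

fw_gap <- function(ly, x, training) {
  d <- dim(x)
  xp <- aperm(x, c(2L, 1L, 3L))
  dim(xp) <- c(d[2], d[1] * d[3])
  y <- colMeans(xp)
  dim(y) <- c(d[1], d[3])
  list(out = y, cache = if (training) d else NULL, layer = ly)
}

bw_gap <- function(ly, cache, dy) {
  d <- cache
  g <- dy / d[2]                                   # (n, C)
  dx <- aperm(array(g, c(d[1], d[3], d[2])), c(1L, 3L, 2L))
  list(dx = dx, grads = list())
}

fw_flatten <- function(ly, x, training) {
  d <- dim(x)
  # (n, T, C) -> (n, T*C)
  y <- x
  dim(y) <- c(d[1], d[2] * d[3])
  list(out = y, cache = if (training) d else NULL, layer = ly)
}

bw_flatten <- function(ly, cache, dy) {
  dim(dy) <- cache
  list(dx = dy, grads = list())
}

fw_dropout <- function(ly, x, training) {
  if (!training || ly$rate <= 0)
    return(list(out = x, cache = NULL, layer = ly))
  mask <- array(runif(length(x)) >= ly$rate, dim = dim(x)) / (1 - ly$rate)
  list(out = x * mask, cache = mask, layer = ly)
}

bw_dropout <- function(ly, cache, dy) {
  list(dx = if (is.null(cache)) dy else dy * cache, grads = list())
}

sigm_ <- function(x) 1 / (1 + exp(-x))

fw_lstm <- function(ly, x, training) {
  d <- dim(x); n <- d[1]; T <- d[2]
  u <- ly$units
  W <- ly$params$W; b <- ly$params$b
  h <- matrix(0, n, u); cc <- matrix(0, n, u)
  H <- if (ly$return_sequences || training) array(0, c(n, T, u)) else NULL
  cache <- if (training) vector("list", T) else NULL
  for (t in seq_len(T)) {
    xt <- x[, t, , drop = FALSE]; dim(xt) <- c(n, d[3])
    z <- cbind(xt, h) %*% W
    z <- z + rep(b, each = n)
    i <- sigm_(z[, 1:u, drop = FALSE])
    f <- sigm_(z[, (u + 1):(2 * u), drop = FALSE])
    g <- tanh(z[, (2 * u + 1):(3 * u), drop = FALSE])
    o <- sigm_(z[, (3 * u + 1):(4 * u), drop = FALSE])
    c_prev <- cc
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    h <- o * tc
    if (!is.null(H)) H[, t, ] <- h
    if (training)
      cache[[t]] <- list(xt = xt, i = i, f = f, g = g, o = o,
                         c_prev = c_prev, tc = tc)
  }
  out <- if (ly$return_sequences) H else h
  list(out = out,
       cache = if (training) list(steps = cache, n = n, T = T) else NULL,
       layer = ly)
}

bw_lstm <- function(ly, cache, dy) {
  n <- cache$n; T <- cache$T; u <- ly$units; d <- ly$input_dim
  W <- ly$params$W
  dW <- matrix(0, d + u, 4 * u); db <- numeric(4 * u)
  dh_next <- matrix(0, n, u); dc_next <- matrix(0, n, u)
  dx <- array(0, c(n, T, d))
  seq_out <- ly$return_sequences
  # recover h_{t-1} from the per-step caches (h_t = o_t * tanh(c_t))
  h_prev_of <- function(t) {
    if (t == 1L) matrix(0, n, u)
    else cache$steps[[t - 1L]]$o * cache$steps[[t - 1L]]$tc
  }
  for (t in rev(seq_len(T))) {
    st <- cache$steps[[t]]
    dh <- dh_next
    if (seq_out) {
      dyt <- dy[, t, , drop = FALSE]; dim(dyt) <- c(n, u)
      dh <- dh + dyt
    } else if (t == T) {
      dh <- dh + dy
    }
    do_ <- dh * st$tc
    dc <- dc_next + dh * st$o * (1 - st$tc^2)
    di <- dc * st$g
    dg <- dc * st$i
    df <- dc * st$c_prev
    dc_next <- dc * st$f
    dz <- cbind(di * st$i * (1 - st$i),
                df * st$f * (1 - st$f),
                dg * (1 - st$g^2),
                do_ * st$o * (1 - st$o))
    inp <- cbind(st$xt, h_prev_of(t))
    dW <- dW + crossprod(inp, dz)
    db <- db + colSums(dz)
    dinp <- dz %*% t(W)
    dx[, t, ] <- dinp[, seq_len(d), drop = FALSE]
    dh_next <- dinp[, d + seq_len(u), drop = FALSE]
  }
  list(dx = dx, grads = list(W = dW, b = db))
}

fw_softmax <- function(ly, x, training) {
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  p <- e / rowSums(e)
  list(out = p, cache = if (training) p else NULL, layer = ly)
}

bw_softmax <- function(ly, cache, dy) {
  p <- cache
  list(dx = p * (dy - rowSums(dy * p)), grads = list())
}

.fw_table <- list(conv1d = fw_conv1d, dense = fw_dense,
                  batchnorm = fw_batchnorm, relu = fw_relu,
                  pool1d = fw_pool1d, gap = fw_gap, flatten = fw_flatten,
                  dropout = fw_dropout, lstm = fw_lstm, softmax = fw_softmax)
.bw_table <- list(conv1d = bw_conv1d, dense = bw_dense,
                  batchnorm = bw_batchnorm, relu = bw_relu,
                  pool1d = bw_pool1d, gap = bw_gap, flatten = bw_flatten,
                  dropout = bw_dropout, lstm = bw_lstm, softmax = bw_softmax)

layer_forward <- function(ly, x, training = FALSE)
  .fw_table[[ly$type]](ly, x, training)

layer_backward <- function(ly, cache, dy)
  .bw_table[[ly$type]](ly, cache, dy)
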