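# Core differentiable tensor operations.
#
# The universal tensor contract is a numeric 4-D array with
# dim = c(H, W, C, N): spatial height, width, channels, batch. Every op here
# comes as a `*_fw` returning `list(y, cache)` and a matching `*_bw` taking
# the upstream gradient and the cache; backward passes are hand-derived and
# verified against central finite differences in the test suite.

#' Construct a feature map
#'
#' Coerces a numeric array to the `(H, W, C, N)` feature-map layout used by
#' every network module. 2-D inputs become single-channel single-sample maps;
#' 3-D inputs are treated as `(H, W, C)` with one sample.
#'
#' @param x numeric array with 2, 3 or 4 dimensions.
#' @return a 4-D numeric array `(H, W, C, N)`.
#' @export
as_feature_map <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("x must be an array")
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  else if (length(d) == 3L) dim(x) <- c(d, 1L)
  else if (length(d) != 4L) stop("x must have 2-4 dimensions")
  storage.mode(x) <- "double"
  x
}

fm_dims <- function(x) {
  d <- dim(x)
  stopifnot(length(d) == 4L)
  list(H = d[1L], W = d[2L], C = d[3L], N = d[4L])
}

conv2d_fw <- function(x, w, b = NULL, pad = (dim(w)[1L] - 1L) %/% 2L, groups = 1L) {
  y <- .conv2d_fw_cpp(x, w, if (is.null(b)) numeric(0) else b, as.integer(pad), as.integer(groups))
  list(y = y, cache = list(x = x, w = w, pad = as.integer(pad),
                           groups = as.integer(groups), has_bias = !is.null(b)))
}

conv2d_bw <- function(cache, dy) {
  g <- .conv2d_bw_cpp(cache$x, cache$w, dy, cache$pad, cache$groups, cache$has_bias)
  list(dx = g$dx, dw = g$dw, db = if (cache$has_bias) as.numeric(g$db) else NULL)
}

maxpool2_fw <- function(x) {
  r <- .maxpool2_fw_cpp(x)
  list(y = r$y, cache = list(idx = r$idx, H = dim(x)[1L], W = dim(x)[2L]))
}

maxpool2_bw <- function(cache, dy) .maxpool2_bw_cpp(dy, cache$idx, cache$H, cache$W)

upsample2_fw <- function(x) list(y = .upsample2_fw_cpp(x), cache = NULL)

upsample2_bw <- function(cache, dy) .upsample2_bw_cpp(dy)

relu_fw <- function(x) {
  y <- x * (x > 0)
  list(y = y, cache = x > 0)
}

relu_bw <- function(cache, dy) dy * cache

sigmoid_fw <- function(x) {
  y <- 1 / (1 + exp(-x))
  list(y = y, cache = y)
}

sigmoid_bw <- function(cache, dy) dy * cache * (1 - cache)

# Fast channel-axis reductions; all return (H, W, 1, N) arrays.
sum_channels <- function(x) {
  d <- dim(x)
  x2 <- x
  dim(x2) <- c(d[1L] * d[2L], d[3L], d[4L])
  o <- matrix(0, d[1L] * d[2L], d[4L])
  for (n in seq_len(d[4L])) o[, n] <- rowSums(x2[, , n, drop = FALSE])
  dim(o) <- c(d[1L], d[2L], 1L, d[4L])
  o
}

max_channels <- function(x) {
  d <- dim(x)
  m <- x[, , 1L, , drop = FALSE]
  if (d[3L] > 1L)
    for (c in 2:d[3L]) m <- pmax(m, x[, , c, , drop = FALSE])
  m
}

argmax_channels <- function(x) {
  d <- dim(x)
  best <- x[, , 1L, , drop = FALSE]
  amax <- array(1L, dim = c(d[1L], d[2L], 1L, d[4L]))
  if (d[3L] > 1L)
    for (c in 2:d[3L]) {
      xc <- x[, , c, , drop = FALSE]
      sel <- xc > best
      best[sel] <- xc[sel]
      amax[sel] <- c
    }
  amax
}

# Softmax over the channel axis (axis 3 of the H,W,C,N layout), per pixel.
softmax_channel <- function(x) {
  d <- dim(x)
  e <- exp(x - bcast_channel(max_channels(x), d[3L]))
  e / bcast_channel(sum_channels(e), d[3L])
}

softmax_channel_fw <- function(x) {
  p <- softmax_channel(x)
  list(y = p, cache = p)
}

# dx = p * (dy - sum_c(dy * p))
softmax_channel_bw <- function(cache, dy) {
  p <- cache
  p * (dy - bcast_channel(sum_channels(dy * p), dim(p)[3L]))
}

# Batch normalization over (H, W, N) per channel, using current-batch moments
# in both training and inference (no running statistics are kept; evaluation
# is done per slice so outputs stay deterministic).
batchnorm_fw <- function(x, gamma, beta, eps = 1e-5) {
  d <- fm_dims(x)
  xhat <- x
  istd <- numeric(d$C)
  for (c in seq_len(d$C)) {
    xc <- x[, , c, ]
    mu <- mean(xc)
    v <- mean((xc - mu)^2)
    istd[c] <- 1 / sqrt(v + eps)
    xhat[, , c, ] <- (xc - mu) * istd[c]
  }
  y <- xhat
  for (c in seq_len(d$C)) y[, , c, ] <- xhat[, , c, ] * gamma[c] + beta[c]
  list(y = y, cache = list(xhat = xhat, istd = istd, gamma = gamma))
}

batchnorm_bw <- function(cache, dy) {
  d <- dim(dy)
  C <- d[3L]
  dgamma <- numeric(C)
  dbeta <- numeric(C)
  dx <- dy
  for (c in seq_len(C)) {
    dyc <- dy[, , c, ]
    xh <- cache$xhat[, , c, ]
    dgamma[c] <- sum(dyc * xh)
    dbeta[c] <- sum(dyc)
    dxh <- dyc * cache$gamma[c]
    dx[, , c, ] <- (dxh - mean(dxh) - xh * mean(dxh * xh)) * cache$istd[c]
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# Channel concatenation / split
cat_channel <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1L]])
  cs <- vapply(xs, function(x) dim(x)[3L], integer(1L))
  y <- array(0, dim = c(d[1L], d[2L], sum(cs), d[4L]))
  off <- 0L
  for (x in xs) {
    y[, , off + seq_len(dim(x)[3L]), ] <- x
    off <- off + dim(x)[3L]
  }
  y
}

# Broadcast a per-channel map (1, 1, C, N) across an H x W grid.
bcast_spatial <- function(g, H, W) {
  d <- dim(g)
  array(rep(as.vector(g), each = H * W), dim = c(H, W, d[3L], d[4L]))
}

# Broadcast a single-channel map (H, W, 1, N) across `ch` channels.
bcast_channel <- function(g, ch) {
  d <- dim(g)
  y <- array(0, dim = c(d[1L], d[2L], ch, d[4L]))
  for (c in seq_len(ch)) y[, , c, ] <- g
  y
}

split_channel <- function(x, sizes) {
  off <- 0L
  lapply(sizes, function(sz) {
    out <- x[, , off + seq_len(sz), , drop = FALSE]
    off <<- off + sz
    out
  })
}
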