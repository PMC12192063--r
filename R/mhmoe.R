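# Multihead Mixture of convolutional Experts (MHMoE).
#
# The input channels are split into `num_heads` equal heads. Each head owns
# `num_experts` expert subnetworks (3x3 conv -> ReLU -> 3x3 conv, spatial
# shape preserved) and an independent gating network (a 1x1 convolution from
# the head's channels to `num_experts` logits) whose per-pixel softmax over
# the expert axis weights the expert outputs:
#   O_i = sum_j G_ij * E_j(X_i),  gate weights broadcast over the head's
# channels. The head outputs are re-concatenated in the original order, so
# the module preserves the input shape.

#' MHMoE configuration
#'
#' @param channels total channel count C (must be divisible by `num_heads`).
#' @param num_heads number of heads (default 4).
#' @param num_experts experts per head, `k` (default 4).
#' @param share_experts if `TRUE` all heads share one expert bank; by default
#'   every head has independent experts.
#' @return an `mhmoe_config` list.
#' @export
mhmoe_config <- function(channels, num_heads = 4L, num_experts = 4L,
                         share_experts = FALSE) {
  if (num_heads < 1L || num_experts < 1L) stop("num_heads and num_experts must be >= 1")
  if (channels %% num_heads != 0L)
    stop("channels (", channels, ") not divisible by num_heads (", num_heads, ")")
  structure(list(channels = as.integer(channels), num_heads = as.integer(num_heads),
                 num_experts = as.integer(num_experts),
                 share_experts = isTRUE(share_experts)),
            class = "mhmoe_config")
}

expert_init <- function(ch) list(c1 = conv_init(ch, ch), c2 = conv_init(ch, ch))

#' Run one expert subnetwork
#'
#' 3x3 convolution, ReLU, 3x3 convolution; spatial shape and channel count
#' preserved (padding 1, stride 1).
#'
#' @param p expert parameters from the MHMoE parameter tree.
#' @param x feature map `(H, W, ch, N)` with the head's channel count.
#' @return `list(y, cache)`.
#' @export
expert_fw <- function(p, x) {
  a <- conv2d_fw(x, p$c1$w, p$c1$b)
  r <- relu_fw(a$y)
  b <- conv2d_fw(r$y, p$c2$w, p$c2$b)
  list(y = b$y, cache = list(a = a$cache, r = r$cache, b = b$cache))
}

expert_bw <- function(p, cache, dy) {
  g2 <- conv2d_bw(cache$b, dy)
  dr <- relu_bw(cache$r, g2$dx)
  g1 <- conv2d_bw(cache$a, dr)
  list(dx = g1$dx, grads = list(c1 = list(w = g1$dw, b = g1$db),
                                c2 = list(w = g2$dw, b = g2$db)))
}

#' Gate forward: per-pixel softmax expert weights
#'
#' @param p gate parameters (a 1x1 convolution).
#' @param x head features `(H, W, ch, N)`.
#' @return `list(y, cache)` where `y` is `(H, W, k, N)` with nonnegative
#'   entries summing to 1 over the expert axis at every pixel.
#' @export
gate_fw <- function(p, x) {
  a <- conv2d_fw(x, p$w, p$b, pad = 0L)
  s <- softmax_channel_fw(a$y)
  list(y = s$y, cache = list(a = a$cache, s = s$cache))
}

gate_bw <- function(p, cache, dy) {
  ds <- softmax_channel_bw(cache$s, dy)
  g <- conv2d_bw(cache$a, ds)
  list(dx = g$dx, grads = list(w = g$dw, b = g$db))
}

#' Initialize MHMoE parameters
#'
#' @param config an [mhmoe_config()].
#' @return parameter tree with per-head gates and experts.
#' @export
mhmoe_init <- function(config) {
  ch <- config$channels %/% config$num_heads
  k <- config$num_experts
  heads <- lapply(seq_len(config$num_heads), function(i) {
    h <- list(gate = conv_init(ch, k, k = 1L))
    if (!config$share_experts)
      h$experts <- lapply(seq_len(k), function(j) expert_init(ch))
    h
  })
  p <- list(heads = heads)
  if (config$share_experts)
    p$experts <- lapply(seq_len(k), function(j) expert_init(ch))
  p
}

#' MHMoE forward pass
#'
#' @param p parameters from [mhmoe_init()].
#' @param x feature map `(H, W, C, N)`.
#' @param config the [mhmoe_config()] used at init.
#' @return `list(y, cache)`; `y` has the same shape as `x`.
#' @export
mhmoe_fw <- function(p, x, config) {
  nh <- config$num_heads
  k <- config$num_experts
  ch <- config$channels %/% nh
  if (dim(x)[3L] != config$channels) stop("channel count mismatch")
  d <- dim(x)
  y <- array(0, dim = d)
  caches <- vector("list", nh)
  for (i in seq_len(nh)) {
    idx <- (i - 1L) * ch + seq_len(ch)
    xi <- x[, , idx, , drop = FALSE]
    g <- gate_fw(p$heads[[i]]$gate, xi)
    ebank <- if (config$share_experts) p$experts else p$heads[[i]]$experts
    ecaches <- vector("list", k)
    eouts <- vector("list", k)
    oi <- array(0, dim = dim(xi))
    for (j in seq_len(k)) {
      e <- expert_fw(ebank[[j]], xi)
      ecaches[[j]] <- e$cache
      eouts[[j]] <- e$y
      oi <- oi + e$y * bcast_channel(g$y[, , j, , drop = FALSE], ch)
    }
    y[, , idx, ] <- oi
    caches[[i]] <- list(gate = g$cache, gatew = g$y, experts = ecaches,
                        eouts = eouts, xi = xi)
  }
  list(y = y, cache = caches)
}

#' MHMoE backward pass
#'
#' @param p parameters.
#' @param cache forward cache.
#' @param dy upstream gradient, same shape as the forward output.
#' @param config the [mhmoe_config()].
#' @return `list(dx, grads)`.
#' @export
mhmoe_bw <- function(p, cache, dy, config) {
  nh <- config$num_heads
  k <- config$num_experts
  ch <- config$channels %/% nh
  d <- dim(dy)
  dx <- array(0, dim = d)
  grads <- list(heads = vector("list", nh))
  if (config$share_experts)
    grads$experts <- lapply(p$experts, param_zeros_like)
  for (i in seq_len(nh)) {
    idx <- (i - 1L) * ch + seq_len(ch)
    doi <- dy[, , idx, , drop = FALSE]
    ci <- cache[[i]]
    dgate_w <- array(0, dim = dim(ci$gatew)) # (H, W, k, N)
    dxi <- array(0, dim = dim(ci$xi))
    ebank <- if (config$share_experts) p$experts else p$heads[[i]]$experts
    eg <- vector("list", k)
    for (j in seq_len(k)) {
      dej <- doi * bcast_channel(ci$gatew[, , j, , drop = FALSE], ch)
      dgate_w[, , j, ] <- sum_channels(doi * ci$eouts[[j]])
      eb <- expert_bw(ebank[[j]], ci$experts[[j]], dej)
      dxi <- dxi + eb$dx
      eg[[j]] <- eb$grads
    }
    gb <- gate_bw(p$heads[[i]]$gate, ci$gate, dgate_w)
    dxi <- dxi + gb$dx
    dx[, , idx, ] <- dxi
    hg <- list(gate = gb$grads)
    if (config$share_experts) {
      for (j in seq_len(k)) grads$experts[[j]] <- param_add(grads$experts[[j]], eg[[j]])
    } else hg$experts <- eg
    grads$heads[[i]] <- hg
  }
  list(dx = dx, grads = grads)
}
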