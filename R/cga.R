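# Content-guided attention fusion (CGAFusion).
#
# Two same-shape feature streams fa, fb are blended through a learned
# per-channel-per-pixel weight. From x = fa + fb the module computes channel
# weights Wc (global average pooling -> 1x1 conv -> ReLU -> 1x1 conv) and
# spatial weights Ws (channel-mean and channel-max maps -> 7x7 conv), adds
# their broadcasts into coarse weights Wcoa, interleaves Wcoa with x channel
# by channel, refines with a 7x7 group convolution (one group per channel)
# and a sigmoid into Wfinal in (0,1), and returns
#   Wfinal * fa + (1 - Wfinal) * fb,
# a per-element convex combination of the two streams.

#' Initialize CGAFusion parameters
#'
#' @param channels channel count of each input stream.
#' @param reduction bottleneck reduction ratio of the channel-attention MLP.
#' @return parameter tree.
#' @export
cga_init <- function(channels, reduction = 4L) {
  cr <- max(1L, channels %/% reduction)
  list(wc1 = conv_init(channels, cr, k = 1L),
       wc2 = conv_init(cr, channels, k = 1L),
       ws = conv_init(2L, 1L, k = 7L),
       refine = list(w = he_init(7L, 7L, 2L, channels), b = numeric(channels)))
}

#' Channel attention weights
#'
#' Global average pooling over space, then two 1x1 convolutions with a ReLU
#' in between.
#'
#' @param p CGAFusion parameters.
#' @param x feature map `(H, W, C, N)`.
#' @return `list(y, cache)`; `y` has shape `(1, 1, C, N)`.
#' @export
channel_weights_fw <- function(p, x) {
  d <- fm_dims(x)
  x2 <- x
  dim(x2) <- c(d$H * d$W, d$C * d$N)
  g <- array(colMeans(x2), dim = c(1L, 1L, d$C, d$N))
  a <- conv2d_fw(g, p$wc1$w, p$wc1$b, pad = 0L)
  r <- relu_fw(a$y)
  b <- conv2d_fw(r$y, p$wc2$w, p$wc2$b, pad = 0L)
  list(y = b$y, cache = list(d = d, a = a$cache, r = r$cache, b = b$cache))
}

channel_weights_bw <- function(p, cache, dy) {
  g2 <- conv2d_bw(cache$b, dy)
  dr <- relu_bw(cache$r, g2$dx)
  g1 <- conv2d_bw(cache$a, dr)
  d <- cache$d
  dx <- bcast_spatial(g1$dx, d$H, d$W) / (d$H * d$W)
  list(dx = dx,
       grads = list(wc1 = list(w = g1$dw, b = g1$db),
                    wc2 = list(w = g2$dw, b = g2$db)))
}

#' Spatial attention weights
#'
#' Channel-mean and channel-max maps concatenated and passed through a 7x7
#' convolution (padding 3).
#'
#' @param p CGAFusion parameters.
#' @param x feature map `(H, W, C, N)`.
#' @return `list(y, cache)`; `y` has shape `(H, W, 1, N)`.
#' @export
spatial_weights_fw <- function(p, x) {
  d <- fm_dims(x)
  mm <- array(0, dim = c(d$H, d$W, 2L, d$N))
  mm[, , 1L, ] <- sum_channels(x) / d$C
  mm[, , 2L, ] <- max_channels(x)
  amax <- argmax_channels(x)
  a <- conv2d_fw(mm, p$ws$w, p$ws$b, pad = 3L)
  list(y = a$y, cache = list(d = d, a = a$cache, amax = amax))
}

spatial_weights_bw <- function(p, cache, dy) {
  g <- conv2d_bw(cache$a, dy)
  d <- cache$d
  dmean <- g$dx[, , 1L, , drop = FALSE]
  dmax <- g$dx[, , 2L, , drop = FALSE]
  dx <- bcast_channel(dmean, d$C) / d$C
  # scatter the max-map gradient onto the argmax channel at each pixel
  for (c in seq_len(d$C)) {
    dx[, , c, ] <- dx[, , c, , drop = FALSE] + dmax * (cache$amax == c)
  }
  list(dx = dx, grads = list(ws = list(w = g$dw, b = g$db)))
}

#' Interleave the channels of two feature maps
#'
#' Channel blending used before the refinement convolution: output channels
#' are ordered `a1, b1, a2, b2, ...`. [deinterleave_channels()] is its exact
#' inverse.
#'
#' @param a,b feature maps with identical shape `(H, W, C, N)`.
#' @return feature map `(H, W, 2C, N)`.
#' @export
interleave_channels <- function(a, b) {
  d <- dim(a)
  y <- array(0, dim = c(d[1L], d[2L], 2L * d[3L], d[4L]))
  y[, , seq(1L, 2L * d[3L], by = 2L), ] <- a
  y[, , seq(2L, 2L * d[3L], by = 2L), ] <- b
  y
}

#' @rdname interleave_channels
#' @param x an interleaved feature map with an even channel count.
#' @return `list(a, b)` recovering the two original maps.
#' @export
deinterleave_channels <- function(x) {
  C2 <- dim(x)[3L]
  list(a = x[, , seq(1L, C2, by = 2L), , drop = FALSE],
       b = x[, , seq(2L, C2, by = 2L), , drop = FALSE])
}

#' CGAFusion forward
#'
#' @param p parameters from [cga_init()].
#' @param fa,fb feature maps of identical shape.
#' @return `list(y, wfinal, cache)`; `y` is the fused map, elementwise inside
#'   the interval spanned by `fa` and `fb`.
#' @export
cga_fuse_fw <- function(p, fa, fb) {
  if (!identical(dim(fa), dim(fb))) stop("fa and fb shapes differ")
  d <- fm_dims(fa)
  x <- fa + fb
  cw <- channel_weights_fw(p, x)
  sw <- spatial_weights_fw(p, x)
  wcoa <- bcast_spatial(cw$y, d$H, d$W) + bcast_channel(sw$y, d$C)
  mix <- interleave_channels(wcoa, x)
  rf <- conv2d_fw(mix, p$refine$w, p$refine$b, pad = 3L, groups = d$C)
  sg <- sigmoid_fw(rf$y)
  wf <- sg$y
  y <- wf * fa + (1 - wf) * fb
  list(y = y, wfinal = wf,
       cache = list(d = d, cw = cw$cache, sw = sw$cache, rf = rf$cache,
                    sg = sg$cache, wf = wf, fa = fa, fb = fb))
}

#' CGAFusion backward
#'
#' @param p parameters.
#' @param cache cache from [cga_fuse_fw()].
#' @param dy upstream gradient.
#' @return `list(dfa, dfb, grads)`.
#' @export
cga_fuse_bw <- function(p, cache, dy) {
  wf <- cache$wf
  dfa <- dy * wf
  dfb <- dy * (1 - wf)
  dwf <- dy * (cache$fa - cache$fb)
  drf <- sigmoid_bw(cache$sg, dwf)
  gg <- conv2d_bw(cache$rf, drf)
  de <- deinterleave_channels(gg$dx)
  dwcoa <- de$a
  dx <- de$b
  dw2 <- dwcoa
  dim(dw2) <- c(cache$d$H * cache$d$W, cache$d$C * cache$d$N)
  dwc <- array(colSums(dw2), dim = c(1L, 1L, cache$d$C, cache$d$N))
  dws <- sum_channels(dwcoa)
  cb <- channel_weights_bw(p, cache$cw, dwc)
  sb <- spatial_weights_bw(p, cache$sw, dws)
  dx <- dx + cb$dx + sb$dx
  list(dfa = dfa + dx, dfb = dfb + dx,
       grads = c(cb$grads, sb$grads,
                 list(refine = list(w = gg$dw, b = gg$db))))
}
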