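# U-Net encoder-decoder backbone.
#
# `depth` downsampling levels (2x2 max pool) and the mirrored upsampling
# path with skip connections. Every level is a double-conv block
# (3x3 conv -> BN -> ReLU, twice); upsampling is nearest-neighbour followed
# by a 3x3 convolution that halves the channel count. Input H and W must be
# divisible by 2^depth.

unet_init <- function(cin, base = 32L, depth = 4L, num_classes = 4L) {
  enc <- list()
  c_in <- cin
  for (l in seq_len(depth)) {
    c_out <- base * 2L^(l - 1L)
    enc[[l]] <- double_conv_init(c_in, c_out)
    c_in <- c_out
  }
  bott <- double_conv_init(c_in, base * 2L^depth)
  dec <- list()
  for (l in rev(seq_len(depth))) {
    c_hi <- base * 2L^l
    c_lo <- base * 2L^(l - 1L)
    dec[[length(dec) + 1L]] <- list(up = conv_init(c_hi, c_lo),
                                    dc = double_conv_init(2L * c_lo, c_lo))
  }
  list(enc = enc, bott = bott, dec = dec,
       head = conv_init(base, num_classes, k = 1L))
}

unet_fw <- function(p, x) {
  depth <- length(p$enc)
  d <- dim(x)
  if (d[1L] %% 2L^depth != 0L || d[2L] %% 2L^depth != 0L)
    stop("H and W must be divisible by ", 2L^depth)
  skips <- list()
  ecache <- list()
  pcache <- list()
  h <- x
  for (l in seq_len(depth)) {
    e <- double_conv_fw(p$enc[[l]], h)
    ecache[[l]] <- e$cache
    skips[[l]] <- e$y
    mp <- maxpool2_fw(e$y)
    pcache[[l]] <- mp$cache
    h <- mp$y
  }
  bt <- double_conv_fw(p$bott, h)
  h <- bt$y
  dcache <- list()
  for (i in seq_len(depth)) {
    l <- depth - i + 1L
    up <- upsample2_fw(h)
    uc <- conv2d_fw(up$y, p$dec[[i]]$up$w, p$dec[[i]]$up$b)
    merged <- cat_channel(skips[[l]], uc$y)
    dc <- double_conv_fw(p$dec[[i]]$dc, merged)
    dcache[[i]] <- list(uc = uc$cache, dc = dc$cache,
                        skip_ch = dim(skips[[l]])[3L])
    h <- dc$y
  }
  hd <- conv2d_fw(h, p$head$w, p$head$b, pad = 0L)
  list(y = hd$y,
       cache = list(ecache = ecache, pcache = pcache, bt = bt$cache,
                    dcache = dcache, hd = hd$cache, depth = depth))
}

unet_bw <- function(p, cache, dy) {
  depth <- cache$depth
  hb <- conv2d_bw(cache$hd, dy)
  grads <- list(enc = vector("list", depth), dec = vector("list", depth),
                head = list(w = hb$dw, b = hb$db))
  dh <- hb$dx
  dskips <- vector("list", depth)
  for (i in rev(seq_len(depth))) {
    l <- depth - i + 1L
    dc <- double_conv_bw(p$dec[[i]]$dc, cache$dcache[[i]]$dc, dh)
    sc <- cache$dcache[[i]]$skip_ch
    parts <- split_channel(dc$dx, c(sc, dim(dc$dx)[3L] - sc))
    dskips[[l]] <- parts[[1L]]
    ub <- conv2d_bw(cache$dcache[[i]]$uc, parts[[2L]])
    dh <- upsample2_bw(NULL, ub$dx)
    grads$dec[[i]] <- list(up = list(w = ub$dw, b = ub$db), dc = dc$grads)
  }
  db <- double_conv_bw(p$bott, cache$bt, dh)
  grads$bott <- db$grads
  dh <- db$dx
  for (l in rev(seq_len(depth))) {
    dpool <- maxpool2_bw(cache$pcache[[l]], dh)
    denc_out <- dpool + dskips[[l]]
    eb <- double_conv_bw(p$enc[[l]], cache$ecache[[l]], denc_out)
    grads$enc[[l]] <- eb$grads
    dh <- eb$dx
  }
  list(dx = dh, grads = grads[c("enc", "bott", "dec", "head")])
}
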