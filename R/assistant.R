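# Peripheral-vision assistant network.
#
# The assistant takes the same single-modality input as the student. Its
# peripheral block mimics saccadic vision: the feature map is partitioned
# into four non-overlapping quadrants; each quadrant passes through (a)
# standard multihead self-attention over its pixels (global content,
# "peripheral" pathway) and (b) a mask-modulated MPA convolution whose
# effective kernel K * M emphasizes the kernel center ("foveal" pathway).
# The L2-normalized MPA map multiplies the attention output; a region
# interaction step (channel concat -> 3x3 conv/ReLU -> channel partition ->
# spatial reassembly -> 3x3 conv/sigmoid) lets the quadrants exchange
# information before each is renormalized with a channel softmax. The block
# sits at the bottleneck of a compact 3-level encoder-decoder that returns
# full-resolution 4-class logits.

#' Partition a feature map into four quadrants
#'
#' @param x feature map `(H, W, C, N)` with even H and W.
#' @return list with `FA` (top-left), `FB` (top-right), `FC` (bottom-left),
#'   `FD` (bottom-right), each `(H/2, W/2, C, N)`.
#' @export
partition_quadrants <- function(x) {
  d <- dim(x)
  if (d[1L] %% 2L || d[2L] %% 2L) stop("H and W must be even to partition quadrants")
  h2 <- d[1L] %/% 2L; w2 <- d[2L] %/% 2L
  list(FA = x[1:h2, 1:w2, , , drop = FALSE],
       FB = x[1:h2, (w2 + 1L):d[2L], , , drop = FALSE],
       FC = x[(h2 + 1L):d[1L], 1:w2, , , drop = FALSE],
       FD = x[(h2 + 1L):d[1L], (w2 + 1L):d[2L], , , drop = FALSE])
}

#' Reassemble four quadrants into one feature map
#'
#' Exact inverse of [partition_quadrants()].
#'
#' @param q list with `FA`, `FB`, `FC`, `FD`.
#' @return feature map `(H, W, C, N)`.
#' @export
reassemble_quadrants <- function(q) {
  d <- dim(q$FA)
  x <- array(0, dim = c(2L * d[1L], 2L * d[2L], d[3L], d[4L]))
  x[1:d[1L], 1:d[2L], , ] <- q$FA
  x[1:d[1L], (d[2L] + 1L):(2L * d[2L]), , ] <- q$FB
  x[(d[1L] + 1L):(2L * d[1L]), 1:d[2L], , ] <- q$FC
  x[(d[1L] + 1L):(2L * d[1L]), (d[2L] + 1L):(2L * d[2L]), , ] <- q$FD
  x
}

# ---- multihead self-attention over pixels ----------------------------------

mha_init <- function(channels, num_heads = 2L) {
  if (channels %% num_heads != 0L)
    stop("channels (", channels, ") not divisible by attention heads (", num_heads, ")")
  s <- sqrt(1 / channels)
  m <- function() matrix(rnorm(channels * channels, sd = s), channels, channels)
  list(wq = m(), wk = m(), wv = m(), wout = m(), bout = numeric(channels))
}

#' Multihead self-attention over a region's pixels
#'
#' Each pixel is one token with the channels as its embedding. Scaled
#' dot-product attention per head (`tau = 1/sqrt(head_dim)`), heads
#' concatenated and linearly projected with bias.
#'
#' @param p parameters from `mha_init`.
#' @param x region feature map `(H, W, C, N)`.
#' @param num_heads number of attention heads.
#' @return `list(y, cache)`; `y` has the shape of `x`.
#' @export
mha_fw <- function(p, x, num_heads = 2L) {
  d <- fm_dims(x)
  C <- d$C; T <- d$H * d$W
  dh <- C %/% num_heads
  tau <- 1 / sqrt(dh)
  y <- array(0, dim = dim(x))
  caches <- vector("list", d$N)
  for (n in seq_len(d$N)) {
    X <- matrix(x[, , , n], T, C)
    Q <- X %*% p$wq; K <- X %*% p$wk; V <- X %*% p$wv
    heads <- vector("list", num_heads)
    O <- matrix(0, T, C)
    for (h in seq_len(num_heads)) {
      j <- (h - 1L) * dh + seq_len(dh)
      S <- tau * Q[, j, drop = FALSE] %*% t(K[, j, drop = FALSE])
      S <- S - apply(S, 1L, max)
      E <- exp(S)
      A <- E / rowSums(E)
      O[, j] <- A %*% V[, j, drop = FALSE]
      heads[[h]] <- A
    }
    Yn <- O %*% p$wout + matrix(p$bout, T, C, byrow = TRUE)
    y[, , , n] <- array(Yn, dim = c(d$H, d$W, C))
    caches[[n]] <- list(X = X, Q = Q, K = K, V = V, A = heads, O = O)
  }
  list(y = y, cache = list(per = caches, d = d, num_heads = num_heads,
                           tau = tau, dh = dh))
}

mha_bw <- function(p, cache, dy) {
  d <- cache$d; C <- d$C; T <- d$H * d$W
  nh <- cache$num_heads; dh <- cache$dh; tau <- cache$tau
  dx <- array(0, dim = c(d$H, d$W, C, d$N))
  g <- list(wq = matrix(0, C, C), wk = matrix(0, C, C), wv = matrix(0, C, C),
            wout = matrix(0, C, C), bout = numeric(C))
  for (n in seq_len(d$N)) {
    cn <- cache$per[[n]]
    dYn <- matrix(dy[, , , n], T, C)
    g$wout <- g$wout + t(cn$O) %*% dYn
    g$bout <- g$bout + colSums(dYn)
    dO <- dYn %*% t(p$wout)
    dQ <- matrix(0, T, C); dK <- matrix(0, T, C); dV <- matrix(0, T, C)
    for (h in seq_len(nh)) {
      j <- (h - 1L) * dh + seq_len(dh)
      A <- cn$A[[h]]
      dOh <- dO[, j, drop = FALSE]
      dV[, j] <- t(A) %*% dOh
      dA <- dOh %*% t(cn$V[, j, drop = FALSE])
      dS <- A * (dA - rowSums(dA * A))
      dQ[, j] <- tau * dS %*% cn$K[, j, drop = FALSE]
      dK[, j] <- tau * t(dS) %*% cn$Q[, j, drop = FALSE]
    }
    g$wq <- g$wq + t(cn$X) %*% dQ
    g$wk <- g$wk + t(cn$X) %*% dK
    g$wv <- g$wv + t(cn$X) %*% dV
    dX <- dQ %*% t(p$wq) + dK %*% t(p$wk) + dV %*% t(p$wv)
    dx[, , , n] <- array(dX, dim = c(d$H, d$W, C))
  }
  list(dx = dx, grads = g)
}

# ---- MPA: mask-modulated convolution ----------------------------------------

#' Initialize an MPA convolution
#'
#' 3x3 convolution whose effective kernel is `K * M` with, per output channel
#' n, `M_n = 1 - theta * s_n * (Mlearn * Cmask)` where `s_n` is the sum of
#' filter n's weights, `Mlearn` is initialized from U(-1, 1) and `Cmask` has
#' center 1 and 0.5 elsewhere. With `theta = 0` the layer is a plain
#' convolution with `K`. No bias, so zero input maps to zero output.
#'
#' @param channels input (= output) channel count.
#' @return parameter list with `w`, `mlearn`, `theta`.
#' @export
mpa_init <- function(channels) {
  list(w = he_init(3L, 3L, channels, channels),
       mlearn = matrix(runif(9L, -1, 1), 3L, 3L),
       theta = 0.1)
}

mpa_cmask <- function() {
  m <- matrix(0.5, 3L, 3L)
  m[2L, 2L] <- 1
  m
}

#' MPA forward pass
#'
#' @param p parameters from [mpa_init()].
#' @param x feature map `(H, W, C, N)`.
#' @return `list(y, keff, cache)`.
#' @export
mpa_fw <- function(p, x) {
  wd <- dim(p$w)
  cout <- wd[4L]
  cm <- mpa_cmask()
  s <- apply(p$w, 4L, sum)                       # per-filter weight sum
  mod <- p$mlearn * cm                           # 3x3
  keff <- p$w
  for (n in seq_len(cout)) {
    M <- 1 - p$theta * s[n] * mod
    keff[, , , n] <- p$w[, , , n] * array(M, dim = wd[1:3])
  }
  cv <- conv2d_fw(x, keff, NULL)
  list(y = cv$y, keff = keff,
       cache = list(conv = cv$cache, s = s, mod = mod, cm = cm, w = p$w,
                    theta = p$theta))
}

mpa_bw <- function(p, cache, dy) {
  g <- conv2d_bw(cache$conv, dy)
  dkeff <- g$dw
  wd <- dim(p$w)
  cout <- wd[4L]
  dw <- array(0, dim = wd)
  dmlearn <- matrix(0, 3L, 3L)
  dtheta <- 0
  for (n in seq_len(cout)) {
    M <- 1 - p$theta * cache$s[n] * cache$mod
    Mb <- array(M, dim = wd[1:3])
    dw[, , , n] <- dkeff[, , , n] * Mb
    dM <- apply(dkeff[, , , n, drop = FALSE] * p$w[, , , n, drop = FALSE],
                c(1L, 2L), sum)
    ds <- -p$theta * sum(dM * cache$mod)
    dw[, , , n] <- dw[, , , n] + ds           # s_n = sum of filter n weights
    dtheta <- dtheta - cache$s[n] * sum(dM * cache$mod)
    dmlearn <- dmlearn - p$theta * cache$s[n] * dM * cache$cm
  }
  list(dx = g$dx, grads = list(w = dw, mlearn = dmlearn, theta = dtheta))
}

# ---- L2 channel normalization ----------------------------------------------

l2norm_channel_fw <- function(x, eps = 1e-8) {
  d <- dim(x)
  rb <- bcast_channel(sqrt(sum_channels(x * x) + eps), d[3L])
  list(y = x / rb, cache = list(x = x, rb = rb))
}

l2norm_channel_bw <- function(cache, dy) {
  x <- cache$x; rb <- cache$rb
  d <- dim(x)
  ib <- bcast_channel(sum_channels(dy * x), d[3L])
  dy / rb - x * ib / rb^3
}

# ---- region interaction -----------------------------------------------------

region_interaction_init <- function(channels) {
  list(c1 = conv_init(4L * channels, 4L * channels),
       c2 = conv_init(channels, channels))
}

#' Region interaction across the four quadrants
#'
#' Channel-concatenates the quadrants, applies a 3x3 convolution with ReLU,
#' partitions the channels back into four groups, reassembles them spatially,
#' applies a 3x3 convolution with sigmoid to get the interaction map `Fa`,
#' and updates every region as `softmax_channel(F + F * Fa_region)`.
#'
#' @param p parameters from `region_interaction_init`.
#' @param q quadrant list (`FA`..`FD`).
#' @return `list(q, cache)` with the four updated quadrants.
#' @export
region_interaction_fw <- function(p, q) {
  dq <- dim(q$FA)
  C <- dq[3L]
  for (nm in c("FB", "FC", "FD"))
    if (!identical(dim(q[[nm]]), dq)) stop("quadrant shapes disagree")
  catc <- cat_channel(q$FA, q$FB, q$FC, q$FD)
  a <- conv2d_fw(catc, p$c1$w, p$c1$b)
  r <- relu_fw(a$y)
  parts <- split_channel(r$y, rep(C, 4L))
  fa_full <- reassemble_quadrants(list(FA = parts[[1L]], FB = parts[[2L]],
                                       FC = parts[[3L]], FD = parts[[4L]]))
  b <- conv2d_fw(fa_full, p$c2$w, p$c2$b)
  sg <- sigmoid_fw(b$y)
  fa_q <- partition_quadrants(sg$y)
  out <- list(); sm <- list()
  for (nm in c("FA", "FB", "FC", "FD")) {
    pre <- q[[nm]] + q[[nm]] * fa_q[[nm]]
    s <- softmax_channel_fw(pre)
    out[[nm]] <- s$y
    sm[[nm]] <- s$cache
  }
  list(q = out,
       cache = list(a = a$cache, r = r$cache, b = b$cache, sg = sg$cache,
                    fa_q = fa_q, q_in = q, sm = sm, C = C))
}

region_interaction_bw <- function(p, cache, dq_out) {
  C <- cache$C
  dq <- list()
  dfa_q <- list()
  for (nm in c("FA", "FB", "FC", "FD")) {
    dpre <- softmax_channel_bw(cache$sm[[nm]], dq_out[[nm]])
    dq[[nm]] <- dpre * (1 + cache$fa_q[[nm]])
    dfa_q[[nm]] <- dpre * cache$q_in[[nm]]
  }
  dfa_full <- reassemble_quadrants(dfa_q)
  dsg <- sigmoid_bw(cache$sg, dfa_full)
  g2 <- conv2d_bw(cache$b, dsg)
  dparts <- partition_quadrants(g2$dx)
  dr <- cat_channel(dparts$FA, dparts$FB, dparts$FC, dparts$FD)
  da <- relu_bw(cache$r, dr)
  g1 <- conv2d_bw(cache$a, da)
  dcat <- split_channel(g1$dx, rep(C, 4L))
  for (i in seq_along(c("FA", "FB", "FC", "FD"))) {
    nm <- c("FA", "FB", "FC", "FD")[i]
    dq[[nm]] <- dq[[nm]] + dcat[[i]]
  }
  list(dq = dq,
       grads = list(c1 = list(w = g1$dw, b = g1$db),
                    c2 = list(w = g2$dw, b = g2$db)))
}

# ---- peripheral block -------------------------------------------------------

peripheral_init <- function(channels, num_heads = 2L) {
  list(mha = mha_init(channels, num_heads),
       mpa = mpa_init(channels),
       inter = region_interaction_init(channels))
}

peripheral_fw <- function(p, x, num_heads = 2L) {
  q <- partition_quadrants(x)
  comb <- list(); caches <- list()
  for (nm in c("FA", "FB", "FC", "FD")) {
    att <- mha_fw(p$mha, q[[nm]], num_heads)
    mp <- mpa_fw(p$mpa, q[[nm]])
    nrm <- l2norm_channel_fw(mp$y)
    comb[[nm]] <- nrm$y * att$y
    caches[[nm]] <- list(att = att$cache, mp = mp$cache, nrm = nrm$cache,
                         att_y = att$y, nrm_y = nrm$y)
  }
  ri <- region_interaction_fw(p$inter, comb)
  y <- reassemble_quadrants(ri$q)
  list(y = y, cache = list(per = caches, ri = ri$cache, num_heads = num_heads))
}

peripheral_bw <- function(p, cache, dy) {
  dq_out <- partition_quadrants(dy)
  rb <- region_interaction_bw(p$inter, cache$ri, dq_out)
  gm <- NULL; gp <- NULL
  dx_q <- list()
  for (nm in c("FA", "FB", "FC", "FD")) {
    cn <- cache$per[[nm]]
    dcomb <- rb$dq[[nm]]
    datt <- dcomb * cn$nrm_y
    dnrm <- dcomb * cn$att_y
    dmpa_y <- l2norm_channel_bw(cn$nrm, dnrm)
    ab <- mha_bw(p$mha, cn$att, datt)
    mb <- mpa_bw(p$mpa, cn$mp, dmpa_y)
    gm <- if (is.null(gm)) ab$grads else param_add(gm, ab$grads)
    gp <- if (is.null(gp)) mb$grads else param_add(gp, mb$grads)
    dx_q[[nm]] <- ab$dx + mb$dx
  }
  list(dx = reassemble_quadrants(dx_q),
       grads = list(mha = gm, mpa = gp, inter = rb$grads))
}

# ---- compact encoder-decoder (assistant and student backbones) --------------

stem_init <- function(cin, cout) list(c = conv_init(cin, cout), n = bn_init(cout))

stem_fw <- function(p, x) {
  a <- conv2d_fw(x, p$c$w, p$c$b)
  b <- batchnorm_fw(a$y, p$n$gamma, p$n$beta)
  r <- relu_fw(b$y)
  mp <- maxpool2_fw(r$y)
  list(y = mp$y, cache = list(a = a$cache, b = b$cache, r = r$cache, mp = mp$cache))
}

stem_bw <- function(p, cache, dy) {
  dr <- maxpool2_bw(cache$mp, dy)
  dr <- relu_bw(cache$r, dr)
  gb <- batchnorm_bw(cache$b, dr)
  ga <- conv2d_bw(cache$a, gb$dx)
  list(dx = ga$dx, grads = list(c = list(w = ga$dw, b = ga$db),
                                n = list(gamma = gb$dgamma, beta = gb$dbeta)))
}

up_init <- function(cin, cout) list(c = conv_init(cin, cout), n = bn_init(cout))

up_fw <- function(p, x) {
  u <- upsample2_fw(x)
  a <- conv2d_fw(u$y, p$c$w, p$c$b)
  b <- batchnorm_fw(a$y, p$n$gamma, p$n$beta)
  r <- relu_fw(b$y)
  list(y = r$y, cache = list(a = a$cache, b = b$cache, r = r$cache))
}

up_bw <- function(p, cache, dy) {
  dr <- relu_bw(cache$r, dy)
  gb <- batchnorm_bw(cache$b, dr)
  ga <- conv2d_bw(cache$a, gb$dx)
  list(dx = upsample2_bw(NULL, ga$dx),
       grads = list(c = list(w = ga$dw, b = ga$db),
                    n = list(gamma = gb$dgamma, beta = gb$dbeta)))
}

#' Initialize the assistant network
#'
#' Single-modality input; two downsampling stems, the peripheral-vision block
#' plus a double-conv body at 1/4 resolution, two upsampling stages back to
#' full resolution and a 1x1 classification head.
#'
#' @param channels base channel width.
#' @param num_heads attention heads in the peripheral block.
#' @param peripheral include the peripheral block (ablation toggle).
#' @return parameter tree with attributes `num_heads`, `peripheral`.
#' @export
assistant_init <- function(channels = 8L, num_heads = 2L, peripheral = TRUE) {
  p <- list(stem1 = stem_init(1L, channels),
            stem2 = stem_init(channels, channels),
            body = double_conv_init(channels, channels),
            up1 = up_init(channels, channels),
            up2 = up_init(channels, channels),
            head = conv_init(channels, 4L, k = 1L))
  if (peripheral) p$per <- peripheral_init(channels, num_heads)
  attr(p, "num_heads") <- num_heads
  attr(p, "peripheral") <- peripheral
  p
}

#' Assistant forward pass
#'
#' @param p parameters from [assistant_init()].
#' @param x single-modality input: matrix `(H, W)` or feature map
#'   `(H, W, 1, N)` with H, W divisible by 8.
#' @return `list(logits, probs, cache)`; logits are `(H, W, 4, N)`.
#' @export
assistant_fw <- function(p, x) {
  x <- as_feature_map(x)
  if (dim(x)[3L] != 1L) stop("assistant takes a single modality (1 channel)")
  s1 <- stem_fw(p$stem1, x)
  s2 <- stem_fw(p$stem2, s1$y)
  h <- s2$y
  pc <- NULL
  if (isTRUE(attr(p, "peripheral"))) {
    pf <- peripheral_fw(p$per, h, attr(p, "num_heads"))
    h <- pf$y
    pc <- pf$cache
  }
  bd <- double_conv_fw(p$body, h)
  u1 <- up_fw(p$up1, bd$y)
  u2 <- up_fw(p$up2, u1$y)
  hd <- conv2d_fw(u2$y, p$head$w, p$head$b, pad = 0L)
  list(logits = hd$y, probs = softmax_channel(hd$y),
       cache = list(s1 = s1$cache, s2 = s2$cache, pc = pc, bd = bd$cache,
                    u1 = u1$cache, u2 = u2$cache, hd = hd$cache))
}

#' Assistant backward pass
#'
#' @param p parameters.
#' @param cache cache from [assistant_fw()].
#' @param dlogits upstream gradient on the logits.
#' @return `list(dx, grads)`.
#' @export
assistant_bw <- function(p, cache, dlogits) {
  hb <- conv2d_bw(cache$hd, dlogits)
  grads <- list(head = list(w = hb$dw, b = hb$db))
  b2 <- up_bw(p$up2, cache$u2, hb$dx)
  grads$up2 <- b2$grads
  b1 <- up_bw(p$up1, cache$u1, b2$dx)
  grads$up1 <- b1$grads
  bd <- double_conv_bw(p$body, cache$bd, b1$dx)
  grads$body <- bd$grads
  dh <- bd$dx
  if (!is.null(cache$pc)) {
    pb <- peripheral_bw(p$per, cache$pc, dh)
    grads$per <- pb$grads
    dh <- pb$dx
  }
  sb2 <- stem_bw(p$stem2, cache$s2, dh)
  grads$stem2 <- sb2$grads
  sb1 <- stem_bw(p$stem1, cache$s1, sb2$dx)
  grads$stem1 <- sb1$grads
  # reorder grads to match the parameter tree order
  ord <- names(p)
  list(dx = sb1$dx, grads = grads[ord])
}

#' Initialize the student network
#'
#' The same compact encoder-decoder as the assistant but without the
#' peripheral block.
#'
#' @param channels base channel width.
#' @return parameter tree.
#' @export
student_init <- function(channels = 8L) {
  assistant_init(channels, peripheral = FALSE)
}

#' @rdname assistant_fw
#' @export
student_fw <- function(p, x) assistant_fw(p, x)

#' @rdname assistant_bw
#' @export
student_bw <- function(p, cache, dlogits) assistant_bw(p, cache, dlogits)
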