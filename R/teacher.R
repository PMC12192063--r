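# Full-modality teacher network.
#
# The four modalities enter as two complementary pairs - T1 with T1ce (tumor
# core) and T2 with FLAIR (edema). Each pair is channel-concatenated, lifted
# to the working width by one 3x3 convolution, fused by content-guided
# attention, enhanced by the multihead mixture of experts, and segmented by a
# U-Net. Training minimizes cross-entropy + soft Dice; after pretraining the
# parameters are frozen and never updated again.

#' Initialize the teacher network
#'
#' @param channels base channel width (working width after pair lifting).
#' @param num_heads MHMoE heads (channels must be divisible by it).
#' @param num_experts experts per MHMoE head.
#' @param depth U-Net depth (downsampling levels).
#' @param use_mhmoe include the MHMoE stage (ablation toggle).
#' @return parameter tree; the MHMoE configuration and toggles ride along as
#'   attributes.
#' @export
teacher_init <- function(channels = 8L, num_heads = 4L, num_experts = 4L,
                         depth = 4L, use_mhmoe = TRUE) {
  p <- list(lift1 = conv_init(2L, channels),
            lift2 = conv_init(2L, channels),
            cga = cga_init(channels),
            unet = unet_init(channels, base = channels, depth = depth,
                             num_classes = 4L))
  if (use_mhmoe) {
    cfg <- mhmoe_config(channels, num_heads, num_experts)
    p$moe <- mhmoe_init(cfg)
    attr(p, "mhmoe_config") <- cfg
  }
  attr(p, "use_mhmoe") <- use_mhmoe
  attr(p, "depth") <- depth
  p
}

#' Stack multimodal samples into batch arrays
#'
#' @param samples list of `multimodal_sample`s with identical shapes.
#' @return list with `pair1` (T1 + T1ce, `(H, W, 2, N)`), `pair2`
#'   (T2 + FLAIR), and `labels` `(H, W, N)`.
#' @export
batch_from_samples <- function(samples) {
  if (inherits(samples, "multimodal_sample")) samples <- list(samples)
  d <- dim(samples[[1L]]$label)
  N <- length(samples)
  pair1 <- array(0, dim = c(d, 2L, N))
  pair2 <- array(0, dim = c(d, 2L, N))
  labels <- array(0L, dim = c(d, N))
  for (i in seq_len(N)) {
    s <- samples[[i]]
    for (m in c("t1", "t1ce", "t2", "flair"))
      if (is.null(s[[m]])) stop("missing modality ", m, ": the teacher requires all four")
    pair1[, , 1L, i] <- s$t1; pair1[, , 2L, i] <- s$t1ce
    pair2[, , 1L, i] <- s$t2; pair2[, , 2L, i] <- s$flair
    labels[, , i] <- s$label
  }
  list(pair1 = pair1, pair2 = pair2, labels = labels)
}

teacher_fw_core <- function(p, pair1, pair2) {
  l1 <- conv2d_fw(pair1, p$lift1$w, p$lift1$b)
  l2 <- conv2d_fw(pair2, p$lift2$w, p$lift2$b)
  fu <- cga_fuse_fw(p$cga, l1$y, l2$y)
  h <- fu$y
  mc <- NULL
  if (isTRUE(attr(p, "use_mhmoe"))) {
    mf <- mhmoe_fw(p$moe, h, attr(p, "mhmoe_config"))
    h <- mf$y
    mc <- mf$cache
  }
  un <- unet_fw(p$unet, h)
  list(logits = un$y, probs = softmax_channel(un$y),
       cache = list(l1 = l1$cache, l2 = l2$cache, fu = fu$cache, mc = mc,
                    un = un$cache))
}

teacher_bw_core <- function(p, cache, dlogits) {
  ub <- unet_bw(p$unet, cache$un, dlogits)
  dh <- ub$dx
  grads <- list(unet = ub$grads)
  if (!is.null(cache$mc)) {
    mb <- mhmoe_bw(p$moe, cache$mc, dh, attr(p, "mhmoe_config"))
    grads$moe <- mb$grads
    dh <- mb$dx
  }
  fb <- cga_fuse_bw(p$cga, cache$fu, dh)
  grads$cga <- fb$grads
  g1 <- conv2d_bw(cache$l1, fb$dfa)
  g2 <- conv2d_bw(cache$l2, fb$dfb)
  grads$lift1 <- list(w = g1$dw, b = g1$db)
  grads$lift2 <- list(w = g2$dw, b = g2$db)
  list(dpair1 = g1$dx, dpair2 = g2$dx, grads = grads[names(p)])
}

#' Teacher forward pass
#'
#' @param p parameters from [teacher_init()].
#' @param samples a `multimodal_sample` or list of them (all four modalities
#'   required; H and W divisible by `2^depth`).
#' @return list with `logits`, `probs` (`(H, W, 4, N)`) and `cache`.
#' @export
teacher_forward <- function(p, samples) {
  b <- batch_from_samples(samples)
  out <- teacher_fw_core(p, b$pair1, b$pair2)
  out$labels <- b$labels
  out
}

#' Freeze a parameter tree
#'
#' Frozen parameters are skipped by [sgd_step()] and stay bit-identical.
#'
#' @param p parameter tree.
#' @return the tree with the frozen flag set.
#' @export
freeze_params <- function(p) {
  attr(p, "frozen") <- TRUE
  p
}

#' @rdname freeze_params
#' @export
is_frozen <- function(p) isTRUE(attr(p, "frozen"))

#' Pretrain the teacher
#'
#' Minibatch SGD (momentum, weight decay, poly learning-rate decay) on the
#' cross-entropy + Dice task loss over full-modality samples. Returns the
#' frozen parameters and the per-epoch loss log.
#'
#' @param samples list of `multimodal_sample`s.
#' @param epochs training epochs.
#' @param channels base channel width.
#' @param lr,momentum,weight_decay,poly_power optimizer settings.
#' @param batch_size minibatch size (capped at the dataset size).
#' @param seed seed for init and batch shuffling.
#' @param use_mhmoe include the MHMoE stage.
#' @param depth U-Net depth.
#' @param params optional pre-initialized parameters (overrides `channels`).
#' @return list with frozen `params`, the `log` data frame and the final
#'   `opt` state.
#' @export
pretrain_teacher <- function(samples, epochs = 30L, channels = 8L,
                             lr = 0.05, momentum = 0.9, weight_decay = 1e-4,
                             poly_power = 0.9, batch_size = 8L, seed = 0L,
                             use_mhmoe = TRUE, depth = 4L, params = NULL) {
  if (length(samples) == 0L) stop("empty training set")
  with_seed(seed, {
    p <- if (is.null(params)) teacher_init(channels, use_mhmoe = use_mhmoe,
                                           depth = depth) else params
    n <- length(samples)
    bs <- min(batch_size, n)
    steps_per_epoch <- ceiling(n / bs)
    opt <- sgd_init(p, lr = lr, momentum = momentum, weight_decay = weight_decay,
                    max_iter = epochs * steps_per_epoch, poly_power = poly_power)
    log <- data.frame(epoch = integer(0), loss = numeric(0),
                      ce = numeric(0), dice = numeric(0))
    for (ep in seq_len(epochs)) {
      ord <- sample(n)
      ep_loss <- ep_ce <- ep_dice <- 0
      for (st in seq_len(steps_per_epoch)) {
        idx <- ord[((st - 1L) * bs + 1L):min(st * bs, n)]
        out <- teacher_forward(p, samples[idx])
        tl <- task_loss(out$logits, out$labels)
        dlog <- task_loss_bw(tl$cache)
        bw <- teacher_bw_core(p, out$cache, dlog)
        up <- sgd_step(p, bw$grads, opt)
        p <- up$params; opt <- up$opt
        w <- length(idx) / n
        ep_loss <- ep_loss + tl$total * w
        ep_ce <- ep_ce + tl$ce * w
        ep_dice <- ep_dice + tl$dice * w
      }
      log <- rbind(log, data.frame(epoch = ep, loss = ep_loss, ce = ep_ce,
                                   dice = ep_dice))
    }
    list(params = freeze_params(p), log = log, opt = opt)
  })
}
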