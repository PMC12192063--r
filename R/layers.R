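# Layer constructors and the parameter-tree utilities shared by all networks.
#
# A network's parameters are a nested named list whose leaves are numeric
# arrays. Gradients returned by backward passes mirror that structure, so the
# optimizer and the freeze checksum can walk both trees in lockstep.

he_init <- function(kh, kw, cin, cout) {
  array(rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
        dim = c(kh, kw, cin, cout))
}

conv_init <- function(cin, cout, k = 3L, groups = 1L, bias = TRUE) {
  p <- list(w = he_init(k, k, cin %/% groups, cout))
  if (bias) p$b <- numeric(cout)
  p
}

bn_init <- function(c) list(gamma = rep(1, c), beta = numeric(c))

# conv -> BN -> ReLU, applied twice: the double-conv block used by every
# encoder/decoder level.
double_conv_init <- function(cin, cout) {
  list(c1 = conv_init(cin, cout), n1 = bn_init(cout),
       c2 = conv_init(cout, cout), n2 = bn_init(cout))
}

double_conv_fw <- function(p, x) {
  a <- conv2d_fw(x, p$c1$w, p$c1$b)
  b <- batchnorm_fw(a$y, p$n1$gamma, p$n1$beta)
  r1 <- relu_fw(b$y)
  a2 <- conv2d_fw(r1$y, p$c2$w, p$c2$b)
  b2 <- batchnorm_fw(a2$y, p$n2$gamma, p$n2$beta)
  r2 <- relu_fw(b2$y)
  list(y = r2$y, cache = list(a = a$cache, b = b$cache, r1 = r1$cache,
                              a2 = a2$cache, b2 = b2$cache, r2 = r2$cache))
}

double_conv_bw <- function(p, cache, dy) {
  dy <- relu_bw(cache$r2, dy)
  g2 <- batchnorm_bw(cache$b2, dy)
  c2 <- conv2d_bw(cache$a2, g2$dx)
  dy <- relu_bw(cache$r1, c2$dx)
  g1 <- batchnorm_bw(cache$b, dy)
  c1 <- conv2d_bw(cache$a, g1$dx)
  list(dx = c1$dx,
       grads = list(c1 = list(w = c1$dw, b = c1$db),
                    n1 = list(gamma = g1$dgamma, beta = g1$dbeta),
                    c2 = list(w = c2$dw, b = c2$db),
                    n2 = list(gamma = g2$dgamma, beta = g2$dbeta)))
}

# ---- parameter-tree helpers -------------------------------------------------

tree_keys <- function(p) {
  nm <- names(p)
  if (is.null(nm) || any(nm == "")) seq_along(p) else nm
}

param_leaves <- function(p, prefix = "") {
  if (is.numeric(p)) return(stats::setNames(list(p), prefix))
  out <- list()
  for (k in tree_keys(p))
    out <- c(out, param_leaves(p[[k]], paste0(prefix, "/", k)))
  out
}

param_map2 <- function(f, a, b) {
  if (is.numeric(a)) return(f(a, b))
  out <- a
  for (k in tree_keys(a)) out[[k]] <- param_map2(f, a[[k]], b[[k]])
  out
}

param_zeros_like <- function(p) {
  if (is.numeric(p)) return(p * 0)
  lapply(p, param_zeros_like)
}

param_add <- function(a, b) param_map2(`+`, a, b)

#' Checksum of a parameter tree
#'
#' A cheap deterministic fingerprint (sum, sum of squares and element count of
#' every leaf) used to assert that frozen parameters stay bit-identical across
#' training.
#'
#' @param p nested list of numeric arrays.
#' @return a numeric vector fingerprint.
#' @export
param_checksum <- function(p) {
  lv <- param_leaves(p)
  unlist(lapply(lv, function(x) c(sum(x), sum(x * x), length(x))))
}

#' Create an SGD optimizer state
#'
#' Stochastic gradient descent with momentum, weight decay and polynomial
#' ("poly") learning-rate decay `lr * (1 - iter/max_iter)^power`.
#'
#' @param params parameter tree the optimizer will update.
#' @param lr initial learning rate.
#' @param momentum momentum coefficient.
#' @param weight_decay L2 penalty coefficient.
#' @param max_iter total number of updates used by the poly schedule.
#' @param poly_power exponent of the poly schedule.
#' @return an optimizer state list.
#' @export
sgd_init <- function(params, lr = 2e-4, momentum = 0.9, weight_decay = 1e-4,
                     max_iter = 1000L, poly_power = 0.9) {
  list(v = param_zeros_like(params), lr = lr, momentum = momentum,
       weight_decay = weight_decay, max_iter = max_iter,
       poly_power = poly_power, iter = 0L)
}

#' Poly learning-rate decay
#'
#' @param lr0 initial learning rate.
#' @param iter current iteration (0-based).
#' @param max_iter schedule horizon.
#' @param power polynomial exponent.
#' @return the decayed learning rate.
#' @export
poly_lr <- function(lr0, iter, max_iter, power = 0.9) {
  lr0 * (1 - min(iter, max_iter - 1) / max_iter)^power
}

#' One SGD update
#'
#' @param params parameter tree.
#' @param grads gradient tree of the same shape.
#' @param opt optimizer state from [sgd_init()].
#' @return `list(params, opt)` with updated values.
#' @export
sgd_step <- function(params, grads, opt) {
  if (isTRUE(attr(params, "frozen"))) return(list(params = params, opt = opt))
  lr <- poly_lr(opt$lr, opt$iter, opt$max_iter, opt$poly_power)
  wd <- opt$weight_decay
  mom <- opt$momentum
  step_leaf <- function(pv) {
    p <- pv[[1L]]; g <- pv[[2L]]; v <- pv[[3L]]
    v <- mom * v + g + wd * p
    list(p - lr * v, v)
  }
  walk <- function(p, g, v) {
    if (is.numeric(p)) return(step_leaf(list(p, g, v)))
    np <- p; nv <- v
    for (k in tree_keys(p)) {
      r <- walk(p[[k]], g[[k]], v[[k]])
      np[[k]] <- r[[1L]]; nv[[k]] <- r[[2L]]
    }
    list(np, nv)
  }
  r <- walk(params, grads, opt$v)
  opt$v <- r[[2L]]
  opt$iter <- opt$iter + 1L
  list(params = r[[1L]], opt = opt)
}
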