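# Finite-difference gradient checking against the hand-derived backward
# passes. Inputs are drawn from continuous distributions so max-style ops
# (pooling, channel max) are differentiable at the sampled points with
# probability 1.

fd_key <- function(k) if (grepl("^[0-9]+$", k)) as.integer(k) else k

fd_modify <- function(p, path, i, delta) {
  k <- fd_key(path[1L])
  if (length(path) == 1L) {
    p[[k]][i] <- p[[k]][i] + delta
    p
  } else {
    p[[k]] <- fd_modify(p[[k]], path[-1L], i, delta)
    p
  }
}

# Max abs deviation between analytic and central-difference gradients over
# `n` randomly chosen parameter entries.
fd_param_error <- function(loss_fn, params, grads, n = 15L, h = 1e-5) {
  lv <- param_leaves(params)
  gv <- param_leaves(grads)
  err <- 0
  for (rep in seq_len(n)) {
    nm <- sample(names(lv), 1L)
    i <- sample(length(lv[[nm]]), 1L)
    path <- strsplit(sub("^/", "", nm), "/")[[1L]]
    g <- (loss_fn(fd_modify(params, path, i, h)) -
            loss_fn(fd_modify(params, path, i, -h))) / (2 * h)
    err <- max(err, abs(g - gv[[nm]][i]))
  }
  err
}

fd_input_error <- function(loss_fn, x, dx, n = 10L, h = 1e-5) {
  err <- 0
  for (i in sample(length(x), min(n, length(x)))) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    err <- max(err, abs((loss_fn(xp) - loss_fn(xm)) / (2 * h) - dx[i]))
  }
  err
}

rand_fm <- function(H, W, C, N) array(rnorm(H * W * C * N), dim = c(H, W, C, N))

tiny_phantom_config <- function(size = 32L) phantom_config(image_size = size)
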