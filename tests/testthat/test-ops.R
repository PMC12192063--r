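test_that("convolution matches a direct loop oracle", {
  set.seed(10)
  x <- rand_fm(4, 4, 2, 1)
  w <- he_init(3, 3, 2, 1)
  b <- 0.3
  y <- conv2d_fw(x, w, b)$y
  naive <- array(0, dim = c(4, 4, 1, 1))
  for (ho in 1:4) for (wo in 1:4) {
    acc <- b
    for (ki in 1:3) for (kj in 1:3) for (cc in 1:2) {
      hi <- ho + ki - 2; wi <- wo + kj - 2
      if (hi >= 1 && hi <= 4 && wi >= 1 && wi <= 4)
        acc <- acc + x[hi, wi, cc, 1] * w[ki, kj, cc, 1]
    }
    naive[ho, wo, 1, 1] <- acc
  }
  expect_lt(max(abs(y - naive)), 1e-12)
})

test_that("core op backward passes agree with finite differences", {
  set.seed(11)
  x <- rand_fm(6, 6, 4, 2)
  w <- he_init(3, 3, 4, 3)
  b <- rnorm(3)
  f <- conv2d_fw(x, w, b)
  dy <- array(rnorm(length(f$y)), dim(f$y))
  g <- conv2d_bw(f$cache, dy)
  expect_lt(fd_input_error(function(xx) sum(conv2d_fw(array(xx, dim(x)), w, b)$y * dy),
                           x, g$dx), 1e-6)
  expect_lt(fd_input_error(function(ww) sum(conv2d_fw(x, array(ww, dim(w)), b)$y * dy),
                           w, g$dw), 1e-6)

  # grouped convolution
  xg <- rand_fm(5, 5, 6, 2)
  wg <- he_init(3, 3, 2, 3)
  fg <- conv2d_fw(xg, wg, NULL, groups = 3L)
  dyg <- array(rnorm(length(fg$y)), dim(fg$y))
  gg <- conv2d_bw(fg$cache, dyg)
  expect_lt(fd_input_error(function(xx)
    sum(conv2d_fw(array(xx, dim(xg)), wg, NULL, groups = 3L)$y * dyg),
    xg, gg$dx), 1e-6)

  # batchnorm
  gma <- runif(4, 0.5, 1.5); bta <- rnorm(4)
  bn <- batchnorm_fw(x, gma, bta)
  dyb <- array(rnorm(length(bn$y)), dim(bn$y))
  gb <- batchnorm_bw(bn$cache, dyb)
  expect_lt(fd_input_error(function(xx)
    sum(batchnorm_fw(array(xx, dim(x)), gma, bta)$y * dyb), x, gb$dx), 1e-4)

  # softmax over the channel axis
  sm <- softmax_channel_fw(x)
  dys <- array(rnorm(length(sm$y)), dim(sm$y))
  dxs <- softmax_channel_bw(sm$cache, dys)
  expect_lt(fd_input_error(function(xx)
    sum(softmax_channel_fw(array(xx, dim(x)))$y * dys), x, dxs), 1e-6)

  # pooling and upsampling
  mp <- maxpool2_fw(x)
  dyp <- array(rnorm(length(mp$y)), dim(mp$y))
  dxp <- maxpool2_bw(mp$cache, dyp)
  expect_lt(fd_input_error(function(xx)
    sum(maxpool2_fw(array(xx, dim(x)))$y * dyp), x, dxp, h = 1e-6), 1e-4)
  up <- upsample2_fw(mp$y)
  dyu <- array(rnorm(length(up$y)), dim(up$y))
  dxu <- upsample2_bw(NULL, dyu)
  expect_lt(fd_input_error(function(xx)
    sum(upsample2_fw(array(xx, dim(mp$y)))$y * dyu), mp$y, dxu), 1e-6)
})

test_that("channel softmax normalizes and channel reductions are exact", {
  set.seed(12)
  x <- rand_fm(5, 7, 6, 3)
  p <- softmax_channel(x)
  expect_true(all(p > 0))
  expect_lt(max(abs(sum_channels(p) - 1)), 1e-12)
  expect_equal(as.vector(sum_channels(x)),
               as.vector(apply(x, c(1, 2, 4), sum)))
  expect_equal(as.vector(max_channels(x)),
               as.vector(apply(x, c(1, 2, 4), max)))
  expect_equal(as.vector(argmax_channels(x)),
               as.vector(apply(x, c(1, 2, 4), which.max)))
})

test_that("U-Net preserves resolution and its gradients check out", {
  set.seed(13)
  p <- unet_init(2, base = 4, depth = 2, num_classes = 4)
  x <- rand_fm(8, 8, 2, 2)
  f <- unet_fw(p, x)
  expect_identical(dim(f$y), c(8L, 8L, 4L, 2L))
  dy <- array(rnorm(length(f$y)), dim(f$y))
  bw <- unet_bw(p, f$cache, dy)
  expect_lt(fd_param_error(function(pp) sum(unet_fw(pp, x)$y * dy),
                           p, bw$grads, n = 20), 1e-4)
  expect_error(unet_fw(p, rand_fm(6, 6, 2, 1)), "divisible")
})

test_that("SGD with poly decay updates parameters and respects freezing", {
  set.seed(14)
  p <- list(a = matrix(rnorm(4), 2), b = numeric(2))
  g <- list(a = matrix(1, 2, 2), b = c(1, 1))
  opt <- sgd_init(p, lr = 0.1, momentum = 0, weight_decay = 0, max_iter = 10)
  up <- sgd_step(p, g, opt)
  expect_equal(up$params$a, p$a - 0.1 * g$a)
  expect_equal(poly_lr(0.1, 5, 10, 0.9), 0.1 * 0.5^0.9)
  pf <- freeze_params(p)
  upf <- sgd_step(pf, g, opt)
  expect_identical(upf$params, pf)
})
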