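test_that("quadrant partition and reassembly are exact inverses", {
  set.seed(50)
  x <- rand_fm(8, 10, 3, 2)
  q <- partition_quadrants(x)
  expect_identical(dim(q$FA), c(4L, 5L, 3L, 2L))
  expect_identical(reassemble_quadrants(q), x)
  # 2x2 input: quadrants equal direct indexing
  x2 <- rand_fm(2, 2, 1, 1)
  q2 <- partition_quadrants(x2)
  expect_equal(q2$FA[1, 1, 1, 1], x2[1, 1, 1, 1])
  expect_equal(q2$FB[1, 1, 1, 1], x2[1, 2, 1, 1])
  expect_equal(q2$FC[1, 1, 1, 1], x2[2, 1, 1, 1])
  expect_equal(q2$FD[1, 1, 1, 1], x2[2, 2, 1, 1])
  expect_error(partition_quadrants(rand_fm(5, 4, 1, 1)), "even")
})

test_that("self-attention matches a hand-rolled small-case oracle", {
  set.seed(51)
  p <- mha_init(2, 1)
  x <- rand_fm(1, 3, 2, 1) # three tokens
  f <- mha_fw(p, x, 1)
  X <- matrix(x[, , , 1], 3, 2)
  Q <- X %*% p$wq; K <- X %*% p$wk; V <- X %*% p$wv
  S <- (1 / sqrt(2)) * Q %*% t(K)
  A <- exp(S) / rowSums(exp(S))
  Y <- (A %*% V) %*% p$wout + matrix(p$bout, 3, 2, byrow = TRUE)
  expect_lt(max(abs(matrix(f$y[, , , 1], 3, 2) - Y)), 1e-5)
  # attention rows are nonnegative and normalized
  expect_true(all(f$cache$per[[1]]$A[[1]] >= 0))
  expect_lt(max(abs(rowSums(f$cache$per[[1]]$A[[1]]) - 1)), 1e-12)
  # single token: attention weight is 1, output is the projected value
  p4 <- mha_init(4, 2)
  x1 <- rand_fm(1, 1, 4, 1)
  f1 <- mha_fw(p4, x1, 2)
  V1 <- matrix(x1[, , , 1], 1, 4) %*% p4$wv
  expect_lt(max(abs(matrix(f1$y[, , , 1], 1, 4) -
                      (V1 %*% p4$wout + p4$bout))), 1e-12)
  expect_error(mha_init(5, 2), "divisible")
})

test_that("attention gradients agree with finite differences", {
  set.seed(52)
  p <- mha_init(4, 2)
  x <- rand_fm(3, 4, 4, 2)
  f <- mha_fw(p, x, 2)
  dy <- array(rnorm(length(f$y)), dim(f$y))
  bw <- mha_bw(p, f$cache, dy)
  expect_lt(fd_param_error(function(pp) sum(mha_fw(pp, x, 2)$y * dy),
                           p, bw$grads), 1e-4)
  expect_lt(fd_input_error(function(xx)
    sum(mha_fw(p, array(xx, dim(x)), 2)$y * dy), x, bw$dx), 1e-4)
})

test_that("MPA reduces to a plain convolution at theta = 0 and is linear", {
  set.seed(53)
  p <- mpa_init(3)
  x <- rand_fm(4, 4, 3, 2)
  p0 <- p; p0$theta <- 0
  f0 <- mpa_fw(p0, x)
  expect_identical(f0$keff, p$w)
  expect_equal(f0$y, conv2d_fw(x, p$w, NULL)$y)
  expect_true(all(mpa_fw(p, x * 0)$y == 0))
})

test_that("MPA effective kernel matches the mask arithmetic and trains", {
  set.seed(54)
  p <- mpa_init(2)
  x <- rand_fm(4, 4, 2, 1)
  f <- mpa_fw(p, x)
  cm <- matrix(0.5, 3, 3); cm[2, 2] <- 1
  for (n in 1:2) {
    s_n <- sum(p$w[, , , n])
    M <- 1 - p$theta * s_n * (p$mlearn * cm)
    for (cc in 1:2)
      expect_lt(max(abs(f$keff[, , cc, n] - p$w[, , cc, n] * M)), 1e-12)
  }
  expect_equal(f$y, conv2d_fw(x, f$keff, NULL)$y)
  dy <- array(rnorm(length(f$y)), dim(f$y))
  bw <- mpa_bw(p, f$cache, dy)
  expect_lt(fd_param_error(function(pp) sum(mpa_fw(pp, x)$y * dy),
                           p, bw$grads, n = 25), 1e-4)
  # the learnable mask and scale receive nonzero gradients
  expect_gt(max(abs(bw$grads$mlearn)), 0)
  expect_gt(abs(bw$grads$theta), 0)
})

test_that("region interaction follows the scripted operator chain", {
  set.seed(55)
  p <- region_interaction_init(4)
  q <- lapply(1:4, function(i) rand_fm(4, 4, 4, 1))
  names(q) <- c("FA", "FB", "FC", "FD")
  f <- region_interaction_fw(p, q)
  catc <- cat_channel(q$FA, q$FB, q$FC, q$FD)
  c1 <- conv2d_fw(catc, p$c1$w, p$c1$b)$y
  c1[c1 < 0] <- 0
  parts <- split_channel(c1, rep(4, 4))
  fa_full <- reassemble_quadrants(list(FA = parts[[1]], FB = parts[[2]],
                                       FC = parts[[3]], FD = parts[[4]]))
  fa <- 1 / (1 + exp(-conv2d_fw(fa_full, p$c2$w, p$c2$b)$y))
  faq <- partition_quadrants(fa)
  for (nm in c("FA", "FB", "FC", "FD"))
    expect_lt(max(abs(f$q[[nm]] -
                        softmax_channel(q[[nm]] + q[[nm]] * faq[[nm]]))), 1e-5)
  # identical quadrants stay identical after interaction, in the quadrant
  # interiors, when the interaction convolution treats the four channel
  # groups symmetrically (block-symmetric weights: one self-block, one
  # shared cross-block). At quadrant edges the 3x3 convolutions see seams
  # vs zero-padded borders, so only pixels whose receptive field stays
  # inside the own quadrant are exchangeable.
  ps <- p
  A <- he_init(3, 3, 4, 4)
  B <- he_init(3, 3, 4, 4)
  for (g in 1:4) for (h in 1:4)
    ps$c1$w[, , (h - 1) * 4 + 1:4, (g - 1) * 4 + 1:4] <- if (g == h) A else B
  ps$c1$b <- rep(ps$c1$b[1:4], 4)
  qq <- q; qq$FB <- qq$FA; qq$FC <- qq$FA; qq$FD <- qq$FA
  fs <- region_interaction_fw(ps, qq)$q
  inner <- 2:3 # receptive field of both 3x3 convs stays inside the quadrant
  expect_equal(fs$FA[inner, inner, , , drop = FALSE],
               fs$FD[inner, inner, , , drop = FALSE])
  expect_equal(fs$FB[inner, inner, , , drop = FALSE],
               fs$FC[inner, inner, , , drop = FALSE])
  # zero interaction map: update collapses to a channel softmax
  pz <- p
  pz$c2$w <- pz$c2$w * 0
  pz$c2$b <- rep(-50, 4) # sigmoid ~ 0
  fz <- region_interaction_fw(pz, q)$q
  expect_lt(max(abs(fz$FA - softmax_channel(q$FA))), 1e-8)
})

test_that("assistant produces full-resolution 4-class output and its loss is the shared task loss", {
  set.seed(56)
  p <- assistant_init(4, num_heads = 2)
  x <- rand_fm(16, 16, 1, 2)
  f <- assistant_fw(p, x)
  expect_identical(dim(f$logits), c(16L, 16L, 4L, 2L))
  expect_lt(max(abs(sum_channels(f$probs) - 1)), 1e-5)
  expect_error(assistant_fw(p, rand_fm(16, 16, 2, 1)), "single modality")

  lab <- matrix(sample(c(0L, 1L, 2L, 4L), 256, TRUE), 16)
  labs <- stack_labels(list(lab, lab))
  la <- task_loss(f$logits, labs)
  expect_equal(la$total, mean(la$per_sample$total))

  dy <- task_loss_bw(la$cache)
  bw <- assistant_bw(p, f$cache, dy)
  expect_lt(fd_param_error(function(pp)
    task_loss(assistant_fw(pp, x)$logits, labs)$total, p, bw$grads, n = 20), 1e-4)
  # peripheral parameters (mask, scale, attention) receive gradient
  expect_gt(max(abs(bw$grads$per$mpa$mlearn)), 0)
  expect_gt(abs(bw$grads$per$mpa$theta), 0)
  expect_gt(max(abs(bw$grads$per$mha$wq)), 0)
})
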