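test_that("expert subnetworks preserve shape and pass gradient checks", {
  set.seed(30)
  p <- expert_init(8)
  x <- rand_fm(6, 6, 8, 2)
  f <- expert_fw(p, x)
  expect_identical(dim(f$y), dim(x))
  # zero input with zero biases stays zero through conv-ReLU-conv
  p0 <- p
  p0$c1$b <- p0$c1$b * 0
  p0$c2$b <- p0$c2$b * 0
  expect_true(all(expert_fw(p0, x * 0)$y == 0))
  dy <- array(rnorm(length(f$y)), dim(f$y))
  bw <- expert_bw(p, f$cache, dy)
  expect_lt(fd_input_error(function(xx)
    sum(expert_fw(p, array(xx, dim(x)))$y * dy), x, bw$dx), 1e-6)
})

test_that("gate weights are a per-pixel softmax over the expert axis", {
  set.seed(31)
  p <- conv_init(4, 4, k = 1L)
  x <- rand_fm(5, 5, 4, 3)
  g <- gate_fw(p, x)$y
  expect_identical(dim(g), c(5L, 5L, 4L, 3L))
  expect_true(all(g >= 0))
  expect_lt(max(abs(sum_channels(g) - 1)), 1e-5)
  # all-zero gate parameters give uniform 1/k weights
  p0 <- p
  p0$w <- p0$w * 0
  p0$b <- p0$b * 0
  expect_lt(max(abs(gate_fw(p0, x)$y - 0.25)), 1e-12)
  # scalar softmax oracle for logits (2, 0, 0, 0)
  expect_equal(as.vector(softmax_channel(array(c(2, 0, 0, 0), c(1, 1, 4, 1)))),
               c(exp(2), 1, 1, 1) / (exp(2) + 3))
})

test_that("MHMoE matches the per-pixel loop oracle and preserves shape", {
  set.seed(32)
  cfg <- mhmoe_config(channels = 8, num_heads = 2, num_experts = 2)
  p <- mhmoe_init(cfg)
  x <- rand_fm(6, 6, 8, 1)
  f <- mhmoe_fw(p, x, cfg)
  expect_identical(dim(f$y), dim(x))
  ch <- 4L
  oracle <- array(0, dim(x))
  for (i in 1:2) {
    idx <- (i - 1L) * ch + seq_len(ch)
    xi <- x[, , idx, , drop = FALSE]
    g <- gate_fw(p$heads[[i]]$gate, xi)$y
    for (j in 1:2) {
      ej <- expert_fw(p$heads[[i]]$experts[[j]], xi)$y
      for (cc in seq_len(ch)) for (hh in 1:6) for (ww in 1:6)
        oracle[hh, ww, idx[cc], 1] <- oracle[hh, ww, idx[cc], 1] +
          g[hh, ww, j, 1] * ej[hh, ww, cc, 1]
    }
  }
  expect_lt(max(abs(f$y - oracle)), 1e-5)
})

test_that("MHMoE degenerates correctly: k = 1 and one-hot gating", {
  set.seed(33)
  cfg1 <- mhmoe_config(channels = 4, num_heads = 2, num_experts = 1)
  p1 <- mhmoe_init(cfg1)
  x <- rand_fm(4, 4, 4, 2)
  f1 <- mhmoe_fw(p1, x, cfg1)
  ora <- array(0, dim(x))
  for (i in 1:2) {
    idx <- (i - 1L) * 2L + 1:2
    ora[, , idx, ] <- expert_fw(p1$heads[[i]]$experts[[1]],
                                x[, , idx, , drop = FALSE])$y
  }
  expect_lt(max(abs(f1$y - ora)), 1e-12)

  # force a one-hot gate on expert 2 via a huge bias
  cfg <- mhmoe_config(channels = 4, num_heads = 2, num_experts = 2)
  p <- mhmoe_init(cfg)
  for (i in 1:2) {
    p$heads[[i]]$gate$w <- p$heads[[i]]$gate$w * 0
    p$heads[[i]]$gate$b <- c(-50, 50)
  }
  f <- mhmoe_fw(p, x, cfg)
  ora2 <- array(0, dim(x))
  for (i in 1:2) {
    idx <- (i - 1L) * 2L + 1:2
    ora2[, , idx, ] <- expert_fw(p$heads[[i]]$experts[[2]],
                                 x[, , idx, , drop = FALSE])$y
  }
  expect_lt(max(abs(f$y - ora2)), 1e-8)
})

test_that("MHMoE output lies in the convex hull of frozen expert outputs", {
  set.seed(34)
  cfg <- mhmoe_config(channels = 4, num_heads = 1, num_experts = 3)
  p <- mhmoe_init(cfg)
  x <- rand_fm(5, 5, 4, 1)
  f <- mhmoe_fw(p, x, cfg)
  eo <- sapply(1:3, function(j) expert_fw(p$heads[[1]]$experts[[j]], x)$y)
  lo <- array(apply(eo, 1, min), dim(x))
  hi <- array(apply(eo, 1, max), dim(x))
  expect_true(all(f$y >= lo - 1e-10 & f$y <= hi + 1e-10))
})

test_that("all experts and gates receive nonzero gradients under soft gating", {
  set.seed(35)
  cfg <- mhmoe_config(channels = 4, num_heads = 2, num_experts = 2)
  p <- mhmoe_init(cfg)
  x <- rand_fm(6, 6, 4, 2)
  f <- mhmoe_fw(p, x, cfg)
  dy <- array(rnorm(length(f$y)), dim(f$y))
  bw <- mhmoe_bw(p, f$cache, dy, cfg)
  expect_lt(fd_param_error(function(pp) sum(mhmoe_fw(pp, x, cfg)$y * dy),
                           p, bw$grads), 1e-4)
  for (lv in param_leaves(bw$grads))
    expect_gt(max(abs(lv)), 0)
})

test_that("invalid MHMoE configurations are rejected", {
  expect_error(mhmoe_config(channels = 6, num_heads = 4), "divisible")
  expect_error(mhmoe_config(channels = 4, num_heads = 0), ">= 1")
  cfg <- mhmoe_config(channels = 8, num_heads = 2, num_experts = 2)
  p <- mhmoe_init(cfg)
  expect_error(mhmoe_fw(p, rand_fm(4, 4, 6, 1), cfg), "mismatch")
})
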