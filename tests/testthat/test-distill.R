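test_that("teacher-assistant blending has the limit and normalization properties", {
  set.seed(70)
  pt <- softmax_channel(rand_fm(4, 4, 4, 2))
  pa <- softmax_channel(rand_fm(4, 4, 4, 2))
  expect_equal(teacher_assistant_output(pt, pa, 1)$probs, pt)
  expect_equal(teacher_assistant_output(pt, pt, 0.5)$probs, pt)
  b <- teacher_assistant_output(pt, pa, 0.3)$probs
  expect_lt(max(abs(sum_channels(b) - 1)), 1e-6)
  expect_error(teacher_assistant_output(pt, pa, 1.5), "ta_weight")
})

test_that("KD loss has its algebraic limits and matches a scalar oracle", {
  set.seed(71)
  z <- rand_fm(4, 4, 3, 2)
  expect_lt(kd_loss(z, softmax_channel(z), tau = 3)$value, 1e-12)
  # tau -> inf: both sides soften to uniform
  q <- softmax_channel(rand_fm(4, 4, 3, 2))
  expect_lt(kd_loss(z, q, tau = 1e6)$value, 1e-9)
  expect_error(kd_loss(z, q, tau = 0), "positive")
  # scalar oracle: one pixel, 3 classes, tau = 2
  zs <- array(c(1, 0, -1), c(1, 1, 3, 1))
  zt <- array(c(0.5, 0.2, 0.3), c(1, 1, 3, 1))
  qs <- exp(c(1, 0, -1) / 2); qs <- qs / sum(qs)
  qt <- exp(log(c(0.5, 0.2, 0.3) / sum(c(0.5, 0.2, 0.3))) / 2)
  qt <- qt / sum(qt)
  ora <- sum((qt - qs)^2)
  expect_equal(kd_loss(zs, array(c(0.5, 0.2, 0.3), c(1, 1, 3, 1)), tau = 2)$value,
               ora, tolerance = 1e-10)
})

test_that("student loss is the exact convex combination", {
  expect_equal(student_loss(2, 1, alpha = 1), 2)
  expect_equal(student_loss(2, 1, alpha = 0), 1)
  expect_equal(student_loss(2, 1, alpha = 0.3), 1.3)
  expect_error(student_loss(1, 1, alpha = 1.2), "alpha")
})

test_that("competitive loss reproduces the scalar worked example", {
  r <- competitive_loss(L_T = 0.5, L_TA = 0.5, L_S = 0.3,
                        lambda = 0.1, mu = 10)
  expect_equal(r$terms$r, 0.02)
  expect_equal(r$terms$gamma, 0.625)
  expect_equal(r$terms$delta, exp(0.05))
  expect_equal(r$value, 0.625 * exp(0.05) * 0.02, tolerance = 1e-12)
  expect_equal(r$value, 0.01314, tolerance = 1e-3)
})

test_that("competitive loss: tie gives exactly zero, signs and slopes behave", {
  set.seed(72)
  L_T <- runif(20, 0.1, 2)
  L_S <- runif(20, 0.1, 2)
  tie <- competitive_loss(L_T, L_S, L_S)
  expect_identical(tie$value, 0)
  # sign of the loss follows the sign of the weighted mean reward
  L_TA <- runif(20, 0.1, 2)
  cl <- competitive_loss(L_T, L_TA, L_S)
  expect_equal(sign(cl$value),
               sign(sum(cl$terms$gamma * cl$terms$delta * cl$terms$r)))
  # d r_i / d L_S_i = -lambda, verified by finite differences
  h <- 1e-6
  up <- competitive_loss(L_T, L_TA, L_S + h, lambda = 0.1)
  dn <- competitive_loss(L_T, L_TA, L_S - h, lambda = 0.1)
  expect_equal((up$terms$r - dn$terms$r) / (2 * h), rep(-0.1, 20),
               tolerance = 1e-6)
  expect_error(competitive_loss(-1, 1, 1), "nonnegative")
})

test_that("gamma and delta ranges hold over many random loss draws", {
  set.seed(73)
  for (rep in 1:100) {
    L_T <- runif(5, 1e-3, 5)
    L_TA <- runif(5, 0, 5)
    L_S <- runif(5, 1e-3, 5)
    cl <- competitive_loss(L_T, L_TA, L_S, lambda = 0.1, mu = 10)
    expect_true(all(cl$terms$gamma > 0 & cl$terms$gamma < 1))
    expect_true(all(cl$terms$delta >= 1))
  }
  # gamma is monotone: increasing in L_T, decreasing in L_S
  g1 <- competitive_loss(1, 1, 1)$terms$gamma
  expect_gt(competitive_loss(2, 1, 1)$terms$gamma, g1)
  expect_lt(competitive_loss(1, 1, 2)$terms$gamma, g1)
})

test_that("total loss is the exact weighted sum", {
  expect_equal(total_loss(2, 0.4, 1,
                          list(lambda_student = 1, lambda_comp = 0.5,
                               lambda_res = 0.5)), 2.7)
  expect_equal(total_loss(5, 5, 5, list(lambda_student = 0, lambda_comp = 0,
                                        lambda_res = 0)), 0)
  expect_equal(total_loss(3, 9, 9, list(lambda_student = 1, lambda_comp = 0,
                                        lambda_res = 0)), 3)
})

test_that("ablation toggles map onto the objective structurally", {
  ab <- ablation_config(mhmoe = TRUE, assistant = TRUE, compete = FALSE)
  expect_equal(ab$config$lambda_comp, 0)
  ab2 <- ablation_config(assistant = FALSE)
  expect_equal(ab2$config$lambda_res, 0)
  expect_equal(ab2$config$ta_weight, 1)
  expect_false(ab2$use_assistant)
  ab3 <- ablation_config(mhmoe = FALSE)
  expect_false(ab3$use_mhmoe)
  # the teacher built without MHMoE has no expert stage
  pt <- teacher_init(4, num_heads = 2, num_experts = 2, depth = 2,
                     use_mhmoe = FALSE)
  expect_null(pt$moe)
})

test_that("distillation training updates student and assistant but never the teacher", {
  set.seed(74)
  samples <- generate_phantom_dataset(6, phantom_config(image_size = 32), seed = 5)
  tr <- pretrain_teacher(samples, epochs = 3, channels = 4, lr = 0.05,
                         batch_size = 3, seed = 0, depth = 2)
  res <- train_student(samples, "t1", tr$params, epochs = 3, channels = 4,
                       lr = 0.05, batch_size = 3, seed = 0,
                       val_samples = samples[1:2])
  expect_identical(res$teacher_checksum_before, res$teacher_checksum_after)
  expect_equal(nrow(res$log), 3)
  expect_true(all(c("L_task", "L_KD", "L_student", "L_comp", "L_assistant",
                    "L_total", "val_dice_wt") %in% names(res$log)))
  # unfrozen teacher is rejected; missing modality is rejected
  expect_error(train_student(samples, "t1", teacher_init(4, 2, 2, 2)),
               "frozen")
  s2 <- lapply(samples, function(s) { s$t2 <- NULL; s })
  expect_error(train_student(s2, "t2", tr$params, epochs = 1, channels = 4,
                             batch_size = 3), "missing")
})
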