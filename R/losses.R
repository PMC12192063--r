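# Segmentation and distillation losses.
#
# Task loss (teacher, assistant and student alike): mean pixelwise
# cross-entropy plus the sum over the three foreground tumor classes of
# (1 - soft Dice), computed per sample so the competitive mechanism can
# weight samples individually.

#' Map BraTS label values to class indices
#'
#' `{0, 1, 2, 4}` (background, necrotic/non-enhancing core, edema, enhancing)
#' become class indices 1..4.
#'
#' @param label integer matrix or array with values in \{0, 1, 2, 4\}.
#' @return same-shaped integer array of class indices.
#' @export
remap_labels <- function(label) {
  lut <- c(`0` = 1L, `1` = 2L, `2` = 3L, `4` = 4L)
  v <- lut[as.character(as.integer(label))]
  if (anyNA(v)) stop("label contains values outside {0,1,2,4}")
  array(v, dim = dim(label))
}

# labels: (H, W, N) class indices 1..K -> one-hot (H, W, K, N)
one_hot <- function(cls, K = 4L) {
  d <- dim(cls)
  t <- array(0, dim = c(d[1L], d[2L], K, d[3L]))
  for (k in seq_len(K)) t[, , k, ] <- cls == k
  t
}

stack_labels <- function(labels) {
  if (is.list(labels)) {
    d <- dim(labels[[1L]])
    array(unlist(labels), dim = c(d, length(labels)))
  } else if (length(dim(labels)) == 2L) {
    array(labels, dim = c(dim(labels), 1L))
  } else labels
}

#' Task loss: cross-entropy plus soft Dice
#'
#' `CE` is the mean pixelwise negative log-probability of the true class;
#' the Dice term sums `1 - softDice` over the three foreground classes
#' (smoothing `eps` in numerator and denominator). `total = ce + dice`.
#'
#' @param logits `(H, W, 4, N)` class logits.
#' @param labels `(H, W, N)` array, matrix, or list of matrices with raw
#'   label values in \{0, 1, 2, 4\}.
#' @param eps Dice smoothing constant.
#' @return list with scalars `ce`, `dice`, `total` (batch means / mean of
#'   per-sample totals), a `per_sample` data frame, and a `cache` for the
#'   backward pass.
#' @export
task_loss <- function(logits, labels, eps = 1e-5) {
  labels <- stack_labels(labels)
  cls <- remap_labels(labels)
  d <- dim(logits)
  if (!identical(dim(cls), d[c(1L, 2L, 4L)])) stop("label shape does not match logits")
  K <- d[3L]
  N <- d[4L]
  npix <- d[1L] * d[2L]
  p <- softmax_channel(logits)
  t <- one_hot(cls, K)
  ce_i <- numeric(N)
  dice_i <- numeric(N)
  dstat <- vector("list", N)
  for (i in seq_len(N)) {
    pi <- p[, , , i, drop = FALSE]
    ti <- t[, , , i, drop = FALSE]
    ce_i[i] <- -sum(ti * log(pi + 1e-12)) / npix
    st <- lapply(2:K, function(k) {
      A <- sum(pi[, , k, 1L] * ti[, , k, 1L])
      B <- sum(pi[, , k, 1L]) + sum(ti[, , k, 1L])
      c(A = A, B = B)
    })
    dice_i[i] <- sum(vapply(st, function(s) 1 - (2 * s["A"] + eps) / (s["B"] + eps),
                            numeric(1L)))
    dstat[[i]] <- st
  }
  list(ce = mean(ce_i), dice = mean(dice_i), total = mean(ce_i + dice_i),
       per_sample = data.frame(ce = ce_i, dice = dice_i, total = ce_i + dice_i),
       cache = list(p = p, t = t, dstat = dstat, eps = eps, npix = npix, K = K))
}

#' Task-loss gradient with per-sample weights
#'
#' Returns `d(sum_i w_i * total_i) / d logits`; with the default
#' `w = rep(1/N, N)` this is the gradient of the batch-mean task loss.
#'
#' @param cache cache from [task_loss()].
#' @param w per-sample weight vector.
#' @return gradient array shaped like the logits.
#' @export
task_loss_bw <- function(cache, w = NULL) {
  p <- cache$p; t <- cache$t
  d <- dim(p)
  N <- d[4L]; K <- cache$K
  if (is.null(w)) w <- rep(1 / N, N)
  dlogits <- array(0, dim = d)
  for (i in seq_len(N)) {
    pi <- p[, , , i, drop = FALSE]
    ti <- t[, , , i, drop = FALSE]
    # CE through softmax collapses to (p - t)/npix
    dz <- (pi - ti) / cache$npix
    # Dice: dL/dp then softmax jacobian
    dp <- array(0, dim = dim(pi))
    for (k in 2:K) {
      s <- cache$dstat[[i]][[k - 1L]]
      A <- s[["A"]]; B <- s[["B"]]
      denom <- (B + cache$eps)^2
      dp[, , k, 1L] <- -(2 * ti[, , k, 1L] * (B + cache$eps) - (2 * A + cache$eps)) / denom
    }
    dz_dice <- pi * (dp - bcast_channel(sum_channels(dp * pi), K))
    dlogits[, , , i] <- w[i] * (dz + dz_dice)
  }
  dlogits
}

# Temperature softening of a probability map: softmax(log(p)/tau) over the
# class axis.
soften_probs <- function(p, tau) {
  softmax_channel(log(pmax(p, 1e-12)) / tau)
}

#' Knowledge-distillation loss
#'
#' Mean over pixels and samples of the squared L2 distance between the
#' temperature-softened class distributions of the student (from logits) and
#' the distillation target (a probability map, typically the blended
#' teacher-assistant output). Softening shrinks both the distance and its
#' gradient (by roughly `1/tau^2` for large `tau`), so the default
#' temperature is 1: the un-softened squared distance carries the strongest
#' signal under this objective, and the temperature stays exposed for
#' experimentation.
#'
#' @param student_logits `(H, W, K, N)` logits.
#' @param target_probs `(H, W, K, N)` probabilities.
#' @param tau softening temperature (> 0).
#' @return list with scalar `value` and `cache`.
#' @export
kd_loss <- function(student_logits, target_probs, tau = 1) {
  if (tau <= 0) stop("tau must be positive")
  if (!identical(dim(student_logits), dim(target_probs))) stop("shape mismatch")
  ps <- softmax_channel(student_logits / tau)
  qt <- soften_probs(target_probs, tau)
  d <- dim(ps)
  scale <- 1 / (d[1L] * d[2L] * d[4L])
  value <- sum((qt - ps)^2) * scale
  list(value = value,
       cache = list(ps = ps, qt = qt, target_probs = target_probs,
                    tau = tau, scale = scale))
}

#' Knowledge-distillation loss gradients
#'
#' @param cache cache from [kd_loss()].
#' @return list with `dstudent_logits` and `dtarget_probs`.
#' @export
kd_loss_bw <- function(cache) {
  ps <- cache$ps; qt <- cache$qt
  tau <- cache$tau; sc <- cache$scale
  dps <- 2 * (ps - qt) * sc
  dz <- softmax_channel_bw(ps, dps) / tau
  dqt <- 2 * (qt - ps) * sc
  dlogq <- softmax_channel_bw(qt, dqt) / tau
  dtarget <- dlogq / pmax(cache$target_probs, 1e-12)
  list(dstudent_logits = dz, dtarget_probs = dtarget)
}

#' Student loss: convex mix of task and distillation loss
#'
#' @param task scalar task loss.
#' @param kd scalar distillation loss.
#' @param alpha mixing weight in \[0, 1\].
#' @return `alpha * task + (1 - alpha) * kd`.
#' @export
student_loss <- function(task, kd, alpha = 0.5) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  alpha * task + (1 - alpha) * kd
}

#' Reward-weighted competitive loss
#'
#' Per sample i: reward `r_i = lambda * (L_TA_i - L_S_i)` (positive when the
#' student beats the teacher-assistant), relative-difficulty weight
#' `gamma_i = L_T_i / (L_T_i + L_S_i)` and emphasis weight
#' `delta_i = exp(L_TA_i / mu)`. The reported loss is
#' `sum_i gamma_i * delta_i * r_i`, which grows as the student wins. The
#' training loop therefore descends on the negated reward: each sample's
#' task-loss gradient receives the extra weight `lambda * gamma_i * delta_i`
#' (`-dL_S`), so difficult samples where the student trails the
#' teacher-assistant are emphasized. `gamma` and `delta` act as detached
#' sample weights.
#'
#' @param L_T per-sample losses of the frozen teacher.
#' @param L_TA per-sample losses of the blended teacher-assistant output.
#' @param L_S per-sample losses of the student.
#' @param lambda reward scale (default 0.1).
#' @param mu difficulty scale (default 10).
#' @return list with scalar `value`, a `terms` data frame (`r`, `gamma`,
#'   `delta`), and `dL_S`, the gradient of the loss with respect to each
#'   `L_S[i]` (`-lambda * gamma_i * delta_i`).
#' @export
competitive_loss <- function(L_T, L_TA, L_S, lambda = 0.1, mu = 10) {
  if (mu <= 0) stop("mu must be positive")
  n <- length(L_S)
  if (length(L_T) != n || length(L_TA) != n) stop("loss vectors must have equal length")
  if (any(c(L_T, L_TA, L_S) < 0)) stop("losses must be nonnegative")
  r <- lambda * (L_TA - L_S)
  gamma <- L_T / (L_T + L_S)
  delta <- exp(L_TA / mu)
  list(value = sum(gamma * delta * r),
       terms = data.frame(r = r, gamma = gamma, delta = delta),
       dL_S = -lambda * gamma * delta)
}

#' Total training objective
#'
#' @param student scalar student loss.
#' @param competitive scalar competitive loss.
#' @param assistant scalar assistant task loss.
#' @param weights named list/vector with `lambda_student`, `lambda_comp`,
#'   `lambda_res`.
#' @return weighted sum.
#' @export
total_loss <- function(student, competitive, assistant,
                       weights = list(lambda_student = 1, lambda_comp = 1,
                                      lambda_res = 1)) {
  if (any(unlist(weights) < 0)) stop("loss weights must be nonnegative")
  weights$lambda_student * student + weights$lambda_comp * competitive +
    weights$lambda_res * assistant
}

#' Blend teacher and assistant outputs
#'
#' `ta_weight * teacher + (1 - ta_weight) * assistant` on probability maps,
#' renormalized over the class axis.
#'
#' @param p_teacher,p_assistant `(H, W, K, N)` probability maps.
#' @param ta_weight blend weight in \[0, 1\] on the teacher.
#' @return list with `probs` and `cache` (for the gradient into the
#'   assistant probabilities).
#' @export
teacher_assistant_output <- function(p_teacher, p_assistant, ta_weight = 0.7) {
  if (ta_weight < 0 || ta_weight > 1) stop("ta_weight must lie in [0, 1]")
  if (!identical(dim(p_teacher), dim(p_assistant))) stop("shape mismatch")
  mix <- ta_weight * p_teacher + (1 - ta_weight) * p_assistant
  d <- dim(mix)
  sb <- bcast_channel(sum_channels(mix), d[3L])
  probs <- mix / sb
  list(probs = probs,
       cache = list(mix = mix, sb = sb, ta_weight = ta_weight, d = d))
}

# Gradient of the blended probabilities wrt the assistant probabilities:
# dprobs/dmix through the renormalization, then * (1 - ta_weight).
teacher_assistant_bw <- function(cache, dprobs) {
  d <- cache$d
  # probs = mix / s; dmix = dprobs/s - (sum_c dprobs*mix / s^2)
  ib <- bcast_channel(sum_channels(dprobs * cache$mix), d[3L])
  dmix <- dprobs / cache$sb - ib / cache$sb^2
  (1 - cache$ta_weight) * dmix
}
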