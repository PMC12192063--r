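# Collaborative-competitive knowledge distillation.
#
# Step 1 pretrains the teacher and freezes it. Step 2 distills: the student
# sees one modality and learns from the blended teacher-assistant output via
# a temperature-softened KD loss mixed with its own task loss. Step 3 makes
# it compete: a reward r_i = lambda (L_TA_i - L_S_i), weighted by the
# relative-difficulty factor gamma_i and the emphasis factor delta_i, is
# minimized so the student is pushed below the teacher-assistant loss sample
# by sample. The assistant trains jointly (its own task loss plus the KD
# gradient through the blend), which is what lets the frozen teacher's
# output adapt.

#' Distillation configuration
#'
#' @param tau KD softening temperature (> 0); 1 (no softening) by default,
#'   since the squared-distance objective has no temperature compensation.
#' @param alpha task-vs-KD mixing weight in \[0, 1\].
#' @param lambda reward scale of the competitive loss (reference value 0.1).
#' @param mu difficulty scale of the emphasis weight (reference value 10).
#' @param lambda_student,lambda_comp,lambda_res nonnegative weights of the
#'   student, competitive and assistant terms in the total objective.
#' @param ta_weight teacher share in the teacher-assistant blend, in \[0, 1\]
#'   (1 distills from the teacher alone).
#' @return a `distill_config` list.
#' @export
distill_config <- function(tau = 1, alpha = 0.5, lambda = 0.1, mu = 10,
                           lambda_student = 1, lambda_comp = 1,
                           lambda_res = 1, ta_weight = 0.7) {
  if (tau <= 0) stop("tau must be positive")
  if (mu <= 0) stop("mu must be positive")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (ta_weight < 0 || ta_weight > 1) stop("ta_weight must lie in [0, 1]")
  if (any(c(lambda_student, lambda_comp, lambda_res) < 0))
    stop("loss weights must be nonnegative")
  structure(list(tau = tau, alpha = alpha, lambda = lambda, mu = mu,
                 lambda_student = lambda_student, lambda_comp = lambda_comp,
                 lambda_res = lambda_res, ta_weight = ta_weight),
            class = "distill_config")
}

#' Ablation toggles to a distillation configuration
#'
#' Component toggles of the ablation harness: `compete = FALSE` zeroes the
#' competitive weight; `assistant = FALSE` zeroes the assistant weight and
#' distills from the teacher alone (`ta_weight = 1`); `mhmoe` is consumed by
#' the teacher builder.
#'
#' @param mhmoe,assistant,compete logical component toggles.
#' @param base a [distill_config()] supplying the remaining values.
#' @return list with the adjusted `config`, `use_assistant` and `use_mhmoe`.
#' @export
ablation_config <- function(mhmoe = TRUE, assistant = TRUE, compete = TRUE,
                            base = distill_config()) {
  cfg <- base
  if (!compete) cfg$lambda_comp <- 0
  if (!assistant) {
    cfg$lambda_res <- 0
    cfg$ta_weight <- 1
  }
  list(config = cfg, use_assistant = assistant, use_mhmoe = mhmoe)
}

# Task loss (CE + Dice) evaluated on a probability map, per sample. Used for
# the teacher-assistant blend, which exists only as probabilities. No
# gradient needed: these losses enter the competitive loss as detached
# targets.
prob_task_loss_per_sample <- function(probs, labels, eps = 1e-5) {
  labels <- stack_labels(labels)
  cls <- remap_labels(labels)
  d <- dim(probs)
  t <- one_hot(cls, d[3L])
  npix <- d[1L] * d[2L]
  vapply(seq_len(d[4L]), function(i) {
    pi <- probs[, , , i, drop = FALSE]
    ti <- t[, , , i, drop = FALSE]
    ce <- -sum(ti * log(pi + 1e-12)) / npix
    dc <- sum(vapply(2:d[3L], function(k) {
      A <- sum(pi[, , k, 1L] * ti[, , k, 1L])
      B <- sum(pi[, , k, 1L]) + sum(ti[, , k, 1L])
      1 - (2 * A + eps) / (B + eps)
    }, numeric(1L)))
    ce + dc
  }, numeric(1L))
}

modality_batch <- function(samples, modality) {
  d <- dim(samples[[1L]]$label)
  x <- array(0, dim = c(d, 1L, length(samples)))
  for (i in seq_along(samples)) {
    img <- samples[[i]][[modality]]
    if (is.null(img)) stop("modality ", modality, " missing from dataset")
    x[, , 1L, i] <- img
  }
  x
}

#' Precompute frozen-teacher outputs for a dataset
#'
#' The teacher is frozen and deterministic, so its per-slice probabilities
#' and task losses are computed once and reused by every distillation run
#' against the same teacher.
#'
#' @param teacher frozen teacher parameters.
#' @param samples list of `multimodal_sample`s.
#' @return list (one element per sample) with `probs` and `loss`.
#' @export
precompute_teacher <- function(teacher, samples) {
  lapply(samples, function(s) {
    out <- teacher_forward(teacher, s)
    tl <- task_loss(out$logits, s$label)
    list(probs = out$probs, loss = tl$per_sample$total[1L])
  })
}

#' Train a single-modality student by competitive distillation
#'
#' Runs the joint student + assistant training loop against a frozen
#' teacher. Per minibatch: the student and assistant see the chosen modality,
#' the teacher-assistant blend forms the distillation target, and the total
#' objective `lambda_student * L_student + lambda_comp * L_competitive +
#' lambda_res * L_assistant` is backpropagated into the student and assistant
#' only. The competitive weights `gamma`/`delta` and the blend's own loss are
#' treated as detached targets, so the assistant cannot inflate rewards by
#' degrading itself.
#'
#' @param samples training `multimodal_sample`s.
#' @param modality one of `"t1"`, `"t1ce"`, `"t2"`, `"flair"`.
#' @param teacher frozen teacher parameters ([pretrain_teacher()]).
#' @param config a [distill_config()].
#' @param epochs training epochs.
#' @param channels base width of student and assistant.
#' @param lr,momentum,weight_decay,poly_power optimizer settings.
#' @param batch_size minibatch size.
#' @param seed seed for init and shuffling.
#' @param use_assistant train and blend the assistant; if `FALSE` the
#'   distillation target is the teacher alone.
#' @param val_samples optional validation set; WT/TC/ET Dice logged per epoch.
#' @param student,assistant optional pre-initialized parameter trees.
#' @param teacher_cache optional precomputed [precompute_teacher()] output
#'   for `samples` (reusable across paired runs with the same teacher).
#' @return list with `student`, `assistant`, per-epoch `log`, and the
#'   teacher checksum before/after.
#' @export
train_student <- function(samples, modality, teacher,
                          config = distill_config(), epochs = 40L,
                          channels = 8L, lr = 0.05, momentum = 0.9,
                          weight_decay = 1e-4, poly_power = 0.9,
                          batch_size = 8L, seed = 0L, use_assistant = TRUE,
                          val_samples = NULL, student = NULL, assistant = NULL,
                          teacher_cache = NULL) {
  if (!modality %in% c("t1", "t1ce", "t2", "flair"))
    stop("modality must be one of t1, t1ce, t2, flair")
  if (!is_frozen(teacher)) stop("teacher must be frozen before distillation")
  cks_before <- param_checksum(teacher)
  tpre <- if (is.null(teacher_cache)) precompute_teacher(teacher, samples)
          else teacher_cache
  n <- length(samples)
  with_seed(seed, {
    sp <- if (is.null(student)) student_init(channels) else student
    ap <- if (use_assistant) {
      if (is.null(assistant)) assistant_init(channels) else assistant
    } else NULL
    bs <- min(batch_size, n)
    steps_per_epoch <- ceiling(n / bs)
    opt_s <- sgd_init(sp, lr = lr, momentum = momentum,
                      weight_decay = weight_decay,
                      max_iter = epochs * steps_per_epoch,
                      poly_power = poly_power)
    opt_a <- if (use_assistant)
      sgd_init(ap, lr = lr, momentum = momentum, weight_decay = weight_decay,
               max_iter = epochs * steps_per_epoch, poly_power = poly_power)
    log <- NULL
    for (ep in seq_len(epochs)) {
      ord <- sample(n)
      acc <- c(L_task = 0, L_KD = 0, L_student = 0, L_comp = 0,
               L_assistant = 0, L_total = 0)
      for (st in seq_len(steps_per_epoch)) {
        idx <- ord[((st - 1L) * bs + 1L):min(st * bs, n)]
        nb <- length(idx)
        xb <- modality_batch(samples[idx], modality)
        labels <- stack_labels(lapply(samples[idx], `[[`, "label"))
        p_teacher <- array(0, dim = c(dim(xb)[1:2], 4L, nb))
        L_T <- numeric(nb)
        for (i in seq_len(nb)) {
          p_teacher[, , , i] <- tpre[[idx[i]]]$probs
          L_T[i] <- tpre[[idx[i]]]$loss
        }

        sf <- student_fw(sp, xb)
        s_tl <- task_loss(sf$logits, labels)
        L_S <- s_tl$per_sample$total

        if (use_assistant) {
          af <- assistant_fw(ap, xb)
          a_tl <- task_loss(af$logits, labels)
          ta <- teacher_assistant_output(p_teacher, af$probs, config$ta_weight)
          target <- ta$probs
        } else {
          a_tl <- NULL
          target <- p_teacher
        }
        L_TA <- prob_task_loss_per_sample(target, labels)

        kd <- kd_loss(sf$logits, target, config$tau)
        L_task <- mean(L_S)
        L_stu <- student_loss(L_task, kd$value, config$alpha)
        comp <- competitive_loss(L_T, L_TA, L_S, config$lambda, config$mu)
        L_ass <- if (use_assistant) a_tl$total else 0
        L_tot <- total_loss(L_stu, comp$value, L_ass,
                            list(lambda_student = config$lambda_student,
                                 lambda_comp = config$lambda_comp,
                                 lambda_res = config$lambda_res))

        # student gradient: task (mean + competitive per-sample weights) + KD.
        # The competitive term trains by descending the negated reward
        # (+lambda*gamma*delta/N per sample, batch-size invariant like the
        # mean task loss): hard samples where the student trails the
        # teacher-assistant get extra task-loss weight, so the reported
        # reward grows as the student wins.
        kdb <- kd_loss_bw(kd$cache)
        w_s <- rep(config$lambda_student * config$alpha / nb, nb) -
          config$lambda_comp * comp$dL_S / nb
        dz_s <- task_loss_bw(s_tl$cache, w_s) +
          config$lambda_student * (1 - config$alpha) * kdb$dstudent_logits
        sb <- student_bw(sp, sf$cache, dz_s)
        up <- sgd_step(sp, sb$grads, opt_s)
        sp <- up$params; opt_s <- up$opt

        if (use_assistant) {
          dz_a <- task_loss_bw(a_tl$cache,
                               rep(config$lambda_res / nb, nb))
          # KD gradient through the blend and the assistant softmax
          dprobs_a <- teacher_assistant_bw(ta$cache,
                                           config$lambda_student *
                                             (1 - config$alpha) *
                                             kdb$dtarget_probs)
          dz_a <- dz_a + softmax_channel_bw(af$probs, dprobs_a)
          ab <- assistant_bw(ap, af$cache, dz_a)
          upa <- sgd_step(ap, ab$grads, opt_a)
          ap <- upa$params; opt_a <- upa$opt
        }

        w <- nb / n
        acc <- acc + w * c(L_task, kd$value, L_stu, comp$value, L_ass, L_tot)
      }
      row <- as.data.frame(as.list(acc))
      row$epoch <- ep
      if (!is.null(val_samples)) {
        ev <- evaluate_model(function(s)
          student_fw(sp, modality_batch(list(s), modality))$probs,
          val_samples, modality)
        row$val_dice_wt <- ev$report$WT
        row$val_dice_tc <- ev$report$TC
        row$val_dice_et <- ev$report$ET
      }
      log <- rbind(log, row)
    }
    list(student = sp, assistant = ap, log = log,
         teacher_checksum_before = cks_before,
         teacher_checksum_after = param_checksum(teacher))
  })
}

#' Train a task-loss-only baseline student
#'
#' The same student architecture and optimizer, trained on the task loss
#' alone (no teacher, assistant or competition); the no-distillation
#' comparison arm.
#'
#' @inheritParams train_student
#' @return list with `student` and `log`.
#' @export
train_student_baseline <- function(samples, modality, epochs = 40L,
                                   channels = 8L, lr = 0.05, momentum = 0.9,
                                   weight_decay = 1e-4, poly_power = 0.9,
                                   batch_size = 8L, seed = 0L,
                                   val_samples = NULL) {
  n <- length(samples)
  with_seed(seed, {
    sp <- student_init(channels)
    bs <- min(batch_size, n)
    steps_per_epoch <- ceiling(n / bs)
    opt <- sgd_init(sp, lr = lr, momentum = momentum,
                    weight_decay = weight_decay,
                    max_iter = epochs * steps_per_epoch,
                    poly_power = poly_power)
    log <- NULL
    for (ep in seq_len(epochs)) {
      ord <- sample(n)
      ep_loss <- 0
      for (st in seq_len(steps_per_epoch)) {
        idx <- ord[((st - 1L) * bs + 1L):min(st * bs, n)]
        xb <- modality_batch(samples[idx], modality)
        labels <- stack_labels(lapply(samples[idx], `[[`, "label"))
        sf <- student_fw(sp, xb)
        tl <- task_loss(sf$logits, labels)
        sb <- student_bw(sp, sf$cache, task_loss_bw(tl$cache))
        up <- sgd_step(sp, sb$grads, opt)
        sp <- up$params; opt <- up$opt
        ep_loss <- ep_loss + tl$total * length(idx) / n
      }
      row <- data.frame(epoch = ep, L_task = ep_loss)
      if (!is.null(val_samples)) {
        ev <- evaluate_model(function(s)
          student_fw(sp, modality_batch(list(s), modality))$probs,
          val_samples, modality)
        row$val_dice_wt <- ev$report$WT
        row$val_dice_tc <- ev$report$TC
        row$val_dice_et <- ev$report$ET
      }
      log <- rbind(log, row)
    }
    list(student = sp, log = log)
  })
}
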