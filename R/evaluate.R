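# Dice evaluation over the nested BraTS regions.

#' Compose WT/TC/ET region masks from a label map
#'
#' Whole tumor = labels \{1, 2, 4\}, tumor core = \{1, 4\}, enhancing
#' tumor = \{4\}; the three masks are nested by construction.
#'
#' @param label integer matrix/array with values in \{0, 1, 2, 4\}.
#' @return list of logical masks `wt`, `tc`, `et`.
#' @export
region_masks <- function(label) {
  lapply(list(wt = label %in% c(1L, 2L, 4L),
              tc = label %in% c(1L, 4L),
              et = label == 4L),
         function(m) array(m, dim = dim(label)))
}

#' Dice similarity coefficient
#'
#' `2 TP / (2 TP + FP + FN)`. When both masks are empty the score is 1 by
#' default (`empty_value`), the convention documented for this package;
#' set `empty_value = NA` to skip such cases in aggregation.
#'
#' @param pred,truth logical/0-1 masks of identical shape.
#' @param empty_value value returned when both masks are empty.
#' @return Dice score in \[0, 1\] (or `empty_value`).
#' @export
dice <- function(pred, truth, empty_value = 1) {
  if (!identical(dim(pred), dim(truth))) stop("mask shapes differ")
  p <- as.logical(pred); t <- as.logical(truth)
  tp <- sum(p & t)
  fp <- sum(p & !t)
  fn <- sum(!p & t)
  if (tp + fp + fn == 0L) return(empty_value)
  2 * tp / (2 * tp + fp + fn)
}

#' Predicted label map from class probabilities
#'
#' Argmax over the class axis, mapped back to BraTS label values.
#'
#' @param probs `(H, W, 4, N)` probability (or logit) array.
#' @return integer array `(H, W, N)` with values in \{0, 1, 2, 4\}.
#' @export
predict_labels <- function(probs) {
  d <- dim(probs)
  cls <- argmax_channels(probs)
  lut <- c(0L, 1L, 2L, 4L)
  array(lut[cls], dim = c(d[1L], d[2L], d[4L]))
}

#' Per-region Dice for one prediction
#'
#' @param pred_label,true_label label maps with values in \{0, 1, 2, 4\}.
#' @param empty_value both-empty Dice convention (see [dice()]).
#' @return named numeric vector `wt`, `tc`, `et`.
#' @export
region_dice <- function(pred_label, true_label, empty_value = 1) {
  pm <- region_masks(pred_label)
  tm <- region_masks(true_label)
  c(wt = dice(pm$wt, tm$wt, empty_value),
    tc = dice(pm$tc, tm$tc, empty_value),
    et = dice(pm$et, tm$et, empty_value))
}

#' Evaluate a segmentation model on a dataset
#'
#' Runs the forward function slice by slice, computes WT/TC/ET Dice per
#' slice, and reports the per-region means plus their average, in percent.
#'
#' @param forward_fn function taking one `multimodal_sample` and returning
#'   class probabilities `(H, W, 4, 1)`.
#' @param samples list of `multimodal_sample`s.
#' @param modality label recorded in the report row.
#' @param empty_value both-empty Dice convention.
#' @return list with the per-slice `per_case` data frame and a one-row
#'   `report` data frame (`modality`, `WT`, `TC`, `ET`, `Avg`, percent).
#' @export
evaluate_model <- function(forward_fn, samples, modality = "t1",
                           empty_value = 1) {
  if (length(samples) == 0L) stop("empty evaluation set")
  rows <- lapply(samples, function(s) {
    probs <- forward_fn(s)
    pl <- predict_labels(probs)[, , 1L]
    rd <- region_dice(pl, s$label, empty_value)
    data.frame(case_id = s$case_id, wt = rd[["wt"]], tc = rd[["tc"]],
               et = rd[["et"]])
  })
  per_case <- do.call(rbind, rows)
  means <- 100 * colMeans(per_case[, c("wt", "tc", "et")], na.rm = TRUE)
  report <- data.frame(modality = modality,
                       WT = means[["wt"]], TC = means[["tc"]], ET = means[["et"]],
                       Avg = mean(means))
  list(per_case = per_case, report = report)
}
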