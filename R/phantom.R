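# Synthetic multimodal tumor phantoms.
#
# Each phantom is one axial slice with four co-registered MRI contrasts and a
# nested label hierarchy following the BraTS convention: 0 background,
# 1 necrotic/non-enhancing core, 2 peritumoral edema, 4 enhancing core, so
# that whole tumor = {1,2,4} ⊇ tumor core = {1,4} ⊇ enhancing = {4}.
# Contrast roles mirror clinical MRI: the core is salient on T1/T1ce (the
# enhancing rim brightest on T1ce), edema is salient on T2/FLAIR.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Phantom generator configuration
#'
#' @param image_size side length in pixels of the square slice.
#' @param tumor_radius_range ordered pair: semi-axis range (pixels) of the
#'   solid tumor ellipse. `c(0, 0)` disables the tumor entirely.
#' @param edema_margin_range ordered pair: width (pixels) of the edema ring
#'   added around the solid tumor.
#' @param core_fraction_range ordered pair in (0, 1): tumor-core semi-axes as
#'   a fraction of the solid tumor's.
#' @param enhancing_fraction_range ordered pair in (0, 1): enhancing-core
#'   semi-axes as a fraction of the core's.
#' @param noise_sigma standard deviation of the additive Gaussian intensity
#'   noise (image units on \[0, 1\]).
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(image_size = 160L,
                           tumor_radius_range = c(15, 40),
                           edema_margin_range = c(5, 15),
                           core_fraction_range = c(0.45, 0.7),
                           enhancing_fraction_range = c(0.4, 0.7),
                           noise_sigma = 0.03) {
  chk_pair <- function(p, nm, lo = 0) {
    if (length(p) != 2L || any(!is.finite(p)) || p[1L] > p[2L] || p[1L] < lo)
      stop(sprintf("invalid %s: must be an ordered pair with lower bound >= %g", nm, lo))
  }
  if (image_size < 32L) stop("image_size must be at least 32")
  chk_pair(tumor_radius_range, "tumor_radius_range")
  chk_pair(edema_margin_range, "edema_margin_range")
  chk_pair(core_fraction_range, "core_fraction_range")
  chk_pair(enhancing_fraction_range, "enhancing_fraction_range")
  if (core_fraction_range[2L] >= 1 || enhancing_fraction_range[2L] >= 1)
    stop("fraction ranges must lie strictly inside (0, 1)")
  if (noise_sigma < 0) stop("noise_sigma must be nonnegative")
  structure(list(image_size = as.integer(image_size),
                 tumor_radius_range = tumor_radius_range,
                 edema_margin_range = edema_margin_range,
                 core_fraction_range = core_fraction_range,
                 enhancing_fraction_range = enhancing_fraction_range,
                 noise_sigma = noise_sigma),
            class = "phantom_config")
}

ellipse_mask <- function(S, cx, cy, a, b, theta) {
  if (a <= 0 || b <= 0) return(matrix(FALSE, S, S))
  x <- matrix(rep(seq_len(S), S), S) - cx        # row coordinate
  y <- matrix(rep(seq_len(S), each = S), S) - cy # column coordinate
  u <- cos(theta) * x + sin(theta) * y
  v <- -sin(theta) * x + cos(theta) * y
  (u / a)^2 + (v / b)^2 <= 1
}

# Mean tissue intensities per modality (background brain, edema, non-enhancing
# core, enhancing core). Chosen so that tumor core is salient on T1/T1ce and
# edema on T2/FLAIR.
# Edema is nearly iso-intense with brain on T1/T1ce (it is a T2/FLAIR
# finding), which is what makes the single-modality problem genuinely
# partial: a T1-only network cannot read the edema extent directly.
.phantom_levels <- list(
  t1    = c(bg = 0.35, edema = 0.36, core = 0.55, enh = 0.60),
  t1ce  = c(bg = 0.35, edema = 0.37, core = 0.50, enh = 0.85),
  t2    = c(bg = 0.25, edema = 0.75, core = 0.55, enh = 0.50),
  flair = c(bg = 0.30, edema = 0.85, core = 0.55, enh = 0.50)
)

#' Generate one synthetic multimodal phantom slice
#'
#' Draws an elliptical tumor with randomized eccentricity, rotation and
#' off-center placement, surrounds it with an edema ring and nests a tumor
#' core and an enhancing core inside it, then renders the four MRI contrasts
#' with modality-specific tissue intensities plus Gaussian noise. The result
#' is deterministic for a fixed seed.
#'
#' @param config a [phantom_config()].
#' @param seed integer seed controlling all randomness.
#' @param case_id case identifier stored in the sample.
#' @param slice_index slice index stored in the sample.
#' @return a `multimodal_sample`: list with matrices `t1`, `t1ce`, `t2`,
#'   `flair` (values in \[0, 1\]), integer matrix `label` (values in
#'   \{0, 1, 2, 4\}), plus `case_id` and `slice_index`.
#' @export
generate_phantom <- function(config = phantom_config(), seed = 1L,
                             case_id = sprintf("phantom_%04d", seed),
                             slice_index = 0L) {
  stopifnot(inherits(config, "phantom_config"))
  S <- config$image_size
  with_seed(seed, {
    rr <- config$tumor_radius_range
    tumor_on <- rr[2L] > 0
    if (tumor_on) {
      a <- runif(1, rr[1L], rr[2L])
      b <- runif(1, rr[1L], rr[2L])
      m <- runif(1, config$edema_margin_range[1L], config$edema_margin_range[2L])
      cf <- runif(1, config$core_fraction_range[1L], config$core_fraction_range[2L])
      ef <- runif(1, config$enhancing_fraction_range[1L], config$enhancing_fraction_range[2L])
      theta <- runif(1, 0, pi)
      # scale the lesion down if it cannot fit inside the slice
      lim <- max(a, b) + m
      max_lim <- min(S * 0.35, (S - 6) / 2)
      if (lim > max_lim) {
        sc <- max_lim / lim
        a <- a * sc; b <- b * sc; m <- m * sc
        lim <- max_lim
      }
      cx <- runif(1, lim + 2, S - lim - 1)
      cy <- runif(1, lim + 2, S - lim - 1)
      whole <- ellipse_mask(S, cx, cy, a + m, b + m, theta)
      core <- ellipse_mask(S, cx, cy, a * cf, b * cf, theta)
      enh <- ellipse_mask(S, cx, cy, a * cf * ef, b * cf * ef, theta)
      core <- core & whole
      enh <- enh & core
    } else {
      whole <- core <- enh <- matrix(FALSE, S, S)
    }
    label <- matrix(0L, S, S)
    label[whole] <- 2L
    label[core] <- 1L
    label[enh] <- 4L

    brain <- ellipse_mask(S, S / 2 + 0.5, S / 2 + 0.5, S * 0.47, S * 0.43, 0)
    mods <- lapply(.phantom_levels, function(lv) {
      img <- matrix(0.02, S, S)
      img[brain] <- lv[["bg"]]
      img[whole] <- lv[["edema"]]
      img[core] <- lv[["core"]]
      img[enh] <- lv[["enh"]]
      if (config$noise_sigma > 0)
        img <- img + matrix(rnorm(S * S, sd = config$noise_sigma), S, S)
      pmin(pmax(img, 0), 1)
    })
    structure(list(t1 = mods$t1, t1ce = mods$t1ce, t2 = mods$t2,
                   flair = mods$flair, label = label,
                   case_id = case_id, slice_index = as.integer(slice_index)),
              class = "multimodal_sample")
  })
}

#' Validate a multimodal sample
#'
#' Checks the shared-shape, value-range and label-alphabet invariants.
#'
#' @param sample a `multimodal_sample`.
#' @return the sample, invisibly; errors if an invariant is violated.
#' @export
validate_sample <- function(sample) {
  mods <- c("t1", "t1ce", "t2", "flair")
  d <- dim(sample$label)
  for (m in mods) {
    if (!identical(dim(sample[[m]]), d)) stop("modality ", m, " shape mismatch")
    if (any(sample[[m]] < 0 | sample[[m]] > 1)) stop("modality ", m, " outside [0,1]")
  }
  if (!all(sample$label %in% c(0L, 1L, 2L, 4L))) stop("label values outside {0,1,2,4}")
  invisible(sample)
}

#' Generate a phantom dataset
#'
#' @param n_cases number of cases; each case contributes one slice.
#' @param config a [phantom_config()].
#' @param seed base seed; case `i` uses `seed + i`.
#' @return list of `multimodal_sample`s with ids `case_0001`, ...
#' @export
generate_phantom_dataset <- function(n_cases, config = phantom_config(), seed = 1L) {
  lapply(seq_len(n_cases), function(i)
    generate_phantom(config, seed = seed + i, case_id = sprintf("case_%04d", i)))
}

#' Split case ids into train/validation/test
#'
#' Deterministic shuffled 80/10/10 partition.
#'
#' @param case_ids character vector of at least 10 unique ids.
#' @param seed shuffle seed.
#' @param fractions train/val/test fractions summing to 1.
#' @return list with `train`, `val`, `test` character vectors.
#' @export
split_cases <- function(case_ids, seed = 1L, fractions = c(0.8, 0.1, 0.1)) {
  if (length(case_ids) < 10L) stop("need at least 10 cases to split")
  if (anyDuplicated(case_ids)) stop("case_ids must be unique")
  stopifnot(abs(sum(fractions) - 1) < 1e-9)
  n <- length(case_ids)
  ids <- with_seed(seed, sample(case_ids))
  n_train <- round(fractions[1L] * n)
  n_val <- max(1L, round(fractions[2L] * n))
  list(train = ids[seq_len(n_train)],
       val = ids[n_train + seq_len(n_val)],
       test = ids[(n_train + n_val + 1L):n])
}

#' Linear contrast/brightness enhancement
#'
#' `clip(gain * image + bias, 0, 1)`. The defaults are the identity, so the
#' step is opt-in and fully reversible from its parameters.
#'
#' @param image matrix with values in \[0, 1\].
#' @param gain multiplicative contrast factor.
#' @param bias additive brightness offset.
#' @return enhanced image, clipped to \[0, 1\].
#' @export
enhance_contrast_brightness <- function(image, gain = 1, bias = 0) {
  pmin(pmax(gain * image + bias, 0), 1)
}
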