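test_that("phantoms satisfy the shape, range and label contracts", {
  s <- generate_phantom(phantom_config(image_size = 64), seed = 7)
  validate_sample(s)
  expect_identical(dim(s$t1), c(64L, 64L))
  expect_identical(dim(s$label), c(64L, 64L))
  expect_true(all(s$label %in% c(0L, 1L, 2L, 4L)))
  for (m in c("t1", "t1ce", "t2", "flair"))
    expect_true(all(s[[m]] >= 0 & s[[m]] <= 1))
})

test_that("phantom generation is deterministic for a fixed seed", {
  cfg <- phantom_config(image_size = 48)
  a <- generate_phantom(cfg, seed = 7)
  b <- generate_phantom(cfg, seed = 7)
  expect_identical(a, b)
  c <- generate_phantom(cfg, seed = 8)
  expect_false(identical(a$label, c$label))
})

test_that("a zero tumor radius disables the lesion entirely", {
  cfg <- phantom_config(image_size = 48, tumor_radius_range = c(0, 0))
  s <- generate_phantom(cfg, seed = 3)
  expect_true(all(s$label == 0L))
  # background-only intensities: no pixel carries a lesion level
  expect_true(all(abs(s$t1ce - 0.85) > 0.05))
})

test_that("label regions are nested: enhancing within core within whole tumor", {
  for (seed in 1:10) {
    s <- generate_phantom(phantom_config(image_size = 48), seed = seed)
    m <- region_masks(s$label)
    expect_true(all(m$et <= m$tc))
    expect_true(all(m$tc <= m$wt))
    expect_gt(sum(m$et), 0)
  }
})

test_that("modality contrast roles hold: core salient in T1ce, edema in FLAIR", {
  for (seed in 1:5) {
    s <- generate_phantom(phantom_config(image_size = 64), seed = seed)
    m <- region_masks(s$label)
    bg <- !m$wt
    expect_gt(mean(s$t1ce[m$tc]), mean(s$t1ce[bg]))
    expect_gt(mean(s$flair[s$label == 2L]), mean(s$flair[bg]))
    expect_gt(mean(s$t2[s$label == 2L]), mean(s$t2[bg]))
  }
})

test_that("invalid phantom configurations are rejected", {
  expect_error(phantom_config(image_size = 16), "at least 32")
  expect_error(phantom_config(tumor_radius_range = c(10, 5)), "ordered pair")
  expect_error(phantom_config(core_fraction_range = c(0.5, 1.2)), "inside")
  expect_error(phantom_config(noise_sigma = -1), "nonnegative")
})

test_that("split_cases yields deterministic disjoint 80/10/10 partitions", {
  ids <- sprintf("case_%03d", 1:100)
  sp <- split_cases(ids, seed = 5)
  expect_length(sp$train, 80)
  expect_length(sp$val, 10)
  expect_length(sp$test, 10)
  expect_setequal(c(sp$train, sp$val, sp$test), ids)
  expect_length(intersect(sp$train, sp$val), 0)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(sp, split_cases(ids, seed = 5))

  sp10 <- split_cases(sprintf("c%02d", 1:10), seed = 1)
  expect_equal(lengths(sp10), c(train = 8L, val = 1L, test = 1L))
  expect_error(split_cases(sprintf("c%d", 1:9)), "at least 10")
})

test_that("contrast/brightness enhancement is a clipped linear map", {
  img <- matrix(seq(0, 1, length.out = 25), 5)
  expect_identical(enhance_contrast_brightness(img), img)
  expect_equal(enhance_contrast_brightness(matrix(0.5, 2, 2), gain = 2),
               matrix(1, 2, 2))
  expect_equal(enhance_contrast_brightness(img, 1.2, 0.05),
               pmin(pmax(1.2 * img + 0.05, 0), 1))
})

test_that("NIfTI round-trip reproduces a phantom within float tolerance", {
  s <- generate_phantom(phantom_config(image_size = 48), seed = 11)
  dir <- file.path(tempdir(), "case_rt")
  write_phantom_nifti(s, dir, config = phantom_config(image_size = 48), seed = 11)
  r <- read_phantom_nifti(dir)
  for (m in c("t1", "t1ce", "t2", "flair"))
    expect_lt(max(abs(r[[m]] - s[[m]])), 1e-6)
  expect_identical(r$label, s$label)
  unlink(dir, recursive = TRUE)
})

test_that("BraTS slice loading crops, normalizes and guards degenerate slices", {
  dir <- file.path(tempdir(), "brats_fix")
  dir.create(dir, showWarnings = FALSE)
  set.seed(21)
  vol <- array(runif(40 * 40 * 5, 0, 1000), dim = c(40, 40, 5))
  const <- array(7, dim = c(40, 40, 5))
  lab <- array(sample(c(0L, 1L, 2L, 4L), 40 * 40 * 5, TRUE), dim = c(40, 40, 5))
  paths <- list()
  for (m in c("t1", "t1ce", "t2", "flair")) {
    paths[[m]] <- file.path(dir, paste0(m, ".nii.gz"))
    RNifti::writeNifti(if (m == "t2") const else vol, paths[[m]])
  }
  labp <- file.path(dir, "seg.nii.gz")
  RNifti::writeNifti(lab, labp)

  s <- load_brats_slice(paths, labp, slice_index = 3, crop_size = 32)
  expect_identical(dim(s$t1), c(32L, 32L))
  expect_true(all(s$t1 >= 0 & s$t1 <= 1))
  # constant modality maps to zeros (min == max guard)
  expect_true(all(s$t2 == 0))
  # crop window equals direct index arithmetic
  sl <- vol[, , 3]
  win <- sl[5:36, 5:36]
  expect_equal(s$t1, (win - min(win)) / (max(win) - min(win)))
  expect_identical(s$label, lab[5:36, 5:36, 3])
  expect_error(load_brats_slice(paths, labp, slice_index = 9), "out of range")
  unlink(dir, recursive = TRUE)
})
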