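# BraTS-style NIfTI input and phantom round-trip IO.

center_crop_window <- function(n, size) {
  if (size > n) stop("crop size larger than image extent")
  start <- (n - size) %/% 2L + 1L
  start:(start + size - 1L)
}

#' Center-crop a matrix
#'
#' @param m matrix.
#' @param size side length of the square crop.
#' @return list with the cropped `image` and the 1-based `origin` (row, col)
#'   of the crop window.
#' @export
center_crop <- function(m, size) {
  ri <- center_crop_window(nrow(m), size)
  ci <- center_crop_window(ncol(m), size)
  list(image = m[ri, ci, drop = FALSE], origin = c(ri[1L], ci[1L]))
}

#' Min-max normalize to \[0, 1\]
#'
#' Constant images (min == max) map to all zeros.
#'
#' @param m numeric matrix.
#' @return normalized matrix.
#' @export
minmax_normalize <- function(m) {
  lo <- min(m); hi <- max(m)
  if (hi - lo <= 0) return(m * 0)
  (m - lo) / (hi - lo)
}

#' Load one axial slice from BraTS-style NIfTI volumes
#'
#' Extracts slice `slice_index` from each modality volume and the label
#' volume, center-crops to `crop_size` and min-max normalizes each modality
#' to \[0, 1\]; the label passes through unchanged (as integers).
#'
#' @param volume_paths named character vector/list with entries `t1`, `t1ce`,
#'   `t2`, `flair` pointing to NIfTI files.
#' @param label_path path to the label NIfTI.
#' @param slice_index 1-based axial slice index.
#' @param crop_size side length of the center crop (default 160).
#' @param gain,bias optional linear contrast/brightness enhancement applied
#'   after normalization (defaults are the identity).
#' @return a `multimodal_sample` with attribute `crop_origin`.
#' @export
load_brats_slice <- function(volume_paths, label_path, slice_index,
                             crop_size = 160L, gain = 1, bias = 0) {
  mods <- c("t1", "t1ce", "t2", "flair")
  if (!all(mods %in% names(volume_paths))) stop("volume_paths must name t1, t1ce, t2, flair")
  vols <- lapply(mods, function(m) RNifti::readNifti(volume_paths[[m]]))
  names(vols) <- mods
  lab <- RNifti::readNifti(label_path)
  d <- dim(vols$t1)
  for (m in mods) if (!identical(dim(vols[[m]]), d)) stop("modality volume shapes disagree")
  if (!identical(dim(lab)[1:2], d[1:2])) stop("label shape disagrees with modalities")
  nz <- if (length(d) >= 3L) d[3L] else 1L
  if (slice_index < 1L || slice_index > nz) stop("slice_index out of range [1, ", nz, "]")
  take <- function(v) {
    m <- if (length(dim(v)) >= 3L) v[, , slice_index] else v[, ]
    matrix(as.vector(m), nrow(m)) # drop NIfTI attributes
  }
  origin <- NULL
  imgs <- lapply(vols, function(v) {
    cr <- center_crop(take(v), crop_size)
    origin <<- cr$origin
    enhance_contrast_brightness(minmax_normalize(cr$image), gain, bias)
  })
  lab2 <- center_crop(take(lab), crop_size)$image
  storage.mode(lab2) <- "integer"
  out <- structure(list(t1 = imgs$t1, t1ce = imgs$t1ce, t2 = imgs$t2,
                        flair = imgs$flair, label = lab2,
                        case_id = basename(dirname(label_path)),
                        slice_index = as.integer(slice_index)),
                   class = "multimodal_sample")
  attr(out, "crop_origin") <- origin
  out
}

#' Write a phantom case as NIfTI volumes plus a JSON manifest
#'
#' @param sample a `multimodal_sample`.
#' @param dir output directory for this case (created if needed).
#' @param config optional [phantom_config()] echoed into the manifest.
#' @param seed optional seed echoed into the manifest.
#' @return the case directory, invisibly.
#' @export
write_phantom_nifti <- function(sample, dir, config = NULL, seed = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (m in c("t1", "t1ce", "t2", "flair")) {
    v <- sample[[m]]
    dim(v) <- c(dim(v), 1L)
    RNifti::writeNifti(v, file.path(dir, paste0(m, ".nii.gz")))
  }
  lab <- sample$label
  dim(lab) <- c(dim(lab), 1L)
  RNifti::writeNifti(lab, file.path(dir, "seg.nii.gz"))
  manifest <- list(case_id = sample$case_id, slice_index = sample$slice_index,
                   seed = seed, config = unclass(config))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(dir)
}

#' Read back a phantom case written by [write_phantom_nifti()]
#'
#' Values are read verbatim (phantoms are already normalized), so a
#' write/read round-trip reproduces the sample to float precision.
#'
#' @param dir case directory.
#' @return a `multimodal_sample`.
#' @export
read_phantom_nifti <- function(dir) {
  rd <- function(f) {
    v <- as.array(RNifti::readNifti(file.path(dir, f)))
    if (length(dim(v)) == 3L) v <- v[, , 1L]
    matrix(as.vector(v), nrow(v)) # drop NIfTI attributes
  }
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  lab <- rd("seg.nii.gz")
  storage.mode(lab) <- "integer"
  structure(list(t1 = rd("t1.nii.gz"), t1ce = rd("t1ce.nii.gz"),
                 t2 = rd("t2.nii.gz"), flair = rd("flair.nii.gz"),
                 label = lab,
                 case_id = manifest$case_id %||% basename(dir),
                 slice_index = as.integer(manifest$slice_index %||% 0L)),
            class = "multimodal_sample")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
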