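## Data model and I/O for 3D volumes and masks. Volumes are rank-3
## intensity grids with per-axis physical spacing in mm; masks and
## probability maps live on the same grid. NIfTI-1 (.nii/.nii.gz) is read
## and written through RNifti; NRRD through the bundled reader (see nrrd.R).

#' Construct a 3D volume
#'
#' @param data Numeric 3D array (H x W x Z). Axis convention: the first two
#'   axes span the in-plane (IJ, axial) slice, the third indexes slices.
#' @param spacing Positive voxel spacing in mm along each axis.
#' @param source_id Free-text provenance tag.
#' @return A `volume3d` object.
#' @export
volume3d <- function(data, spacing = c(1, 1, 1), source_id = "") {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("volume payload must be rank-3, got rank ", length(dim(data)))
  if (any(dim(data) < 1L)) stop("all dimensions must be >= 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive reals (mm)")
  if (any(!is.finite(data))) stop("volume intensities must be finite")
  structure(list(data = data, spacing = spacing, source_id = source_id),
            class = "volume3d")
}

#' Construct a binary label mask
#'
#' @param data 3D array with values exactly in \{0, 1\}.
#' @param spacing Voxel spacing in mm.
#' @return A `label_mask` object.
#' @export
label_mask <- function(data, spacing = c(1, 1, 1)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("mask must be rank-3")
  if (!all(data %in% c(0, 1))) stop("mask values must be exactly 0 or 1")
  structure(list(data = array(as.integer(data), dim(data)),
                 spacing = as.numeric(spacing)),
            class = "label_mask")
}

#' Construct a probability map
#'
#' @param data 3D array with values in \[0, 1\].
#' @param spacing Voxel spacing in mm.
#' @return A `probability_map` object.
#' @export
probability_map <- function(data, spacing = c(1, 1, 1)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("probability map must be rank-3")
  if (any(!is.finite(data)) || any(data < 0) || any(data > 1))
    stop("probability values must lie in [0, 1]")
  structure(list(data = data, spacing = as.numeric(spacing)),
            class = "probability_map")
}

## Accept a label_mask, volume3d or plain array; return a validated binary
## 3D array.
mask_data <- function(x) {
  d <- if (inherits(x, c("label_mask", "volume3d"))) x$data else as.array(x)
  if (!all(d %in% c(0, 1))) stop("mask values must be exactly 0 or 1")
  d
}

vol_data <- function(x) if (inherits(x, "volume3d")) x$data else as.array(x)

#' Read a volume from NIfTI or NRRD
#'
#' @param path Path to a `.nii`, `.nii.gz` or `.nrrd` file.
#' @param nan One of `"error"` (default: non-finite voxels abort) or
#'   `"zero"` (replace with 0, with a warning).
#' @return A [volume3d()] with spacing taken from the file header.
#' @export
read_volume <- function(path, nan = c("error", "zero")) {
  nan <- match.arg(nan)
  if (!file.exists(path)) stop("no such file: ", path)
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    img <- RNifti::readNifti(path)
    data <- array(as.numeric(img), dim(img))  # strip image attributes
    spacing <- abs(RNifti::pixdim(img))
  } else if (grepl("\\.nrrd$", lower)) {
    nr <- read_nrrd(path)
    data <- nr$data
    spacing <- nr$spacing
  } else {
    stop("unsupported volume format (expect .nii, .nii.gz or .nrrd): ", path)
  }
  if (length(dim(data)) == 4L && dim(data)[4] == 1L)
    data <- array(data, dim(data)[1:3])
  if (length(dim(data)) != 3L)
    stop("expected a 3D payload, got rank ", length(dim(data)), " in ", path)
  if (any(!is.finite(data))) {
    if (nan == "error") stop("non-finite voxel intensities in ", path)
    warning("non-finite voxels replaced by 0 in ", path)
    data[!is.finite(data)] <- 0
  }
  volume3d(data, spacing = spacing[1:3], source_id = basename(path))
}

#' Write a volume to NIfTI or NRRD
#'
#' @param vol A [volume3d()] (or 3D array, spacing 1 mm).
#' @param path Output path; format chosen by extension.
#' @export
write_volume <- function(vol, path) {
  if (!inherits(vol, "volume3d")) vol <- volume3d(vol)
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    img <- RNifti::asNifti(vol$data)
    RNifti::pixdim(img) <- vol$spacing
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.nrrd$", lower)) {
    write_nrrd(vol$data, path, spacing = vol$spacing)
  } else {
    stop("unsupported volume format: ", path)
  }
  invisible(path)
}

#' Write a binary mask aligned to a reference volume
#'
#' @param mask A [label_mask()] or binary array.
#' @param ref The reference [volume3d()] providing grid and spacing.
#' @param path Output path (`.nii`, `.nii.gz` or `.nrrd`).
#' @export
write_mask <- function(mask, ref, path) {
  m <- mask_data(mask)
  if (!identical(dim(m), dim(vol_data(ref))))
    stop("mask shape ", paste(dim(m), collapse = "x"),
         " does not match reference ",
         paste(dim(vol_data(ref)), collapse = "x"))
  spacing <- if (inherits(ref, "volume3d")) ref$spacing else c(1, 1, 1)
  write_volume(volume3d(m * 1.0, spacing = spacing), path)
}

#' Pad a volume so every dimension is a multiple of `multiple`
#'
#' Padding is appended on the high side of each axis and filled with the
#' volume's minimum intensity (an approximation of MRI background). The
#' returned record inverts the padding exactly via [crop_by_record()].
#'
#' @param vol A [volume3d()] or 3D array.
#' @param multiple Positive integer; the network needs 16.
#' @param fill Padding value; default the volume minimum.
#' @return List with `vol` (padded) and `record` (a `pad_record`).
#' @export
pad_to_multiple <- function(vol, multiple = 16L, fill = NULL) {
  is_vol <- inherits(vol, "volume3d")
  x <- vol_data(vol)
  d <- dim(x)
  target <- as.integer(ceiling(d / multiple) * multiple)
  if (is.null(fill)) fill <- min(x)
  out <- array(fill, target)
  out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- x
  record <- structure(list(original_shape = d,
                           pad_lo = c(0L, 0L, 0L),
                           pad_hi = target - d),
                      class = "pad_record")
  padded <- if (is_vol) volume3d(out, vol$spacing, vol$source_id) else out
  list(vol = padded, record = record)
}

#' Crop a padded grid back to its original shape
#'
#' @param x Padded [volume3d()] or array.
#' @param record The `pad_record` from [pad_to_multiple()].
#' @return Object of the original shape.
#' @export
crop_by_record <- function(x, record) {
  is_vol <- inherits(x, "volume3d")
  a <- vol_data(x)
  d <- record$original_shape
  lo <- record$pad_lo
  out <- a[lo[1] + seq_len(d[1]), lo[2] + seq_len(d[2]), lo[3] + seq_len(d[3]),
           drop = FALSE]
  if (is_vol) volume3d(out, x$spacing, x$source_id) else out
}

#' Per-volume z-score intensity normalization
#'
#' @param vol A [volume3d()] or array.
#' @return Same type, intensities with mean 0 and SD 1.
#' @export
normalize_volume <- function(vol) {
  x <- vol_data(vol)
  s <- stats::sd(as.numeric(x))
  if (s == 0) s <- 1
  out <- (x - mean(x)) / s
  if (inherits(vol, "volume3d")) volume3d(out, vol$spacing, vol$source_id)
  else out
}
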