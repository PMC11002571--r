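## Training-time augmentation: a random in-plane (IJ, axial) affine
## transform -- scaling, rotation and translation about the slice centre --
## applied with 50% probability. One parameter draw per scan, applied
## identically to every slice so the stack stays coherent; images are
## resampled bilinearly, masks by nearest neighbour.

#' Augmentation configuration
#'
#' @param prob Probability that a transform is applied at all.
#' @param scale_range,angle_range,shift_range Open sampling intervals for
#'   the scale factor, rotation angle (degrees) and per-axis translation
#'   (pixels).
#' @return An `augment_config` list.
#' @export
augment_config <- function(prob = 0.5, scale_range = c(0.5, 1.5),
                           angle_range = c(-25, 25), shift_range = c(-10, 10)) {
  stopifnot(prob >= 0, prob <= 1, scale_range[1] < scale_range[2],
            angle_range[1] < angle_range[2], shift_range[1] < shift_range[2])
  structure(list(prob = prob, scale_range = scale_range,
                 angle_range = angle_range, shift_range = shift_range),
            class = "augment_config")
}

#' Draw in-plane affine parameters
#'
#' With probability `cfg$prob` draws scale, angle and shifts uniformly from
#' the configured intervals; otherwise returns the identity (`applied =
#' FALSE`). Uses the current R random stream.
#'
#' @param cfg An [augment_config()].
#' @return An `affine_params` list: `applied`, `scale`, `angle`, `shift`.
#' @export
sample_affine <- function(cfg = augment_config()) {
  if (stats::runif(1) >= cfg$prob) {
    return(structure(list(applied = FALSE, scale = 1, angle = 0,
                          shift = c(0, 0)), class = "affine_params"))
  }
  structure(list(
    applied = TRUE,
    scale = stats::runif(1, cfg$scale_range[1], cfg$scale_range[2]),
    angle = stats::runif(1, cfg$angle_range[1], cfg$angle_range[2]),
    shift = stats::runif(2, cfg$shift_range[1], cfg$shift_range[2])
  ), class = "affine_params")
}

#' Apply one in-plane affine to a volume/mask pair
#'
#' The forward map of a point p in the IJ plane is
#' `p' = s * R(angle) (p - c) + c + t` about the slice centre c; voxels are
#' resampled through the inverse map, the image bilinearly and the mask by
#' nearest neighbour, slice by slice with shared parameters. Out-of-field
#' image voxels are filled with the volume minimum, mask voxels with 0.
#'
#' @param vol 3D intensity array (or [volume3d()]).
#' @param mask Binary 3D array (or [label_mask()]) on the same grid; may be
#'   `NULL`.
#' @param par An `affine_params` from [sample_affine()].
#' @return List with transformed `vol` and `mask` (plain arrays).
#' @export
apply_inplane_affine <- function(vol, mask, par) {
  x <- vol_data(vol)
  m <- if (is.null(mask)) NULL else mask_data(mask)
  if (!is.null(m) && !identical(dim(x), dim(m)))
    stop("volume and mask are not aligned")
  if (!par$applied) return(list(vol = x, mask = m))
  d <- dim(x)
  H <- d[1]; W <- d[2]; Z <- d[3]
  ci <- (H + 1) / 2
  cj <- (W + 1) / 2
  th <- par$angle * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  ## inverse map: p = R^T ((p' - c - t)) / s + c
  gi <- rep.int(seq_len(H), W)
  gj <- rep(seq_len(W), each = H)
  pi_ <- gi - ci - par$shift[1]
  pj_ <- gj - cj - par$shift[2]
  si <- (R[1, 1] * pi_ + R[2, 1] * pj_) / par$scale + ci
  sj <- (R[1, 2] * pi_ + R[2, 2] * pj_) / par$scale + cj

  fill <- min(x)
  i0 <- floor(si); j0 <- floor(sj)
  fi <- si - i0; fj <- sj - j0
  inb <- function(i, j) i >= 1 & i <= H & j >= 1 & j <= W
  gather <- function(slice, i, j, fill) {
    ok <- inb(i, j)
    v <- rep(fill, length(i))
    v[ok] <- slice[cbind(i[ok], j[ok])]
    v
  }
  vout <- array(fill, d)
  mout <- if (is.null(m)) NULL else array(0L, d)
  ri <- round(si); rj <- round(sj)
  for (z in seq_len(Z)) {
    sl <- x[, , z]
    v00 <- gather(sl, i0, j0, fill)
    v10 <- gather(sl, i0 + 1, j0, fill)
    v01 <- gather(sl, i0, j0 + 1, fill)
    v11 <- gather(sl, i0 + 1, j0 + 1, fill)
    vout[, , z] <- (1 - fi) * (1 - fj) * v00 + fi * (1 - fj) * v10 +
      (1 - fi) * fj * v01 + fi * fj * v11
    if (!is.null(m)) mout[, , z] <- as.integer(gather(m[, , z], ri, rj, 0L))
  }
  list(vol = vout, mask = mout)
}
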