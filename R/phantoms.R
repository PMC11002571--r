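## Seeded synthetic phantoms emulating atrial LGE scans: an ellipsoidal
## body with a few curved tubular appendages (pulmonary-vein-like) and an
## optional extra lobe, rendered at low foreground/background contrast
## with Gaussian noise. The generator reproduces the segmentation
## challenges of the clinical data -- small foreground fraction, indistinct
## boundaries, elongated thin structures, shape variability -- without
## claiming anatomical fidelity.

#' Phantom specification
#'
#' @param grid_shape Grid dims (default 64 x 64 x 32).
#' @param spacing Voxel spacing in mm (default 1.25 x 1.25 x 2.5, the
#'   acquisition resolution of the public atrial challenge data).
#' @param body_a,body_b,body_c Ranges (voxels) of the ellipsoid semi-axes.
#' @param n_tubes Range of the number of tubular appendages.
#' @param tube_radius,tube_length Ranges (voxels) of tube radius and length.
#' @param appendage Add an extra small lobe.
#' @param contrast Foreground-background mean intensity gap, in units of
#'   the noise SD. The low default makes boundaries indistinct.
#' @param noise_sd Additive Gaussian noise SD.
#' @param smooth_sigma Gaussian blur width (voxels) applied to the clean
#'   foreground signal before noise, softening boundaries.
#' @param fg_fraction Admissible bounds on the foreground voxel fraction
#'   (class imbalance); shapes are redrawn until satisfied.
#' @param max_retries Redraw budget before giving up.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 32L),
                         spacing = c(1.25, 1.25, 2.5),
                         body_a = c(8, 14), body_b = c(7, 12), body_c = c(4, 7),
                         n_tubes = c(2L, 4L),
                         tube_radius = c(1.0, 1.8), tube_length = c(8, 16),
                         appendage = TRUE,
                         contrast = 1.5, noise_sd = 1.0, smooth_sigma = 1.0,
                         fg_fraction = c(0.005, 0.05), max_retries = 25L) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 16),
            contrast >= 0, noise_sd >= 0,
            fg_fraction[1] > 0, fg_fraction[2] < 1,
            fg_fraction[1] < fg_fraction[2])
  structure(as.list(environment()), class = "phantom_spec")
}

arr_shift <- function(x, s, axis) {
  d <- dim(x)
  out <- array(0, d)
  n <- d[axis]
  if (abs(s) >= n) return(out)
  src <- if (s >= 0) 1:(n - s) else (1 - s):n
  dst <- if (s >= 0) (1 + s):n else 1:(n + s)
  ix_src <- list(1:d[1], 1:d[2], 1:d[3])
  ix_dst <- ix_src
  ix_src[[axis]] <- src
  ix_dst[[axis]] <- dst
  out[ix_dst[[1]], ix_dst[[2]], ix_dst[[3]]] <-
    x[ix_src[[1]], ix_src[[2]], ix_src[[3]]]
  out
}

## Separable Gaussian blur with edge renormalization.
gaussian_blur3 <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  w <- stats::dnorm(-r:r, sd = sigma)
  w <- w / sum(w)
  blur1 <- function(a) {
    for (axis in 1:3) {
      acc <- array(0, dim(a))
      for (m in -r:r) acc <- acc + w[m + r + 1] * arr_shift(a, m, axis)
      a <- acc
    }
    a
  }
  blur1(x) / blur1(array(1, dim(x)))
}

## Unit vector, mostly in-plane (tilt limited so tubes stay thin and long
## within the anisotropic grid).
rand_dir <- function() {
  phi <- stats::runif(1, 0, 2 * pi)
  tilt <- stats::runif(1, -pi / 6, pi / 6)
  c(cos(phi) * cos(tilt), sin(phi) * cos(tilt), sin(tilt))
}

## Scalar t so that centre + t * u lies on the ellipsoid surface.
ellipsoid_reach <- function(u, axes) 1 / sqrt(sum((u / axes)^2))

stamp_ball <- function(mask, centre, radius, d) {
  lo <- pmax(1L, floor(centre - radius))
  hi <- pmin(d, ceiling(centre + radius))
  if (any(lo > hi)) return(mask)
  ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
  di2 <- (ii - centre[1])^2
  dj2 <- (jj - centre[2])^2
  dk2 <- (kk - centre[3])^2
  sub <- outer(outer(di2, dj2, `+`), dk2, `+`) <= radius^2
  mask[ii, jj, kk] <- mask[ii, jj, kk] | sub
  mask
}

draw_phantom_mask <- function(spec) {
  d <- spec$grid_shape
  ctr <- d / 2 + stats::runif(3, -3, 3)
  axes <- c(stats::runif(1, spec$body_a[1], spec$body_a[2]),
            stats::runif(1, spec$body_b[1], spec$body_b[2]),
            stats::runif(1, spec$body_c[1], spec$body_c[2]))
  gi <- seq_len(d[1]); gj <- seq_len(d[2]); gk <- seq_len(d[3])
  e <- outer(outer(((gi - ctr[1]) / axes[1])^2, ((gj - ctr[2]) / axes[2])^2, `+`),
             ((gk - ctr[3]) / axes[3])^2, `+`) <= 1
  mask <- e
  body_only <- e

  nt <- sample(spec$n_tubes[1]:spec$n_tubes[2], 1)
  for (t in seq_len(nt)) {
    u <- rand_dir()
    pos <- ctr + 0.85 * ellipsoid_reach(u, axes) * u
    r <- stats::runif(1, spec$tube_radius[1], spec$tube_radius[2])
    len <- stats::runif(1, spec$tube_length[1], spec$tube_length[2])
    nstep <- ceiling(len / 0.5)
    for (s in seq_len(nstep)) {
      mask <- stamp_ball(mask, pos, r, d)
      u <- u + stats::rnorm(3, sd = 0.08)   # gentle random curvature
      u <- u / sqrt(sum(u^2))
      pos <- pos + 0.5 * u
    }
  }
  if (spec$appendage) {
    u <- rand_dir()
    base <- ctr + 0.9 * ellipsoid_reach(u, axes) * u
    mask <- stamp_ball(mask, base + 2 * u, stats::runif(1, 2.5, 4), d)
  }
  list(mask = mask * 1L, body_only = body_only * 1L)
}

#' Generate one phantom volume/mask pair
#'
#' Deterministic given `(spec, seed)`. Shape parameters are redrawn (up to
#' `spec$max_retries` times) until the mask is a single 6-connected
#' component with foreground fraction inside `spec$fg_fraction`.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed.
#' @return List with `vol` ([volume3d()]), `mask` ([label_mask()]), and the
#'   achieved `fg_fraction`.
#' @export
generate_phantom <- function(spec = phantom_spec(), seed = 1L) {
  set.seed(seed)
  d <- spec$grid_shape
  for (try in seq_len(spec$max_retries)) {
    dr <- draw_phantom_mask(spec)
    frac <- sum(dr$mask) / prod(d)
    ncomp <- count_components6(as.integer(dr$mask), d[1], d[2], d[3])
    if (frac >= spec$fg_fraction[1] && frac <= spec$fg_fraction[2] &&
        ncomp == 1L) {
      signal <- gaussian_blur3(dr$mask * (spec$contrast * spec$noise_sd),
                               spec$smooth_sigma)
      noise <- array(stats::rnorm(prod(d), sd = spec$noise_sd), d)
      vol <- volume3d(signal + noise, spacing = spec$spacing,
                      source_id = sprintf("phantom-seed-%d", seed))
      return(list(vol = vol,
                  mask = label_mask(array(dr$mask, d), spacing = spec$spacing),
                  body_only = dr$body_only,
                  fg_fraction = frac, seed = seed))
    }
  }
  stop("phantom spec infeasible: no admissible mask in ",
       spec$max_retries, " draws (seed ", seed, ")")
}

#' Generate a phantom dataset
#'
#' Produces `n` phantoms with per-item seeds derived as `seed + i`, and
#' optionally writes NIfTI volume/mask pairs plus a CSV manifest.
#'
#' @param n Number of phantoms.
#' @param spec A [phantom_spec()].
#' @param seed Base seed.
#' @param dir Output directory; `NULL` keeps everything in memory.
#' @return List of phantoms (as from [generate_phantom()]) with a
#'   `manifest` attribute (data frame: id, seed, foreground fraction).
#' @export
generate_dataset <- function(n, spec = phantom_spec(), seed = 1L, dir = NULL) {
  stopifnot(n >= 1)
  items <- lapply(seq_len(n), function(i) {
    ph <- generate_phantom(spec, seed = seed + i)
    ph$id <- sprintf("phantom_%03d", i)
    ph
  })
  manifest <- data.frame(
    id = vapply(items, `[[`, character(1), "id"),
    seed = vapply(items, `[[`, numeric(1), "seed"),
    foreground_fraction = vapply(items, `[[`, numeric(1), "fg_fraction"),
    stringsAsFactors = FALSE
  )
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (ph in items) {
      write_volume(ph$vol, file.path(dir, paste0(ph$id, "_vol.nii.gz")))
      write_mask(ph$mask, ph$vol, file.path(dir, paste0(ph$id, "_mask.nii.gz")))
    }
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  attr(items, "manifest") <- manifest
  items
}
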