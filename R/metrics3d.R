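## Spacing-aware 3D evaluation metrics: Dice overlap, full (symmetric)
## Hausdorff distance and average symmetric surface distance (ASSD), both
## surface distances in physical millimetres between voxel centres.
## Surfaces are foreground voxels with at least one background 6-neighbour;
## the array border counts as background.

#' Voxel-wise confusion counts
#'
#' @param pred,truth Binary masks (arrays or [label_mask()] objects) of the
#'   same shape.
#' @return List with integer `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(pred, truth) {
  p <- mask_data(pred)
  y <- mask_data(truth)
  check_same_shape(p, y)
  tp <- sum(p == 1 & y == 1)
  tn <- sum(p == 0 & y == 0)
  fp <- sum(p == 1 & y == 0)
  list(TP = tp, TN = tn, FP = fp, FN = length(p) - tp - tn - fp)
}

#' 3D Dice score
#'
#' `2TP / (2TP + FN + FP)` over the whole volume. When both masks are
#' empty the score is defined as 1 (with a warning).
#'
#' @inheritParams confusion_counts
#' @return Dice in \[0, 1\].
#' @export
dice3d <- function(pred, truth) {
  cc <- confusion_counts(pred, truth)
  if (cc$TP + cc$FP + cc$FN == 0) {
    warning("both masks empty; dice defined as 1")
    return(1)
  }
  2 * cc$TP / (2 * cc$TP + cc$FN + cc$FP)
}

#' Surface voxels of a binary mask
#'
#' Foreground voxels with at least one background 6-neighbour; out-of-bounds
#' neighbours count as background.
#'
#' @param mask Binary 3D array (or [label_mask()]).
#' @return Integer matrix with columns i, j, k (1-based voxel indices).
#' @export
surface_voxels <- function(mask) {
  m <- mask_data(mask)
  if (sum(m) == 0) stop("mask is empty: surface undefined")
  d <- dim(m)
  pad <- array(0L, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  core <- function(si, sj, sk) {
    pad[si + 1 + 1:d[1], sj + 1 + 1:d[2], sk + 1 + 1:d[3], drop = FALSE]
  }
  nb_bg <- (core(-1, 0, 0) == 0) | (core(1, 0, 0) == 0) |
    (core(0, -1, 0) == 0) | (core(0, 1, 0) == 0) |
    (core(0, 0, -1) == 0) | (core(0, 0, 1) == 0)
  which(m == 1 & nb_bg, arr.ind = TRUE)
}

surface_coords_mm <- function(surf, spacing) {
  sweep(surf - 1, 2, spacing, `*`)
}

#' Hausdorff distance between two surfaces
#'
#' Full symmetric Hausdorff distance (not a percentile):
#' `max(max_p min_g d(p,g), max_g min_p d(p,g))` with Euclidean distances
#' between voxel centres in physical mm.
#'
#' @param pred_surf,truth_surf Surface voxel index matrices from
#'   [surface_voxels()] (or binary masks, converted internally).
#' @param spacing Voxel spacing in mm along each axis.
#' @return Distance in mm.
#' @export
hausdorff <- function(pred_surf, truth_surf, spacing = c(1, 1, 1)) {
  d <- directed_surface_dists(pred_surf, truth_surf, spacing)
  max(max(d$p_to_g), max(d$g_to_p))
}

#' Average symmetric surface distance (ASSD)
#'
#' Sum of both directed nearest-surface distance sets divided by the total
#' number of surface voxels `|P| + |G|`, in mm.
#'
#' @inheritParams hausdorff
#' @return Distance in mm.
#' @export
assd <- function(pred_surf, truth_surf, spacing = c(1, 1, 1)) {
  d <- directed_surface_dists(pred_surf, truth_surf, spacing)
  (sum(d$p_to_g) + sum(d$g_to_p)) / (length(d$p_to_g) + length(d$g_to_p))
}

as_surface <- function(x) {
  if (is.matrix(x) && ncol(x) == 3) x else surface_voxels(x)
}

directed_surface_dists <- function(pred_surf, truth_surf, spacing) {
  P <- as_surface(pred_surf)
  G <- as_surface(truth_surf)
  if (nrow(P) == 0 || nrow(G) == 0) stop("empty surface: distance undefined")
  Pm <- surface_coords_mm(P, spacing)
  Gm <- surface_coords_mm(G, spacing)
  list(p_to_g = nearest_dists(Pm, Gm), g_to_p = nearest_dists(Gm, Pm))
}

#' Evaluate a set of prediction/truth pairs
#'
#' @param pairs List of lists with elements `pred`, `truth` and optionally
#'   `spacing` (mm, default 1) and `id`.
#' @return An `eval_report`: data frame of per-scan `dice`, `hd_mm`,
#'   `assd_mm` with attributes `mean` and `sd` (population SD) per metric.
#' @export
evaluate_set <- function(pairs) {
  stopifnot(length(pairs) >= 1)
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    spacing <- if (is.null(p$spacing)) c(1, 1, 1) else p$spacing
    ps <- surface_voxels(p$pred)
    gs <- surface_voxels(p$truth)
    data.frame(
      id = if (is.null(p$id)) as.character(i) else p$id,
      dice = dice3d(p$pred, p$truth),
      hd_mm = hausdorff(ps, gs, spacing),
      assd_mm = assd(ps, gs, spacing),
      stringsAsFactors = FALSE
    )
  })
  rep_df <- do.call(rbind, rows)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  structure(rep_df,
            mean = c(dice = mean(rep_df$dice), hd_mm = mean(rep_df$hd_mm),
                     assd_mm = mean(rep_df$assd_mm)),
            sd = c(dice = pop_sd(rep_df$dice), hd_mm = pop_sd(rep_df$hd_mm),
                   assd_mm = pop_sd(rep_df$assd_mm)),
            class = c("eval_report", "data.frame"))
}

#' @export
print.eval_report <- function(x, ...) {
  print.data.frame(x, row.names = FALSE)
  m <- attr(x, "mean")
  s <- attr(x, "sd")
  cat(sprintf("mean dice %.4f (sd %.4f), HD %.3f mm (sd %.3f), ASSD %.3f mm (sd %.3f)\n",
              m["dice"], s["dice"], m["hd_mm"], s["hd_mm"],
              m["assd_mm"], s["assd_mm"]))
  invisible(x)
}
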