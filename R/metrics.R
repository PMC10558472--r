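#' Sorensen-Dice overlap coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)`: 1 is a perfect match, 0 a complete
#' mismatch. Two empty masks make the coefficient undefined and raise an
#' error rather than silently returning 0.
#'
#' @param A,B logical arrays on a shared grid.
#' @return proportion in \[0, 1\].
#' @export
dice <- function(A, B) {
  if (!all(dim(A) == dim(B))) stop("masks do not share a grid")
  na <- sum(A); nb <- sum(B)
  if (na + nb == 0)
    stop("Dice coefficient is undefined for two empty masks")
  2 * sum(A & B) / (na + nb)
}

#' Signed surface distance between predicted and ground-truth ablations
#'
#' For every voxel on the predicted-ablation surface, the unsigned Euclidean
#' distance to the nearest ground-truth surface voxel is computed; the sign
#' is positive where the predicted surface lies outside the ground truth
#' (ground truth locally enclosed by the prediction) and negative where the
#' surface point falls inside the ground-truth mask (ground truth extending
#' beyond the prediction). The mean absolute value is the Absolute Average
#' Error (AAE); the maximum absolute value is also reported.
#'
#' @param pred,gt nonempty logical arrays on `grid`.
#' @param grid the [voxel_grid()].
#' @return object of class `surface_distance_result` with elements
#'   `distances` (mm, signed, one per predicted-surface voxel), `aae`,
#'   `max_abs`, `mean_signed`, and the sign convention.
#' @export
signed_surface_distance <- function(pred, gt, grid) {
  stopifnot(all(dim(pred) == grid$shape), all(dim(gt) == grid$shape))
  if (!any(pred) || !any(gt))
    stop("signed surface distance requires nonempty masks")
  sp <- surface_voxels(pred)
  sg <- surface_voxels(gt)
  dmap <- distance_transform(sg, grid)
  d <- dmap[sp]
  sgn <- ifelse(gt[sp], -1, 1)
  d <- d * sgn
  structure(list(distances = d, aae = mean(abs(d)), max_abs = max(abs(d)),
                 mean_signed = mean(d),
                 sign_convention = "positive outside ground truth"),
            class = "surface_distance_result")
}

#' @export
print.surface_distance_result <- function(x, ...) {
  cat(sprintf("<surface_distance> AAE %.2f mm, max |d| %.2f mm, mean signed %.2f mm\n",
              x$aae, x$max_abs, x$mean_signed))
  invisible(x)
}

#' Vascular fraction of a reference manufacturer ellipsoid
#'
#' Quantifies the expected vessel cooling before any simulation: the
#' manufacturer-specified ablation ellipsoid for the given settings is
#' voxelized around the active-zone center, aligned with the applicator
#' axis, and the fraction of its voxels occupied by segmented vasculature is
#' returned.
#'
#' @param vessel_mask logical array of vessel voxels.
#' @param plan an [applicator_plan()].
#' @param power generator power, W.
#' @param duration_s ablation duration, s.
#' @param table a [manufacturer_table()].
#' @param grid the [voxel_grid()].
#' @return proportion in \[0, 1\].
#' @export
vascular_fraction <- function(vessel_mask, plan, power, duration_s, table,
                              grid) {
  stopifnot(all(dim(vessel_mask) == grid$shape))
  dims <- manufacturer_lookup(table, power, duration_s)
  L <- dims[["length_mm"]]; D <- dims[["diameter_mm"]]
  a <- plan$direction
  # support half-extent of the spheroid along each world axis
  half <- sqrt((L / 2)^2 * a^2 + (D / 2)^2 * (1 - a^2))
  bb <- grid_world_bounds(grid)
  ctr <- plan$active_zone_center
  if (any(ctr - half < bb["lo", ]) || any(ctr + half > bb["hi", ]))
    stop("reference ellipsoid extends outside the grid")
  ell <- voxelize_spheroid(grid, ctr, L, D, a)
  if (!any(ell)) stop("reference ellipsoid voxelized to an empty mask")
  sum(ell & vessel_mask) / sum(ell)
}

#' Relative ablation volume difference
#'
#' `| |pred| - |gt| | / |gt|` using voxel volumes; the ground truth must be
#' nonempty.
#'
#' @param pred,gt logical arrays on a shared grid.
#' @return nonnegative proportion.
#' @export
relative_volume_difference <- function(pred, gt) {
  if (!all(dim(pred) == dim(gt))) stop("masks do not share a grid")
  ng <- sum(gt)
  if (ng == 0) stop("relative volume difference undefined for empty ground truth")
  abs(sum(pred) - ng) / ng
}

#' Per-case metric set
#'
#' Convenience wrapper computing all per-case metrics between a predicted
#' and a ground-truth ablation mask.
#'
#' @param pred,gt logical arrays on `grid`.
#' @param grid the [voxel_grid()].
#' @return one-row tibble: `dice`, `aae_mm`, `max_abs_mm`, `mean_signed_mm`,
#'   `rel_vol_diff`, `pred_volume_ml`, `gt_volume_ml`.
#' @export
case_metrics <- function(pred, gt, grid) {
  sd <- signed_surface_distance(pred, gt, grid)
  tibble::tibble(dice = dice(pred, gt),
                 aae_mm = sd$aae, max_abs_mm = sd$max_abs,
                 mean_signed_mm = sd$mean_signed,
                 rel_vol_diff = relative_volume_difference(pred, gt),
                 pred_volume_ml = mask_volume_ml(pred, grid),
                 gt_volume_ml = mask_volume_ml(gt, grid))
}
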