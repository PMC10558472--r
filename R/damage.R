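#' Accumulate Arrhenius thermal damage
#'
#' Adds `dt * A * exp(-Ea / (R * T_K))` to the cumulative damage at every
#' voxel (temperature converted to kelvin). Damage is additive over time
#' partitions: accumulating one step of length `dt` equals accumulating any
#' sub-partition of it at constant temperature.
#'
#' @param damage a [damage_field()].
#' @param T a [temperature_field()] on the same grid.
#' @param dt time step, s (`dt = 0` leaves damage unchanged).
#' @param params a [damage_params()].
#' @return the updated [damage_field()].
#' @export
arrhenius_update <- function(damage, T, dt, params = damage_params()) {
  stop_if_grid_mismatch(damage$grid, T$grid)
  if (dt < 0) stop("dt must be nonnegative")
  TK <- T$values + 273.15
  if (any(TK <= 0)) stop("non-physical temperature at or below 0 K")
  damage_field(damage$grid,
               damage$omega + dt * params$A * exp(-params$Ea / (params$R * TK)))
}

#' Threshold a damage field into an ablation mask
#'
#' @param damage a [damage_field()].
#' @param params a [damage_params()]; voxels with `Omega >= threshold` are
#'   ablated.
#' @return logical array.
#' @export
ablation_mask <- function(damage, params = damage_params()) {
  damage$omega >= params$threshold
}

#' Unite sequential ablation masks
#'
#' The final ablation volume of a multi-ablation procedure is the voxelwise
#' union of the per-ablation volumes.
#'
#' @param masks list of logical arrays on a shared grid.
#' @return logical array.
#' @export
unite_ablations <- function(masks) {
  stopifnot(length(masks) >= 1)
  d <- dim(masks[[1]])
  for (m in masks)
    if (!all(dim(m) == d)) stop("ablation masks do not share a grid")
  Reduce(`|`, masks)
}

#' Ablation ellipsoid dimensions along an axis
#'
#' Length is the extent of the mask along `axis`; diameter is twice the
#' largest radial distance from the axis line through the mask centroid,
#' measured in the central slab (within one voxel of the centroid's axial
#' position). One voxel spacing is added to each extent to account for voxel
#' width. Intended for the compact, approximately ellipsoidal masks produced
#' in homogeneous tissue.
#'
#' @param mask nonempty logical array.
#' @param grid the [voxel_grid()].
#' @param axis axis direction (world), normalized internally.
#' @return named numeric `length_mm`, `diameter_mm`.
#' @export
ellipsoid_dimensions <- function(mask, grid, axis = c(0, 0, 1)) {
  if (!any(mask)) stop("ellipsoid dimensions of an empty mask are undefined")
  axis <- axis / sqrt(sum(axis^2))
  co <- grid_coord_arrays(grid)
  ctr <- mask_centroid(mask, grid)
  dx <- co$x[mask] - ctr[1]; dy <- co$y[mask] - ctr[2]; dz <- co$z[mask] - ctr[3]
  s <- dx * axis[1] + dy * axis[2] + dz * axis[3]
  h <- mean(grid$spacing)
  r2 <- pmax(dx^2 + dy^2 + dz^2 - s^2, 0)
  slab <- abs(s) <= h
  rmax <- if (any(slab)) sqrt(max(r2[slab])) else 0
  c(length_mm = max(s) - min(s) + h, diameter_mm = 2 * rmax + h)
}
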