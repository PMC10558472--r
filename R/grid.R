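#' Define a regular 3D voxel grid
#'
#' All masks and fields in mwaplan live on a regular, axis-aligned voxel grid.
#' World coordinates are in millimetres, axes ordered (x, y, z), voxel indices
#' are 1-based in R arrays; `origin` is the world position of the *center* of
#' the first voxel.
#'
#' @param shape integer vector of length 3, voxels per axis.
#' @param spacing numeric length 3 (or 1, recycled), mm per voxel. Default 1 mm
#'   isotropic, matching thin-slice CT reconstruction.
#' @param origin world coordinates (mm) of the center of voxel (1,1,1).
#' @return An object of class `voxel_grid`.
#' @export
#' @examples
#' g <- voxel_grid(c(64, 64, 48), spacing = 1)
#' voxel_volume_mm3(g)
voxel_grid <- function(shape, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  if (length(origin) == 1) origin <- rep(origin, 3)
  stopifnot(length(shape) == 3, length(spacing) == 3, length(origin) == 3)
  if (any(shape < 1)) stop("grid shape must be positive on every axis")
  if (any(spacing <= 0)) stop("grid spacing must be positive on every axis")
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Voxel volume in cubic millimetres
#' @param grid a [voxel_grid()].
#' @export
voxel_volume_mm3 <- function(grid) prod(grid$spacing)

#' Axis coordinate vectors (voxel centers, world mm)
#' @param grid a [voxel_grid()].
#' @return list with numeric vectors `x`, `y`, `z`.
#' @export
grid_axes <- function(grid) {
  list(x = grid$origin[1] + (seq_len(grid$shape[1]) - 1) * grid$spacing[1],
       y = grid$origin[2] + (seq_len(grid$shape[2]) - 1) * grid$spacing[2],
       z = grid$origin[3] + (seq_len(grid$shape[3]) - 1) * grid$spacing[3])
}

# world-coordinate arrays of every voxel center, each of dim grid$shape
grid_coord_arrays <- function(grid) {
  ax <- grid_axes(grid)
  s <- grid$shape
  list(x = array(rep(ax$x, times = s[2] * s[3]), dim = s),
       y = array(rep(rep(ax$y, each = s[1]), times = s[3]), dim = s),
       z = array(rep(ax$z, each = s[1] * s[2]), dim = s))
}

# world extent: outer bounding box of the voxel volume (faces, not centers)
grid_world_bounds <- function(grid) {
  lo <- grid$origin - grid$spacing / 2
  hi <- grid$origin + (grid$shape - 0.5) * grid$spacing
  rbind(lo = lo, hi = hi)
}

#' Test whether two grids describe the same geometry
#' @param a,b [voxel_grid()] objects.
#' @param tol numeric tolerance on spacing/origin (mm).
#' @export
same_grid <- function(a, b, tol = 1e-6) {
  all(a$shape == b$shape) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stop_if_grid_mismatch <- function(a, b) {
  if (!same_grid(a, b)) stop("fields do not share a common voxel grid")
  invisible(TRUE)
}

new_mask <- function(grid, values = FALSE) {
  array(values, dim = grid$shape)
}

#' Mask volume in millilitres
#' @param mask logical 3D array.
#' @param grid the [voxel_grid()] the mask lives on.
#' @export
mask_volume_ml <- function(mask, grid) {
  sum(mask) * voxel_volume_mm3(grid) / 1000
}

#' Euclidean distance transform of a binary mask
#'
#' Exact distance (mm) from every voxel center to the nearest `TRUE` voxel
#' center, computed with a separable lower-envelope algorithm.
#'
#' @param mask logical 3D array.
#' @param grid the [voxel_grid()] the mask lives on.
#' @return numeric array of distances in mm (`Inf` if the mask is empty).
#' @export
distance_transform <- function(mask, grid) {
  stopifnot(all(dim(mask) == grid$shape))
  d <- edt_cpp(as.logical(mask), grid$shape, grid$spacing)
  array(d, dim = grid$shape)
}

#' Surface voxels of a binary mask
#'
#' A mask voxel is a surface voxel when at least one of its six face
#' neighbours is outside the mask (voxels on the array boundary count).
#'
#' @param mask logical 3D array.
#' @return logical array of the same shape.
#' @export
surface_voxels <- function(mask) {
  d <- dim(mask)
  interior <- array(TRUE, dim = d)
  for (ax in 1:3) {
    if (d[ax] == 1) { interior[] <- FALSE; next }
    lo <- shift_array(mask, ax, 1L)
    hi <- shift_array(mask, ax, -1L)
    interior <- interior & lo & hi
  }
  mask & !interior
}

# shift a 3D array by `by` voxels along axis `ax`, padding with FALSE/0
shift_array <- function(a, ax, by) {
  d <- dim(a)
  out <- array(if (is.logical(a)) FALSE else 0, dim = d)
  n <- d[ax]
  if (abs(by) >= n) return(out)
  src <- if (by > 0) seq_len(n - by) else seq(1 - by, n)
  dst <- if (by > 0) seq(1 + by, n) else seq_len(n + by)
  ix <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  src_ix <- ix; src_ix[[ax]] <- src
  dst_ix <- ix; dst_ix[[ax]] <- dst
  out[dst_ix[[1]], dst_ix[[2]], dst_ix[[3]]] <-
    a[src_ix[[1]], src_ix[[2]], src_ix[[3]]]
  out
}

#' Dilate a mask by a Euclidean ball
#' @param mask logical 3D array.
#' @param grid the [voxel_grid()].
#' @param radius_mm ball radius in mm.
#' @export
dilate_mask <- function(mask, grid, radius_mm) {
  if (!any(mask)) return(mask)
  distance_transform(mask, grid) <= radius_mm
}

# --- geometric voxelizers --------------------------------------------------

# axis-aligned ellipsoid by voxel-center inclusion
voxelize_ellipsoid_aa <- function(grid, center, semi_axes) {
  co <- grid_coord_arrays(grid)
  ((co$x - center[1]) / semi_axes[1])^2 +
    ((co$y - center[2]) / semi_axes[2])^2 +
    ((co$z - center[3]) / semi_axes[3])^2 <= 1
}

# axisymmetric (spheroidal) ellipsoid: half-length L/2 along `axis`,
# radius D/2 perpendicular to it
voxelize_spheroid <- function(grid, center, length_mm, diameter_mm, axis) {
  axis <- axis / sqrt(sum(axis^2))
  co <- grid_coord_arrays(grid)
  dx <- co$x - center[1]; dy <- co$y - center[2]; dz <- co$z - center[3]
  s <- dx * axis[1] + dy * axis[2] + dz * axis[3]
  r2 <- pmax(dx^2 + dy^2 + dz^2 - s^2, 0)
  (s / (length_mm / 2))^2 + r2 / (diameter_mm / 2)^2 <= 1
}

# finite cylinder (capsule without caps beyond the segment ends) voxelization;
# only evaluates voxels inside the segment's bounding box for speed
voxelize_segment <- function(grid, p0, p1, radius_mm, mask = NULL) {
  if (is.null(mask)) mask <- new_mask(grid)
  ax <- grid_axes(grid)
  lo <- pmin(p0, p1) - radius_mm
  hi <- pmax(p0, p1) + radius_mm
  ir <- lapply(1:3, function(a) which(ax[[a]] >= lo[a] & ax[[a]] <= hi[a]))
  if (any(lengths(ir) == 0)) return(mask)
  xs <- ax$x[ir[[1]]]; ys <- ax$y[ir[[2]]]; zs <- ax$z[ir[[3]]]
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  X <- array(rep(xs, times = ny * nz), dim = c(nx, ny, nz))
  Y <- array(rep(rep(ys, each = nx), times = nz), dim = c(nx, ny, nz))
  Z <- array(rep(zs, each = nx * ny), dim = c(nx, ny, nz))
  v <- p1 - p0
  L2 <- sum(v^2)
  if (L2 == 0) {
    inside <- (X - p0[1])^2 + (Y - p0[2])^2 + (Z - p0[3])^2 <= radius_mm^2
  } else {
    t <- ((X - p0[1]) * v[1] + (Y - p0[2]) * v[2] + (Z - p0[3]) * v[3]) / L2
    tc <- pmin(pmax(t, 0), 1)
    cx <- p0[1] + tc * v[1]; cy <- p0[2] + tc * v[2]; cz <- p0[3] + tc * v[3]
    inside <- t >= 0 & t <= 1 &
      (X - cx)^2 + (Y - cy)^2 + (Z - cz)^2 <= radius_mm^2
  }
  sub <- mask[ir[[1]], ir[[2]], ir[[3]], drop = FALSE]
  mask[ir[[1]], ir[[2]], ir[[3]]] <- sub | inside
  mask
}

# centroid (world mm) of a mask
mask_centroid <- function(mask, grid) {
  if (!any(mask)) stop("centroid of an empty mask is undefined")
  co <- grid_coord_arrays(grid)
  c(sum(co$x[mask]), sum(co$y[mask]), sum(co$z[mask])) / sum(mask)
}
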