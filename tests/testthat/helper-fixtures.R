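# shared fixtures: tiny grids, analytic masks, fast solver setups

centered_grid <- function(n = 15, h = 2) {
  n <- rep(n, length.out = 3)
  h <- rep(h, length.out = 3)
  voxel_grid(n, h, origin = -(n - 1) / 2 * h)
}

sphere_mask <- function(grid, r, center = c(0, 0, 0)) {
  mwaplan:::voxelize_spheroid(grid, center, 2 * r, 2 * r, c(0, 0, 1))
}

# brute-force Dice from explicit voxel index sets
dice_oracle <- function(A, B) {
  ia <- which(A); ib <- which(B)
  2 * length(intersect(ia, ib)) / (length(ia) + length(ib))
}

# brute-force Euclidean distance transform (small grids only)
edt_oracle <- function(mask, grid) {
  ax <- grid_axes(grid)
  pts <- as.matrix(expand.grid(x = ax$x, y = ax$y, z = ax$z))
  src <- pts[as.vector(mask), , drop = FALSE]
  d <- apply(pts, 1, function(p)
    sqrt(min(colSums((t(src) - p)^2))))
  array(d, dim = grid$shape)
}

# a small liver phantom with one central applicator plan
simple_case <- function(n = 21, h = 2, power = 80, duration_s = 120,
                        zone = 10) {
  g <- centered_grid(n, h)
  semi <- (n - 1) / 2 * h * c(0.85, 0.85, 0.85)
  case <- make_liver_phantom(semi, g, seed = 1)
  case$plans <- list(applicator_plan(tip = c(0, 0, zone / 2),
                                     direction = c(0, 0, 1),
                                     active_zone_length = zone))
  case$settings <- tibble::tibble(power_W = power, duration_s = duration_s)
  case
}
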