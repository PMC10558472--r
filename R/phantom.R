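#' Phantom case container
#'
#' Bundles everything one synthetic ablation case carries: the grid, the
#' liver and vessel masks, the vessel segment graph, the applicator plans
#' with their power/duration settings, an optional ground-truth ablation
#' mask, artifact flags, and the seed it was generated from.
#'
#' @param grid a [voxel_grid()].
#' @param liver_mask,vessel_mask logical arrays on `grid`.
#' @param vessel_graph tibble of vessel segments (one row per cylinder).
#' @param plans list of [applicator_plan()].
#' @param settings tibble with columns `power_W`, `duration_s` (one row per
#'   plan).
#' @param ground_truth_mask logical array or `NULL`.
#' @param seed integer seed the case derives from.
#' @param flags named list of artifact flags
#'   (`misaligned`, `gt_overestimated`).
#' @param id case identifier string.
#' @return object of class `phantom_case`.
#' @export
phantom_case <- function(grid, liver_mask, vessel_mask = NULL,
                         vessel_graph = empty_vessel_graph(),
                         plans = list(), settings = empty_settings(),
                         ground_truth_mask = NULL, seed = NA_integer_,
                         flags = list(misaligned = FALSE,
                                      gt_overestimated = FALSE),
                         id = "case") {
  if (is.null(vessel_mask)) vessel_mask <- new_mask(grid)
  stopifnot(all(dim(liver_mask) == grid$shape),
            all(dim(vessel_mask) == grid$shape))
  if (any(vessel_mask & !liver_mask))
    stop("vessel mask must be contained in the liver mask")
  if (!is.null(ground_truth_mask)) {
    stopifnot(all(dim(ground_truth_mask) == grid$shape))
    if (any(ground_truth_mask & !liver_mask))
      stop("ground truth must be contained in the liver mask")
  }
  if (length(plans) != nrow(settings))
    stop("plans and settings must have matching length")
  for (p in plans)
    if (!point_in_mask(p$active_zone_center, liver_mask, grid))
      stop("applicator active-zone center must lie inside the liver")
  structure(list(grid = grid, liver_mask = liver_mask,
                 vessel_mask = vessel_mask, vessel_graph = vessel_graph,
                 plans = plans, settings = settings,
                 ground_truth_mask = ground_truth_mask,
                 seed = seed, flags = flags, id = id),
            class = "phantom_case")
}

empty_vessel_graph <- function() {
  tibble::tibble(segment = integer(), parent = integer(),
                 generation = integer(),
                 x0 = numeric(), y0 = numeric(), z0 = numeric(),
                 x1 = numeric(), y1 = numeric(), z1 = numeric(),
                 radius_mm = numeric())
}

empty_settings <- function() {
  tibble::tibble(power_W = numeric(), duration_s = numeric())
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf(paste0("<phantom_case %s> liver %.1f mL, vessels %.2f mL, ",
                     "%d plan(s)%s\n"),
              x$id, mask_volume_ml(x$liver_mask, x$grid),
              mask_volume_ml(x$vessel_mask, x$grid), length(x$plans),
              if (is.null(x$ground_truth_mask)) "" else
                sprintf(", ground truth %.1f mL",
                        mask_volume_ml(x$ground_truth_mask, x$grid))))
  invisible(x)
}

# nearest voxel index of a world point; NA when outside the grid
world_to_voxel <- function(grid, p) {
  i <- round((p - grid$origin) / grid$spacing) + 1
  if (any(i < 1) || any(i > grid$shape)) return(rep(NA_integer_, 3))
  as.integer(i)
}

point_in_mask <- function(p, mask, grid) {
  i <- world_to_voxel(grid, p)
  if (any(is.na(i))) return(FALSE)
  mask[i[1], i[2], i[3]]
}

#' Generate an ellipsoidal liver phantom
#'
#' Voxelizes an axis-aligned ellipsoid (voxel-center inclusion) as the liver
#' parenchyma of a new [phantom_case()]. Deterministic for fixed inputs.
#'
#' @param semi_axes_mm numeric length 3, ellipsoid semi-axes in mm; each must
#'   exceed twice the grid spacing on its axis.
#' @param grid a [voxel_grid()]; the ellipsoid must fit inside it.
#' @param seed integer seed recorded on the case.
#' @param center world center of the ellipsoid (default: grid center).
#' @param id case identifier.
#' @return a [phantom_case()] with only the liver mask populated.
#' @export
make_liver_phantom <- function(semi_axes_mm, grid, seed = 1L, center = NULL,
                               id = "case") {
  stopifnot(length(semi_axes_mm) == 3)
  if (any(semi_axes_mm <= 2 * grid$spacing))
    stop("liver semi-axes must exceed twice the grid spacing")
  if (is.null(center)) {
    bb <- grid_world_bounds(grid)
    center <- colMeans(bb)
  }
  bb <- grid_world_bounds(grid)
  if (any(center - semi_axes_mm < bb["lo", ]) ||
      any(center + semi_axes_mm > bb["hi", ]))
    stop("liver ellipsoid exceeds the grid bounds")
  liver <- voxelize_ellipsoid_aa(grid, center, semi_axes_mm)
  phantom_case(grid, liver, seed = as.integer(seed), id = id)
}

# orthonormal basis perpendicular to a unit vector
perp_basis <- function(d) {
  ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- ref - sum(ref * d) * d
  u <- u / sqrt(sum(u^2))
  v <- c(d[2] * u[3] - d[3] * u[2],
         d[3] * u[1] - d[1] * u[3],
         d[1] * u[2] - d[2] * u[1])
  list(u = u, v = v)
}

#' Grow a bifurcating vessel tree inside the liver
#'
#' Recursive, roughly symmetric bifurcation: at each node two children are
#' spawned whose radii follow Murray's law (`r_parent^3 = sum r_child^3`,
#' symmetric split), with seeded jitter on branch angles. Branches are
#' voxelized as cylinders and clipped to the liver; growth stops at
#' `n_generations` or when radii fall below 0.5 mm (branches below that
#' diameter class carry no relevant cooling). Random draws are made in
#' breadth-first order, so the first generations are identical for any
#' larger `n_generations` (tree volume is monotone in `n_generations`).
#'
#' If `target_vascular_fraction` is given, a straight feeder vessel is
#' placed through the neighbourhood of the first applicator's active zone
#' and its radius is bisected until [vascular_fraction()] for the first
#' plan/settings is within one percentage point of the target.
#'
#' @param case a [phantom_case()] with a liver mask (and, when targeting a
#'   fraction, at least one plan plus settings).
#' @param root_point world coordinates of the tree root (inside the liver).
#' @param root_radius_mm root vessel radius, at least 0.5 mm.
#' @param n_generations number of bifurcation generations (0 = single
#'   cylinder).
#' @param target_vascular_fraction optional proportion in \[0, 1\].
#' @param seed integer seed.
#' @param root_direction initial growth direction (default seeded random).
#' @param table [manufacturer_table()] used by the vascular-fraction target
#'   (default: the bundled synthetic table).
#' @param max_iter bisection budget for the fraction target.
#' @return the case with `vessel_mask` and `vessel_graph` populated.
#' @export
grow_vessel_tree <- function(case, root_point, root_radius_mm = 3,
                             n_generations = 4,
                             target_vascular_fraction = NULL, seed = 1L,
                             root_direction = NULL, table = NULL,
                             max_iter = 40) {
  grid <- case$grid
  if (!point_in_mask(root_point, case$liver_mask, grid))
    stop("vessel root must lie inside the liver")
  if (root_radius_mm < 0.5)
    stop("root radius must be at least 0.5 mm")
  withr::with_seed(seed, {
    if (is.null(root_direction)) {
      root_direction <- stats::rnorm(3)
    }
    root_direction <- root_direction / sqrt(sum(root_direction^2))
    segs <- list()
    queue <- list(list(p = as.numeric(root_point), d = root_direction,
                       r = root_radius_mm, gen = 0L, parent = NA_integer_))
    while (length(queue) > 0) {
      node <- queue[[1]]; queue <- queue[-1]
      len <- max(6, 9 * node$r) * stats::runif(1, 0.85, 1.15)
      p1 <- node$p + node$d * len
      id <- length(segs) + 1L
      segs[[id]] <- list(segment = id, parent = node$parent,
                         generation = node$gen,
                         p0 = node$p, p1 = p1, r = node$r)
      child_r <- node$r / 2^(1 / 3)
      if (node$gen < n_generations && child_r >= 0.5 &&
          point_in_mask(p1, case$liver_mask, grid)) {
        theta <- (35 + stats::rnorm(2, 0, 8)) * pi / 180
        phi <- stats::runif(1, 0, 2 * pi)
        pb <- perp_basis(node$d)
        for (kk in 1:2) {
          az <- phi + (kk - 1) * pi + stats::rnorm(1, 0, 0.3)
          dirk <- cos(theta[kk]) * node$d +
            sin(theta[kk]) * (cos(az) * pb$u + sin(az) * pb$v)
          dirk <- dirk / sqrt(sum(dirk^2))
          queue[[length(queue) + 1]] <-
            list(p = p1, d = dirk, r = child_r,
                 gen = node$gen + 1L, parent = id)
        }
      }
    }
    tree <- new_mask(grid)
    for (s in segs) tree <- voxelize_segment(grid, s$p0, s$p1, s$r, tree)
    vessel <- tree & case$liver_mask
    graph <- purrr::map_dfr(segs, function(s)
      tibble::tibble(segment = s$segment, parent = s$parent,
                     generation = s$generation,
                     x0 = s$p0[1], y0 = s$p0[2], z0 = s$p0[3],
                     x1 = s$p1[1], y1 = s$p1[2], z1 = s$p1[3],
                     radius_mm = s$r))

    if (!is.null(target_vascular_fraction)) {
      if (length(case$plans) < 1)
        stop("a vascular-fraction target needs at least one applicator plan")
      if (is.null(table)) table <- default_manufacturer_table()
      plan <- case$plans[[1]]
      pw <- case$settings$power_W[1]; du <- case$settings$duration_s[1]
      vf_of <- function(vm) vascular_fraction(vm, plan, pw, du, table, grid)
      base_vf <- vf_of(vessel)
      tol <- 0.01
      if (base_vf > target_vascular_fraction + tol)
        stop("base vessel tree already exceeds the target vascular fraction")
      if (abs(base_vf - target_vascular_fraction) > tol) {
        pb <- perp_basis(plan$direction)
        az <- stats::runif(1, 0, 2 * pi)
        fd <- cos(az) * pb$u + sin(az) * pb$v
        fd <- cos(0.25) * fd + sin(0.25) * plan$direction  # slight tilt
        fd <- fd / sqrt(sum(fd^2))
        off <- 2 * (sin(az) * pb$u - cos(az) * pb$v)
        fc <- plan$active_zone_center + off
        f0 <- fc - fd * 60; f1 <- fc + fd * 60
        feeder_mask <- function(r) {
          (voxelize_segment(grid, f0, f1, r) & case$liver_mask) | vessel
        }
        lo <- 0.25; hi <- 14
        if (vf_of(feeder_mask(hi)) < target_vascular_fraction - tol)
          stop("target vascular fraction unattainable: feeder at maximum ",
               "radius still below target")
        ok <- FALSE; r_mid <- NA
        for (it in seq_len(max_iter)) {
          r_mid <- (lo + hi) / 2
          vf <- vf_of(feeder_mask(r_mid))
          if (abs(vf - target_vascular_fraction) <= tol) { ok <- TRUE; break }
          if (vf < target_vascular_fraction) lo <- r_mid else hi <- r_mid
        }
        if (!ok)
          stop("vascular-fraction bisection did not converge in ",
               max_iter, " iterations")
        vessel <- feeder_mask(r_mid)
        graph <- dplyr::bind_rows(graph, tibble::tibble(
          segment = nrow(graph) + 1L, parent = NA_integer_,
          generation = NA_integer_,
          x0 = f0[1], y0 = f0[2], z0 = f0[3],
          x1 = f1[1], y1 = f1[2], z1 = f1[3], radius_mm = r_mid))
      }
    }
    case$vessel_mask <- vessel
    case$vessel_graph <- graph
  })
  case
}

#' Synthesize a ground-truth ablation from a predicted mask
#'
#' `distortion = "none"` copies the prediction; `"vessel_indent"` erodes the
#' prediction wherever it lies within `indent_mm` of a vessel voxel,
#' emulating the heat-sink indentation real necrosis zones show near
#' vasculature. The result is clipped to the liver (a fixture device, not a
#' physical claim).
#'
#' @param case a [phantom_case()].
#' @param predicted_mask logical array on the case grid.
#' @param distortion `"none"` or `"vessel_indent"`.
#' @param indent_mm erosion reach around vessels, mm.
#' @param seed unused placeholder kept for interface symmetry.
#' @return the case with `ground_truth_mask` set.
#' @export
synthesize_ground_truth <- function(case, predicted_mask,
                                    distortion = c("none", "vessel_indent"),
                                    indent_mm = 3, seed = NULL) {
  distortion <- match.arg(distortion)
  stopifnot(all(dim(predicted_mask) == case$grid$shape))
  gt <- predicted_mask & case$liver_mask
  if (distortion == "vessel_indent" && any(case$vessel_mask)) {
    d <- distance_transform(case$vessel_mask, case$grid)
    gt <- gt & (d > indent_mm)
  }
  case$ground_truth_mask <- gt
  case
}

#' Inject a triangular infarction wedge into the ground truth
#'
#' Emulates vasculature shortage: a cone with apex on the ground-truth
#' ablation surface, opening toward the nearest point of the liver capsule,
#' is unioned into the ground-truth mask (clipped to the liver). Marks the
#' case `gt_overestimated`.
#'
#' @param case a [phantom_case()] with a ground-truth mask.
#' @param apex world point on the ground-truth surface (within one voxel).
#' @param half_angle_deg cone half-opening angle; 0 leaves the ground truth
#'   unchanged.
#' @param seed unused placeholder kept for interface symmetry.
#' @return the updated case.
#' @export
inject_infarction_wedge <- function(case, apex, half_angle_deg = 12,
                                    seed = NULL) {
  if (is.null(case$ground_truth_mask))
    stop("case has no ground-truth mask to distort")
  grid <- case$grid
  surf <- surface_voxels(case$ground_truth_mask)
  dsurf <- distance_transform(surf, grid)
  iv <- world_to_voxel(grid, apex)
  if (any(is.na(iv)) || dsurf[iv[1], iv[2], iv[3]] > 1.5 * max(grid$spacing))
    stop("wedge apex must lie on the ground-truth ablation surface")
  if (half_angle_deg <= 0) return(case)
  capsule <- surface_voxels(case$liver_mask)
  co <- grid_coord_arrays(grid)
  cx <- co$x[capsule]; cy <- co$y[capsule]; cz <- co$z[capsule]
  d2 <- (cx - apex[1])^2 + (cy - apex[2])^2 + (cz - apex[3])^2
  k <- which.min(d2)
  b <- c(cx[k], cy[k], cz[k])
  axis <- b - apex
  L <- sqrt(sum(axis^2))
  if (L < 1e-9) return(case)
  axis <- axis / L
  dx <- co$x - apex[1]; dy <- co$y - apex[2]; dz <- co$z - apex[3]
  s <- dx * axis[1] + dy * axis[2] + dz * axis[3]
  perp <- sqrt(pmax(dx^2 + dy^2 + dz^2 - s^2, 0))
  wedge <- s >= 0 & s <= L + max(grid$spacing) &
    perp <= s * tan(half_angle_deg * pi / 180)
  case$ground_truth_mask <-
    (case$ground_truth_mask | wedge) & case$liver_mask
  case$flags$gt_overestimated <- TRUE
  case
}

#' Rigidly perturb a mask (registration-error emulation)
#'
#' Applies a rigid transform (rotation about the grid's world center, then
#' translation) with nearest-neighbour resampling; voxels mapped from
#' outside the grid are clipped. With `invert = TRUE` the exact inverse
#' transform is applied, so perturbing and then inverting recovers the
#' original mask up to resampling loss.
#'
#' @param mask logical array on `grid`.
#' @param translation_mm numeric length 3, mm.
#' @param rotation_deg numeric length 3, extrinsic rotations about the world
#'   x, y, z axes (applied in that order), degrees.
#' @param grid the [voxel_grid()].
#' @param invert apply the inverse transform instead.
#' @return logical array.
#' @export
perturb_alignment <- function(mask, translation_mm = c(0, 0, 0),
                              rotation_deg = c(0, 0, 0), grid,
                              invert = FALSE) {
  stopifnot(all(dim(mask) == grid$shape))
  ang <- rotation_deg * pi / 180
  rx <- matrix(c(1, 0, 0,
                 0, cos(ang[1]), -sin(ang[1]),
                 0, sin(ang[1]), cos(ang[1])), 3, byrow = TRUE)
  ry <- matrix(c(cos(ang[2]), 0, sin(ang[2]),
                 0, 1, 0,
                 -sin(ang[2]), 0, cos(ang[2])), 3, byrow = TRUE)
  rz <- matrix(c(cos(ang[3]), -sin(ang[3]), 0,
                 sin(ang[3]), cos(ang[3]), 0,
                 0, 0, 1), 3, byrow = TRUE)
  R <- rz %*% ry %*% rx
  ctr <- colMeans(grid_world_bounds(grid))
  co <- grid_coord_arrays(grid)
  pts <- cbind(as.vector(co$x), as.vector(co$y), as.vector(co$z))
  src <- if (!invert) {
    # forward map y = R (x - c) + c + t  =>  x = R^T (y - c - t) + c
    sweep(sweep(pts, 2, ctr + translation_mm) %*% R, 2, ctr, `+`)
  } else {
    sweep(sweep(pts, 2, ctr) %*% t(R), 2, ctr + translation_mm, `+`)
  }
  ij <- sweep(sweep(src, 2, grid$origin), 2, grid$spacing, `/`)
  ij <- round(ij) + 1
  ok <- ij[, 1] >= 1 & ij[, 1] <= grid$shape[1] &
        ij[, 2] >= 1 & ij[, 2] <= grid$shape[2] &
        ij[, 3] >= 1 & ij[, 3] <= grid$shape[3]
  out <- rep(FALSE, nrow(pts))
  lin <- (ij[ok, 1] - 1) + grid$shape[1] *
    ((ij[ok, 2] - 1) + grid$shape[2] * (ij[ok, 3] - 1)) + 1
  out[ok] <- as.vector(mask)[lin]
  array(out, dim = grid$shape)
}

#' Default cohort-generation configuration
#'
#' The study conditions the synthetic cohort emulates: 1-6 sequential
#' ablations per case, generator power in \{80, 90, 100\} W (most procedures
#' at 80 W), durations of 3-10 minutes, and per-case target vascular
#' fractions drawn from the empirical 0-22.2% range of a 21-patient
#' reference cohort. A fixed fraction of cases is flagged for misalignment
#' and infarction-wedge artifacts.
#'
#' @param spacing grid spacing, mm.
#' @param liver_semi_axes nominal liver ellipsoid semi-axes, mm.
#' @param misalignment_rate,wedge_rate artifact flag probabilities.
#' @param table [manufacturer_table()] for vascular-fraction targeting
#'   (default: the bundled synthetic table).
#' @export
cohort_config <- function(spacing = 2, liver_semi_axes = c(50, 42, 36),
                          misalignment_rate = 0.1, wedge_rate = 0.1,
                          table = NULL) {
  list(spacing = spacing, liver_semi_axes = liver_semi_axes,
       semi_axes_jitter = 0.06,
       active_zone_length = 10,
       powers = c(80, 90, 100), power_probs = c(0.6, 0.15, 0.25),
       duration_range_min = c(3, 10),
       n_ablations_probs = c(0.35, 0.45, 0.08, 0.04, 0.04, 0.04),
       vascular_fractions = c(0.078, 0.041, 0.113, 0.027, 0.021, 0.090,
                              0.175, 0.044, 0.000, 0.010, 0.000, 0.000,
                              0.099, 0.001, 0.006, 0.012, 0.000, 0.000,
                              0.222, 0.000, 0.007),
       misalignment_rate = misalignment_rate, wedge_rate = wedge_rate,
       vessel_root_radius = 3, n_generations = 4,
       table = table)
}

#' Sample a synthetic patient cohort
#'
#' Fully reproducible from `seed`: per case, a jittered ellipsoidal liver,
#' 1-6 applicator plans with sampled power/duration settings, a vessel tree
#' grown to a target vascular fraction drawn from the configured empirical
#' range, and artifact flags. Targets are sampled without replacement while
#' the cohort is no larger than the empirical list, so the configured
#' fraction range is spanned.
#'
#' @param n_cases number of cases (>= 1).
#' @param seed integer seed.
#' @param config a [cohort_config()].
#' @return list of [phantom_case()] objects.
#' @export
sample_cohort <- function(n_cases, seed = 1L, config = cohort_config()) {
  stopifnot(n_cases >= 1)
  if (is.null(config$table)) config$table <- default_manufacturer_table()
  vfs <- withr::with_seed(seed, {
    pool <- config$vascular_fractions
    if (n_cases <= length(pool)) sample(pool, n_cases)
    else sample(pool, n_cases, replace = TRUE)
  })
  purrr::map(seq_len(n_cases), function(i) {
    case_seed <- (seed + i * 7919L) %% 2147483647L
    for (attempt in 0:2) {
      case <- try(build_cohort_case(vfs[i], case_seed + attempt * 131L,
                                    config,
                                    id = sprintf("S%03d", i)),
                  silent = TRUE)
      if (!inherits(case, "try-error")) return(case)
    }
    stop("cohort case ", i, " failed to generate: ",
         attr(case, "condition")$message)
  })
}

build_cohort_case <- function(target_vf, case_seed, config, id) {
  withr::with_seed(case_seed, {
    semi <- config$liver_semi_axes *
      stats::runif(3, 1 - config$semi_axes_jitter, 1 + config$semi_axes_jitter)
    margin <- 12
    extent <- 2 * (semi + margin)
    shape <- ceiling(extent / config$spacing)
    shape <- shape + (shape %% 2 == 0)
    grid <- voxel_grid(shape, config$spacing,
                       origin = -(shape - 1) / 2 * config$spacing)
    case <- make_liver_phantom(semi, grid, seed = case_seed, id = id)

    n_abl <- sample.int(6, 1, prob = config$n_ablations_probs)
    dirv <- stats::rnorm(3); dirv <- dirv / sqrt(sum(dirv^2))
    base_ctr <- stats::runif(3, -5, 5)
    pb <- perp_basis(dirv)
    plans <- list(); pw <- numeric(n_abl); du <- numeric(n_abl)
    for (k in seq_len(n_abl)) {
      offset <- if (k == 1) c(0, 0, 0) else {
        step <- ceiling((k - 1) / 2) * 11
        sgn <- if (k %% 2 == 0) 1 else -1
        sgn * step * (cos(k) * pb$u + sin(k) * pb$v)
      }
      ctr <- base_ctr + offset
      plans[[k]] <- applicator_plan(
        tip = ctr + dirv * config$active_zone_length / 2,
        direction = dirv,
        active_zone_length = config$active_zone_length)
      pw[k] <- sample(config$powers, 1, prob = config$power_probs)
      du[k] <- sample(seq(config$duration_range_min[1],
                          config$duration_range_min[2]), 1) * 60
    }
    case$plans <- plans
    case$settings <- tibble::tibble(power_W = pw, duration_s = du)

    root <- c(-0.5 * semi[1], 0, 0)
    case <- grow_vessel_tree(case, root,
                             root_radius_mm = config$vessel_root_radius,
                             n_generations = config$n_generations,
                             target_vascular_fraction = target_vf,
                             seed = case_seed,
                             root_direction = c(-1, 0.2, 0.1),
                             table = config$table)
    case$flags$misaligned <- stats::runif(1) < config$misalignment_rate
    case$flags$gt_overestimated <- stats::runif(1) < config$wedge_rate
    case$target_vascular_fraction <- target_vf
    case
  })
}
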