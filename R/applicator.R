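#' Applicator pose and active zone
#'
#' The microwave applicator is a needle inserted along `direction` (a unit
#' vector pointing from entry toward the tip). Power is deposited on the
#' *active zone*, the distal segment of length `active_zone_length` ending at
#' the tip; its center is `tip - direction * active_zone_length / 2`.
#'
#' @param tip world coordinates of the applicator tip, mm.
#' @param direction insertion direction; normalized internally, must be
#'   nonzero.
#' @param active_zone_length length of the emitting segment, mm (default 10).
#' @return object of class `applicator_plan`.
#' @export
applicator_plan <- function(tip, direction, active_zone_length = 10) {
  stopifnot(length(tip) == 3, length(direction) == 3, active_zone_length > 0)
  nrm <- sqrt(sum(direction^2))
  if (nrm < 1e-12) stop("applicator direction must be a nonzero vector")
  direction <- direction / nrm
  structure(list(tip = as.numeric(tip), direction = direction,
                 active_zone_length = active_zone_length,
                 active_zone_center = as.numeric(tip) -
                   direction * active_zone_length / 2),
            class = "applicator_plan")
}

#' Simplified applicator heat-source parameters
#'
#' The deposition is axisymmetric about the applicator axis: flat along the
#' active zone with Gaussian axial tapers of scale `axial_taper` beyond its
#' ends, and Gaussian radial falloff of scale `radial_scale`. The field is
#' normalized on the simulation grid so that its volume integral equals
#' `efficiency * power` at baseline temperature; a sigmoidal
#' temperature-dependent absorption multiplier (decaying from 1 to
#' `absorption_floor` across the evaporation band) then throttles deposition
#' in desiccated tissue.
#'
#' @param radial_scale Gaussian radial scale, mm.
#' @param axial_taper Gaussian taper scale beyond the active-zone ends, mm.
#' @param efficiency fraction of nominal generator power deposited, in (0, 1].
#' @param absorption_floor lower bound of the absorption multiplier.
#' @param absorption_Tmid sigmoid midpoint temperature, Celsius.
#' @param absorption_width sigmoid width, Celsius.
#' @return object of class `source_params`.
#' @export
source_params <- function(radial_scale = 3.5, axial_taper = 4,
                          efficiency = 0.7, absorption_floor = 0.2,
                          absorption_Tmid = 99.5, absorption_width = 1.5) {
  stopifnot(radial_scale > 0, axial_taper > 0,
            efficiency > 0, efficiency <= 1,
            absorption_floor > 0, absorption_floor <= 1,
            absorption_width > 0)
  structure(list(radial_scale = radial_scale, axial_taper = axial_taper,
                 efficiency = efficiency, absorption_floor = absorption_floor,
                 absorption_Tmid = absorption_Tmid,
                 absorption_width = absorption_width),
            class = "source_params")
}

# geometric deposition profile (unnormalized) for a plan on a grid
source_profile <- function(plan, params, grid) {
  co <- grid_coord_arrays(grid)
  ctr <- plan$active_zone_center
  a <- plan$direction
  dx <- co$x - ctr[1]; dy <- co$y - ctr[2]; dz <- co$z - ctr[3]
  s <- dx * a[1] + dy * a[2] + dz * a[3]
  r2 <- pmax(dx^2 + dy^2 + dz^2 - s^2, 0)
  half <- plan$active_zone_length / 2
  over <- pmax(abs(s) - half, 0)
  exp(-r2 / (2 * params$radial_scale^2)) *
    exp(-over^2 / (2 * params$axial_taper^2))
}

#' Applicator heat deposition field
#'
#' @param plan an [applicator_plan()]; the active zone must lie inside the
#'   grid.
#' @param power nominal generator power, W.
#' @param T a [temperature_field()] (used by the absorption multiplier), or
#'   `NULL` for baseline absorption.
#' @param params a [source_params()].
#' @param grid the [voxel_grid()].
#' @return numeric array, volumetric heat source in W/m^3. At uniform
#'   baseline temperature its integral over the grid is
#'   `efficiency * power`.
#' @export
source_field <- function(plan, power, T = NULL, params = source_params(),
                         grid) {
  stopifnot(power >= 0)
  bb <- grid_world_bounds(grid)
  ends <- rbind(plan$tip,
                plan$tip - plan$direction * plan$active_zone_length)
  if (any(t(ends) < bb["lo", ] ) || any(t(ends) > bb["hi", ]))
    stop("applicator active zone lies outside the grid")
  if (power == 0) return(new_mask(grid, 0))
  g <- source_profile(plan, params, grid)
  dV_m3 <- voxel_volume_mm3(grid) * 1e-9
  q <- g * (params$efficiency * power / (sum(g) * dV_m3))
  if (!is.null(T)) {
    stop_if_grid_mismatch(T$grid, grid)
    q <- q * absorption_multiplier(T$values, params)
  }
  q
}

# --- manufacturer table ----------------------------------------------------

#' Manufacturer ablation-size table
#'
#' Vendor-published ablation ellipsoid dimensions per (power, duration)
#' setting, typically derived ex vivo. Must form a complete rectangular
#' lattice in power and duration for bilinear interpolation.
#'
#' @param df data frame with columns `power_W`, `duration_min`, `length_mm`,
#'   `diameter_mm`.
#' @return a tibble of class `manufacturer_table`.
#' @export
manufacturer_table <- function(df) {
  need <- c("power_W", "duration_min", "length_mm", "diameter_mm")
  if (!all(need %in% names(df)))
    stop("manufacturer table needs columns ", paste(need, collapse = ", "))
  tb <- tibble::as_tibble(df)[need]
  tb <- dplyr::arrange(tb, .data$power_W, .data$duration_min)
  pw <- sort(unique(tb$power_W)); du <- sort(unique(tb$duration_min))
  if (nrow(tb) != length(pw) * length(du))
    stop("manufacturer table must be a complete power x duration lattice")
  # dimensions must not shrink with longer duration at fixed power
  chk <- dplyr::summarise(dplyr::group_by(tb, .data$power_W),
                          ok = all(diff(.data$length_mm) >= 0) &&
                               all(diff(.data$diameter_mm) >= 0))
  if (!all(chk$ok))
    stop("ablation dimensions must be nondecreasing in duration")
  class(tb) <- c("manufacturer_table", class(tb))
  tb
}

#' Read a manufacturer table from CSV
#' @param path CSV file with columns `power_W`, `duration_min`, `length_mm`,
#'   `diameter_mm`.
#' @export
read_manufacturer_table <- function(path) {
  manufacturer_table(utils::read.csv(path))
}

#' Bundled synthetic manufacturer table
#'
#' A table for a 100 W-class device shipped with the package. The values are
#' *synthetic*: they were generated by this package's own forward model in
#' homogeneous, vessel-free tissue with the default [source_params()] (see
#' [simulate_manufacturer_table()]), emulating the ex vivo provenance of
#' vendor tables. They are not measurements of any real device.
#' @export
default_manufacturer_table <- function() {
  read_manufacturer_table(system.file("extdata",
                                      "synthetic_manufacturer_table.csv",
                                      package = "mwaplan", mustWork = TRUE))
}

#' Interpolate ablation dimensions from a manufacturer table
#'
#' Bilinear interpolation in (power, duration). No extrapolation: settings
#' outside the tabulated range are an error.
#'
#' @param table a [manufacturer_table()].
#' @param power generator power, W.
#' @param duration_s ablation duration, seconds.
#' @return named numeric: `length_mm`, `diameter_mm`, `volume_ml` (ellipsoid
#'   volume `(4/3) pi (L/2) (D/2)^2`).
#' @export
manufacturer_lookup <- function(table, power, duration_s) {
  duration <- duration_s / 60
  pw <- sort(unique(table$power_W)); du <- sort(unique(table$duration_min))
  if (power < min(pw) || power > max(pw))
    stop("power ", power, " W outside the tabulated range [",
         min(pw), ", ", max(pw), "]")
  if (duration < min(du) || duration > max(du))
    stop("duration ", duration, " min outside the tabulated range [",
         min(du), ", ", max(du), "]")
  interp1 <- function(xs, x) {
    i <- findInterval(x, xs, rightmost.closed = TRUE)
    i <- min(max(i, 1), length(xs) - 1)
    w <- if (xs[i + 1] == xs[i]) 0 else (x - xs[i]) / (xs[i + 1] - xs[i])
    list(i = i, w = w)
  }
  gp <- interp1(pw, power); gd <- interp1(du, duration)
  val <- function(p, d, col) {
    table[[col]][table$power_W == p & table$duration_min == d]
  }
  bil <- function(col) {
    v00 <- val(pw[gp$i], du[gd$i], col)
    v10 <- val(pw[gp$i + 1], du[gd$i], col)
    v01 <- val(pw[gp$i], du[gd$i + 1], col)
    v11 <- val(pw[gp$i + 1], du[gd$i + 1], col)
    (1 - gp$w) * ((1 - gd$w) * v00 + gd$w * v01) +
      gp$w * ((1 - gd$w) * v10 + gd$w * v11)
  }
  L <- bil("length_mm"); D <- bil("diameter_mm")
  c(length_mm = L, diameter_mm = D,
    volume_ml = (4 / 3) * pi * (L / 2) * (D / 2)^2 / 1000)
}

# --- calibration -----------------------------------------------------------

# default simulation setup for homogeneous-tissue (ex vivo-like) ablations:
# grid sized to hold the largest tabulated ablation with margin
calibration_setup <- function(max_len, max_diam, spacing = 2,
                              active_zone_length = 10) {
  ext_ax <- max(max_len, active_zone_length) + 40
  ext_rad <- max_diam + 40
  shape <- ceiling(c(ext_rad, ext_rad, ext_ax) / spacing)
  shape <- shape + (shape %% 2 == 0)  # odd so a voxel center sits at 0
  g <- voxel_grid(shape, spacing, origin = -(shape - 1) / 2 * spacing)
  plan <- applicator_plan(tip = c(0, 0, active_zone_length / 2),
                          direction = c(0, 0, 1),
                          active_zone_length = active_zone_length)
  list(grid = g, plan = plan)
}

#' Simulate one homogeneous-tissue ablation and measure its ellipsoid
#'
#' Runs the bioheat solver in vessel-free tissue (the ex vivo-like setting
#' vendor tables are derived in) and returns the predicted ablation
#' dimensions along the applicator axis.
#'
#' @param power generator power, W.
#' @param duration_s ablation duration, s.
#' @param params a [source_params()].
#' @param tissue,blood tissue and blood models.
#' @param spacing grid spacing, mm.
#' @param setup optional precomputed list from the internal grid builder;
#'   mainly for repeated calls during calibration.
#' @return named numeric `length_mm`, `diameter_mm`, `volume_ml`.
#' @export
simulate_ellipsoid_dimensions <- function(power, duration_s,
                                          params = source_params(),
                                          tissue = tissue_model(),
                                          blood = blood_model(),
                                          spacing = 2, setup = NULL) {
  if (is.null(setup)) setup <- calibration_setup(60, 50, spacing)
  grid <- setup$grid; plan <- setup$plan
  cfg <- solver_config(vessel_sink_enabled = FALSE)
  res <- run_single_ablation(grid, plan, power, duration_s, params, tissue,
                             blood, cfg,
                             liver = new_mask(grid, TRUE),
                             vessel = new_mask(grid, FALSE))
  mask <- res$omega >= 1
  if (!any(mask))
    return(c(length_mm = 0, diameter_mm = 0, volume_ml = 0))
  d <- ellipsoid_dimensions(mask, grid, plan$direction)
  c(d, volume_ml = mask_volume_ml(mask, grid))
}

#' Calibrate the applicator source against a manufacturer table
#'
#' Fits `efficiency` and `radial_scale` of [source_params()] by minimizing
#' the mean squared relative mismatch between simulated homogeneous-tissue
#' ablation dimensions and the tabulated ones (Nelder-Mead on
#' log-transformed parameters; deterministic).
#'
#' @param table a [manufacturer_table()] with at least 4 rows.
#' @param tissue,blood tissue and blood models (vessels are never present
#'   during calibration).
#' @param start a [source_params()] providing the starting point and the
#'   fixed (non-fitted) parameters.
#' @param spacing simulation grid spacing, mm.
#' @param maxit optimizer iteration budget.
#' @param reltol optimizer relative convergence tolerance.
#' @param fit_rows indices of the table rows used in the objective. The
#'   default picks the four corners of the (power, duration) lattice —
#'   short durations pin the deposition shape, long durations the deposited
#'   power — while the returned fit table verifies every row.
#' @return object of class `mwa_source_fit`: the fitted [source_params()],
#'   a per-row fit table, and the optimizer report. Errors if the optimizer
#'   fails to converge within `maxit`.
#' @export
calibrate_source <- function(table, tissue = tissue_model(),
                             blood = blood_model(),
                             start = source_params(),
                             spacing = 2, maxit = 60, reltol = 2e-3,
                             fit_rows = NULL) {
  if (nrow(table) < 4)
    stop("calibration needs at least 4 manufacturer table rows ",
         "(the fit is underdetermined otherwise)")
  if (is.null(fit_rows)) {
    fit_rows <- which(table$duration_min %in% range(table$duration_min) &
                      table$power_W %in% range(table$power_W))
  }
  sub <- table[fit_rows, , drop = FALSE]
  setup <- calibration_setup(max(table$length_mm), max(table$diameter_mm),
                             spacing)
  sim_rows <- function(params, tab = table) {
    purrr::pmap_dfr(tab, function(power_W, duration_min, ...) {
      d <- simulate_ellipsoid_dimensions(power_W, duration_min * 60, params,
                                         tissue, blood, spacing, setup)
      tibble::tibble(sim_length_mm = d[["length_mm"]],
                     sim_diameter_mm = d[["diameter_mm"]])
    })
  }
  objective <- function(theta) {
    p <- start
    p$efficiency <- min(exp(theta[1]), 1)
    p$radial_scale <- exp(theta[2])
    s <- sim_rows(p, sub)
    if (any(s$sim_length_mm == 0)) return(10)  # no ablation formed
    mean(((s$sim_length_mm - sub$length_mm) / sub$length_mm)^2 +
         ((s$sim_diameter_mm - sub$diameter_mm) / sub$diameter_mm)^2)
  }
  opt <- stats::optim(log(c(start$efficiency, start$radial_scale)), objective,
                      method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = reltol))
  if (opt$convergence != 0 && opt$value > 0.05)
    stop("source calibration did not converge within ", maxit,
         " iterations (residual ", signif(opt$value, 3), ")")
  fitted <- start
  fitted$efficiency <- min(exp(opt$par[1]), 1)
  fitted$radial_scale <- exp(opt$par[2])
  fit_tab <- dplyr::bind_cols(tibble::as_tibble(table), sim_rows(fitted))
  structure(list(params = fitted, fit = fit_tab,
                 objective = opt$value, convergence = opt$convergence,
                 spacing = spacing),
            class = "mwa_source_fit")
}

#' @export
print.mwa_source_fit <- function(x, ...) {
  cat(sprintf(paste0("<mwa_source_fit> efficiency = %.3f, radial_scale = ",
                     "%.2f mm, rms rel. residual = %.3f\n"),
              x$params$efficiency, x$params$radial_scale,
              sqrt(x$objective)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the fitted source parameters
#' @param x an `mwa_source_fit`.
#' @param ... unused.
#' @export
tidy.mwa_source_fit <- function(x, ...) {
  tibble::tibble(term = c("efficiency", "radial_scale"),
                 estimate = c(x$params$efficiency, x$params$radial_scale),
                 unit = c("fraction", "mm"))
}

#' One-row calibration fit summary
#' @param x an `mwa_source_fit`.
#' @param ... unused.
#' @export
glance.mwa_source_fit <- function(x, ...) {
  rl <- abs(x$fit$sim_length_mm - x$fit$length_mm) / x$fit$length_mm
  rd <- abs(x$fit$sim_diameter_mm - x$fit$diameter_mm) / x$fit$diameter_mm
  tibble::tibble(n_rows = nrow(x$fit), objective = x$objective,
                 max_rel_length_err = max(rl), max_rel_diameter_err = max(rd),
                 converged = x$convergence == 0)
}

#' Generate a synthetic manufacturer table with the forward model
#'
#' Produces a vendor-style table by simulating homogeneous-tissue ablations
#' over a (power, duration) lattice. This is how the bundled synthetic table
#' was built.
#'
#' @param powers_W generator powers, W.
#' @param durations_min durations, minutes.
#' @param params a [source_params()].
#' @param tissue,blood models used for the forward simulations.
#' @param spacing grid spacing, mm.
#' @return a [manufacturer_table()].
#' @export
simulate_manufacturer_table <- function(powers_W = c(80, 90, 100),
                                        durations_min = c(3, 5, 8, 10),
                                        params = source_params(),
                                        tissue = tissue_model(),
                                        blood = blood_model(),
                                        spacing = 2) {
  setup <- calibration_setup(70, 60, spacing)
  rows <- tidyr::expand_grid(power_W = powers_W, duration_min = durations_min)
  dims <- purrr::pmap_dfr(rows, function(power_W, duration_min) {
    d <- simulate_ellipsoid_dimensions(power_W, duration_min * 60, params,
                                       tissue, blood, spacing, setup)
    tibble::tibble(length_mm = round(d[["length_mm"]], 1),
                   diameter_mm = round(d[["diameter_mm"]], 1))
  })
  tb <- dplyr::bind_cols(rows, dims)
  # rounding may nick the monotone-in-duration requirement by 0.1 mm
  tb <- dplyr::mutate(dplyr::group_by(tb, .data$power_W),
                      length_mm = cummax(.data$length_mm),
                      diameter_mm = cummax(.data$diameter_mm))
  manufacturer_table(dplyr::ungroup(tb))
}
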