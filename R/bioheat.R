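#' Explicit diffusive stability bound
#'
#' Largest stable time step of the explicit scheme,
#' `rho * cp_base / (2 * lam * sum(1/h_i^2))` over the active axes
#' (axes of size 1 carry no flux). The perfusion term is integrated
#' analytically per step and therefore does not restrict the step.
#'
#' @param grid a [voxel_grid()].
#' @param tissue a [tissue_model()].
#' @return maximum stable dt in seconds.
#' @export
stable_dt <- function(grid, tissue) {
  h_m <- grid$spacing * 1e-3
  act <- grid$shape > 1
  if (!any(act)) return(Inf)
  tissue$rho * tissue$cp_base / (2 * tissue$lam * sum(1 / h_m[act]^2))
}

# Laplacian of a temperature array (K/m^2) with ghost-cell boundaries:
# Dirichlet faces use ghost = 2*Tb - T (wall half a voxel outside the
# boundary voxel center), insulated faces mirror. Size-1 axes are skipped.
laplacian_bc <- function(Tv, grid, boundary, boundary_T) {
  d <- dim(Tv)
  h2 <- (grid$spacing * 1e-3)^2
  lap <- array(0, dim = d)
  ix <- lapply(d, seq_len)
  for (ax in 1:3) {
    if (d[ax] == 1) next
    lo <- shift_array(Tv, ax, 1L)   # value of left neighbour
    hi <- shift_array(Tv, ax, -1L)  # value of right neighbour
    first <- ix; first[[ax]] <- 1L
    last <- ix; last[[ax]] <- d[ax]
    gf <- Tv[first[[1]], first[[2]], first[[3]], drop = FALSE]
    gl <- Tv[last[[1]], last[[2]], last[[3]], drop = FALSE]
    if (boundary == "dirichlet") {
      gf <- 2 * boundary_T - gf
      gl <- 2 * boundary_T - gl
    }
    lo[first[[1]], first[[2]], first[[3]]] <- gf
    hi[last[[1]], last[[2]], last[[3]]] <- gl
    lap <- lap + (lo - 2 * Tv + hi) / h2[ax]
  }
  lap
}

#' Advance the temperature field by one time step
#'
#' One step of the Pennes bioheat equation
#' `rho Cp dT/dt = div(lam grad T) + omega rho_b cp_b (T_b - T) + Q`.
#' The explicit scheme advances diffusion and source in an enthalpy
#' formulation (exactly conservative across the evaporation band) and then
#' applies the perfusion term as an exact exponential relaxation toward
#' `T_b`. The implicit scheme is backward Euler with coefficients lagged at
#' the current temperature, solved sparsely; it is unconditionally stable.
#'
#' @param T a [temperature_field()].
#' @param Q volumetric heat source, W/m^3 (array of grid shape, or scalar).
#' @param perfusion perfusion rate field, 1/s (array or scalar); see
#'   [perfusion_field()].
#' @param tissue a [tissue_model()].
#' @param blood a [blood_model()].
#' @param config a [solver_config()]; `config$dt` must be set. For the
#'   explicit scheme a `dt` above the stability bound is a configuration
#'   error, not a silent blow-up.
#' @return a [temperature_field()] at `T$time + dt`.
#' @export
step_temperature <- function(T, Q, perfusion, tissue, blood, config) {
  grid <- T$grid
  dt <- config$dt
  if (is.null(dt) || dt <= 0) stop("solver_config dt must be set and positive")
  if (length(Q) == 1) Q <- array(Q, dim = grid$shape)
  if (length(perfusion) == 1) perfusion <- array(perfusion, dim = grid$shape)
  stopifnot(all(dim(Q) == grid$shape), all(dim(perfusion) == grid$shape))

  if (config$scheme == "explicit") {
    if (dt > stable_dt(grid, tissue) * (1 + 1e-12))
      stop("explicit time step dt = ", dt, " s violates the stability bound ",
           signif(stable_dt(grid, tissue), 4), " s")
    lap <- laplacian_bc(T$values, grid, config$boundary, config$boundary_T)
    H <- enthalpy_of_T(T$values, tissue) + dt * (tissue$lam * lap + Q)
    Tn <- T_of_enthalpy(H, tissue)
    pos <- perfusion > 0
    if (any(pos)) {
      k <- perfusion * blood$rho_b * blood$cp_b /
        (tissue$rho * effective_heat_capacity(Tn, tissue))
      Tn[pos] <- blood$T_b + (Tn[pos] - blood$T_b) * exp(-k[pos] * dt)
    }
  } else {
    Tn <- implicit_step(T$values, Q, perfusion, tissue, blood, config, grid)
  }
  temperature_field(grid, Tn, time = T$time + dt)
}

# backward Euler with lagged Cp_eff / absorption; sparse 7-point system
implicit_step <- function(Tv, Q, perfusion, tissue, blood, config, grid) {
  d <- grid$shape
  n <- prod(d)
  h2 <- (grid$spacing * 1e-3)^2
  lam <- tissue$lam
  idx <- array(seq_len(n), dim = d)

  ii <- vector("list", 7); jj <- vector("list", 7); xx <- vector("list", 7)
  diag_coef <- numeric(n)
  rhs_bc <- numeric(n)
  slot <- 1
  for (ax in 1:3) {
    if (d[ax] == 1) next
    ixs <- lapply(d, seq_len)
    # neighbour pairs along axis
    a_lo <- ixs; a_lo[[ax]] <- seq_len(d[ax] - 1)
    a_hi <- ixs; a_hi[[ax]] <- seq(2, d[ax])
    from <- as.vector(idx[a_lo[[1]], a_lo[[2]], a_lo[[3]]])
    to <- as.vector(idx[a_hi[[1]], a_hi[[2]], a_hi[[3]]])
    w <- lam / h2[ax]
    ii[[slot]] <- c(from, to); jj[[slot]] <- c(to, from)
    xx[[slot]] <- rep(-w, 2 * length(from))
    slot <- slot + 1
    diag_coef[from] <- diag_coef[from] + w
    diag_coef[to] <- diag_coef[to] + w
    # boundary faces
    f1 <- ixs; f1[[ax]] <- 1L
    f2 <- ixs; f2[[ax]] <- d[ax]
    b1 <- as.vector(idx[f1[[1]], f1[[2]], f1[[3]]])
    b2 <- as.vector(idx[f2[[1]], f2[[2]], f2[[3]]])
    if (config$boundary == "dirichlet") {
      diag_coef[c(b1, b2)] <- diag_coef[c(b1, b2)] + 2 * w
      rhs_bc[c(b1, b2)] <- rhs_bc[c(b1, b2)] + 2 * w * config$boundary_T
    }
    # insulated: zero flux, no extra term
  }
  rcp <- tissue$rho * effective_heat_capacity(as.vector(Tv), tissue)
  pk <- as.vector(perfusion) * blood$rho_b * blood$cp_b
  dt <- config$dt
  ii <- c(unlist(ii), seq_len(n))
  jj <- c(unlist(jj), seq_len(n))
  xx <- c(unlist(xx), diag_coef + rcp / dt + pk)
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  b <- rcp / dt * as.vector(Tv) + pk * blood$T_b + as.vector(Q) + rhs_bc
  array(as.numeric(Matrix::solve(A, b)), dim = d)
}

# one ablation through the compiled kernel; optional snapshot collection
run_single_ablation <- function(grid, plan, power, duration_s, params,
                                tissue, blood, config, liver, vessel,
                                omega_init = NULL, dp = damage_params()) {
  Qgeom <- source_field(plan, power, T = NULL, params = params, grid = grid)
  dt <- config$dt %||% (0.9 * stable_dt(grid, tissue))
  if (config$scheme == "explicit" && dt > stable_dt(grid, tissue) * (1 + 1e-12))
    stop("explicit time step dt = ", dt, " s violates the stability bound")
  n_steps <- max(1L, as.integer(ceiling(duration_s / dt)))
  dt <- duration_s / n_steps
  b <- tissue$evaporation_band
  om0 <- if (is.null(omega_init)) numeric(0) else as.numeric(omega_init)
  snap_every <- config$snapshot_interval_s
  chunks <- if (is.finite(snap_every)) {
    per <- max(1L, as.integer(round(snap_every / dt)))
    k <- ceiling(n_steps / per)
    c(rep(per, k - 1), n_steps - per * (k - 1))
  } else n_steps
  Tcur <- array(config$T_init, dim = grid$shape)
  omega <- om0
  deposited <- 0; tmax <- -Inf
  snapshots <- list()
  t_acc <- 0
  for (ns in chunks) {
    if (ns <= 0) next
    res <- run_ablation_cpp(
      Tcur, grid$shape, grid$spacing * 1e-3, Qgeom,
      as.integer(liver), as.integer(vessel),
      tissue$rho, tissue$cp_base, tissue$lam,
      tissue$water_fraction, b[1], b[2], tissue$latent_heat,
      blood$omega0, blood$rho_b, blood$cp_b, blood$T_b,
      blood$vessel_enhancement, as.integer(config$vessel_sink_enabled),
      if (blood$shutdown == "exp") 0L else 1L,
      dp$A, dp$Ea, dp$R,
      dt, as.integer(ns),
      if (config$boundary == "dirichlet") 0L else 1L, config$boundary_T,
      params$absorption_floor, params$absorption_Tmid,
      params$absorption_width,
      omega)
    Tcur <- res$T
    omega <- as.numeric(res$omega)
    deposited <- deposited + res$deposited_J
    tmax <- max(tmax, res$T_max)
    t_acc <- t_acc + ns * dt
    if (is.finite(snap_every))
      snapshots[[length(snapshots) + 1]] <-
        temperature_field(grid, Tcur, time = t_acc)
  }
  list(T = temperature_field(grid, Tcur, time = duration_s),
       omega = array(omega, dim = grid$shape),
       deposited_J = deposited, T_max = tmax, snapshots = snapshots,
       dt = dt, n_steps = n_steps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate all ablations of a phantom case
#'
#' Runs the bioheat solver for each planned ablation in sequence. Sequential
#' ablations are treated as independent: the temperature field is reset to
#' `T_init` before each one, while each ablation's Arrhenius damage field is
#' retained; per-ablation masks are thresholded and then united into the
#' final predicted ablation volume.
#'
#' @param case a `phantom_case` (see [make_liver_phantom()]) with at least
#'   one plan and matching settings.
#' @param tissue a [tissue_model()].
#' @param blood a [blood_model()].
#' @param config a [solver_config()].
#' @param params a [source_params()].
#' @param dp a [damage_params()].
#' @return object of class `mwa_simulation`: per-ablation temperature /
#'   damage / mask, the united predicted mask, deposited energy, and solver
#'   provenance. Deterministic for fixed inputs.
#' @export
simulate_case <- function(case, tissue = tissue_model(),
                          blood = blood_model(), config = solver_config(),
                          params = source_params(), dp = damage_params()) {
  if (length(case$plans) < 1) stop("case has no applicator plan")
  if (nrow(case$settings) != length(case$plans))
    stop("settings and plans differ in length")
  grid <- case$grid
  ablations <- purrr::map(seq_along(case$plans), function(i) {
    plan <- case$plans[[i]]
    res <- run_single_ablation(grid, plan,
                               case$settings$power_W[i],
                               case$settings$duration_s[i],
                               params, tissue, blood, config,
                               liver = case$liver_mask,
                               vessel = case$vessel_mask, dp = dp)
    dmg <- damage_field(grid, res$omega)
    list(T_final = res$T, damage = dmg,
         mask = ablation_mask(dmg, dp),
         deposited_J = res$deposited_J, T_max = res$T_max,
         snapshots = res$snapshots)
  })
  union <- unite_ablations(purrr::map(ablations, "mask"))
  structure(list(case = case, ablations = ablations, union_mask = union,
                 grid = grid,
                 deposited_J = sum(purrr::map_dbl(ablations, "deposited_J")),
                 sink_enabled = config$vessel_sink_enabled,
                 params = params, dp = dp),
            class = "mwa_simulation")
}

#' @export
print.mwa_simulation <- function(x, ...) {
  cat(sprintf("<mwa_simulation> %d ablation(s), union volume %.2f mL, sink %s\n",
              length(x$ablations), mask_volume_ml(x$union_mask, x$grid),
              if (x$sink_enabled) "on" else "off"))
  invisible(x)
}

#' Per-ablation volume summary of a simulation
#' @param x an `mwa_simulation`.
#' @param ... unused.
#' @export
tidy.mwa_simulation <- function(x, ...) {
  tibble::tibble(
    ablation = seq_along(x$ablations),
    power_W = x$case$settings$power_W,
    duration_s = x$case$settings$duration_s,
    volume_ml = purrr::map_dbl(x$ablations,
                               ~ mask_volume_ml(.x$mask, x$grid)),
    T_max = purrr::map_dbl(x$ablations, "T_max"))
}

#' One-row simulation summary
#' @param x an `mwa_simulation`.
#' @param ... unused.
#' @export
glance.mwa_simulation <- function(x, ...) {
  tibble::tibble(n_ablations = length(x$ablations),
                 union_volume_ml = mask_volume_ml(x$union_mask, x$grid),
                 deposited_kJ = x$deposited_J / 1000,
                 sink_enabled = x$sink_enabled)
}
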