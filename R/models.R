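#' Liver tissue thermal model
#'
#' Thermal constants of liver parenchyma used by the bioheat solver. Water
#' evaporation is represented by an effective heat capacity: across the
#' evaporation band the latent heat of the tissue water content is absorbed,
#' implemented as a rectangle added to the specific heat so that the enthalpy
#' remains a continuous, invertible function of temperature.
#'
#' Defaults are generic-population liver literature values; every constant is
#' configurable.
#'
#' @param rho density, kg/m^3.
#' @param cp_base specific heat outside the evaporation band, J/(kg K).
#' @param lam thermal conductivity, W/(m K).
#' @param water_fraction mass fraction of tissue water.
#' @param evaporation_band numeric length 2, (T_low, T_high) in Celsius.
#' @param latent_heat latent heat of vaporization of water, J/kg.
#' @return object of class `tissue_model`.
#' @export
tissue_model <- function(rho = 1079, cp_base = 3540, lam = 0.52,
                         water_fraction = 0.778,
                         evaporation_band = c(99, 100),
                         latent_heat = 2.26e6) {
  stopifnot(rho > 0, cp_base > 0, lam > 0,
            water_fraction >= 0, water_fraction <= 1,
            latent_heat > 0, length(evaporation_band) == 2)
  if (evaporation_band[1] >= evaporation_band[2])
    stop("evaporation band must satisfy T_low < T_high")
  structure(list(rho = rho, cp_base = cp_base, lam = lam,
                 water_fraction = water_fraction,
                 evaporation_band = evaporation_band,
                 latent_heat = latent_heat),
            class = "tissue_model")
}

#' Blood / perfusion model
#'
#' Parameters of the Pennes perfusion sink `omega_b * rho_b * cp_b * (T_b - T)`.
#' The distributed rate is modulated by accumulated Arrhenius damage
#' (perfusion ceases as tissue coagulates) and, on the segmented vasculature,
#' enhanced by a constant factor (default 50) accounting for the lower flow
#' resistance of larger vessels relative to the capillary bed.
#'
#' @param omega0 baseline distributed perfusion rate, 1/s.
#' @param rho_b blood density, kg/m^3.
#' @param cp_b blood specific heat, J/(kg K).
#' @param T_b arterial blood temperature, Celsius.
#' @param vessel_enhancement multiplicative enhancement on vessel voxels.
#' @param shutdown damage-coupling rule: `"exp"` for `omega0 * exp(-Omega)`
#'   (smooth cessation) or `"step"` for a hard stop at `Omega >= 1`.
#' @return object of class `blood_model`.
#' @export
blood_model <- function(omega0 = 0.0045, rho_b = 1060, cp_b = 3617,
                        T_b = 37, vessel_enhancement = 50,
                        shutdown = c("exp", "step")) {
  shutdown <- match.arg(shutdown)
  stopifnot(omega0 >= 0, rho_b > 0, cp_b > 0, vessel_enhancement >= 1)
  structure(list(omega0 = omega0, rho_b = rho_b, cp_b = cp_b, T_b = T_b,
                 vessel_enhancement = vessel_enhancement, shutdown = shutdown),
            class = "blood_model")
}

#' Arrhenius damage parameters
#'
#' Cumulative thermal damage `Omega = integral of A * exp(-Ea / (R T))` with T
#' in kelvin; `Omega >= threshold` defines ablated (coagulated) tissue. The
#' default threshold 1 corresponds to the 63.2% protein-denaturation
#' convention. Default A and Ea are standard liver coagulation values.
#'
#' @param A frequency factor, 1/s.
#' @param Ea activation energy, J/mol.
#' @param R universal gas constant, J/(mol K).
#' @param threshold damage value defining the ablation boundary.
#' @return object of class `damage_params`.
#' @export
damage_params <- function(A = 7.39e39, Ea = 2.577e5, R = 8.314,
                          threshold = 1) {
  stopifnot(A > 0, Ea > 0, R > 0, threshold > 0)
  structure(list(A = A, Ea = Ea, R = R, threshold = threshold),
            class = "damage_params")
}

#' Bioheat solver configuration
#'
#' @param dt time step in seconds, or `NULL` to choose automatically from the
#'   explicit diffusive stability bound (with a 0.9 safety factor).
#' @param scheme `"explicit"` (enthalpy-form forward stepping with exact
#'   perfusion relaxation) or `"implicit"` (backward Euler with lagged
#'   coefficients; unconditionally stable, intended for verification on small
#'   grids).
#' @param boundary `"dirichlet"` (outer faces held at `boundary_T`, suitable
#'   when the domain boundary is far from the ablation) or `"insulated"`
#'   (zero flux; used for conservation testing).
#' @param boundary_T Dirichlet face temperature, Celsius.
#' @param T_init initial tissue temperature, Celsius.
#' @param vessel_sink_enabled apply the vessel perfusion enhancement?
#' @param snapshot_interval_s interval at which temperature snapshots are
#'   retained by [simulate_case()] (`Inf` keeps only the final field).
#' @return object of class `solver_config`.
#' @export
solver_config <- function(dt = NULL, scheme = c("explicit", "implicit"),
                          boundary = c("dirichlet", "insulated"),
                          boundary_T = 37, T_init = 37,
                          vessel_sink_enabled = TRUE,
                          snapshot_interval_s = Inf) {
  scheme <- match.arg(scheme)
  boundary <- match.arg(boundary)
  if (!is.null(dt) && dt <= 0) stop("dt must be positive")
  structure(list(dt = dt, scheme = scheme, boundary = boundary,
                 boundary_T = boundary_T, T_init = T_init,
                 vessel_sink_enabled = isTRUE(vessel_sink_enabled),
                 snapshot_interval_s = snapshot_interval_s),
            class = "solver_config")
}

#' Temperature field constructor
#' @param grid a [voxel_grid()].
#' @param values Celsius, scalar or array of grid shape.
#' @param time simulation time, seconds.
#' @export
temperature_field <- function(grid, values = 37, time = 0) {
  v <- if (length(values) == 1) array(values, dim = grid$shape) else values
  stopifnot(all(dim(v) == grid$shape))
  if (!all(is.finite(v))) stop("temperature field must be finite everywhere")
  structure(list(grid = grid, values = v, time = time),
            class = "temperature_field")
}

#' Damage field constructor
#' @param grid a [voxel_grid()].
#' @param omega cumulative Arrhenius damage, scalar or array of grid shape.
#' @export
damage_field <- function(grid, omega = 0) {
  v <- if (length(omega) == 1) array(omega, dim = grid$shape) else omega
  stopifnot(all(dim(v) == grid$shape))
  if (any(v < 0)) stop("damage must be nonnegative")
  structure(list(grid = grid, omega = v), class = "damage_field")
}

#' Effective heat capacity with water evaporation
#'
#' Outside the evaporation band the specific heat is `cp_base`; inside the
#' band `water_fraction * latent_heat` is spread uniformly, so the integral of
#' `Cp_eff - cp_base` over the band equals the latent heat of the tissue water
#' content.
#'
#' @param T temperature in Celsius (vector or array).
#' @param tissue a [tissue_model()].
#' @return effective specific heat, J/(kg K), same shape as `T`.
#' @export
effective_heat_capacity <- function(T, tissue) {
  stopifnot(all(is.finite(T)))
  b <- tissue$evaporation_band
  add <- tissue$water_fraction * tissue$latent_heat / (b[2] - b[1])
  out <- T * 0 + tissue$cp_base
  out[T > b[1] & T <= b[2]] <- tissue$cp_base + add
  out
}

# volumetric enthalpy (J/m^3) relative to 0 C, piecewise linear in T;
# the inverse recovers T from enthalpy. Used by the explicit scheme.
enthalpy_of_T <- function(T, tissue) {
  b <- tissue$evaporation_band
  cpe <- tissue$cp_base +
    tissue$water_fraction * tissue$latent_heat / (b[2] - b[1])
  r <- tissue$rho
  h <- r * tissue$cp_base * pmin(T, b[1])
  h <- h + r * cpe * pmin(pmax(T - b[1], 0), b[2] - b[1])
  h + r * tissue$cp_base * pmax(T - b[2], 0)
}

T_of_enthalpy <- function(H, tissue) {
  b <- tissue$evaporation_band
  cpe <- tissue$cp_base +
    tissue$water_fraction * tissue$latent_heat / (b[2] - b[1])
  r <- tissue$rho
  h1 <- r * tissue$cp_base * b[1]
  h2 <- h1 + r * cpe * (b[2] - b[1])
  out <- H / (r * tissue$cp_base)
  mid <- H > h1 & H <= h2
  out[mid] <- b[1] + (H[mid] - h1) / (r * cpe)
  hi <- H > h2
  out[hi] <- b[2] + (H[hi] - h2) / (r * tissue$cp_base)
  out
}

#' Damage-modulated perfusion rate field
#'
#' The distributed perfusion rate is `omega0 * g(Omega)` on liver voxels
#' (zero elsewhere), where `g` is the shutdown rule of the [blood_model()]
#' (`exp(-Omega)` by default: perfusion ceases smoothly as coagulation damage
#' accrues). On vessel voxels the rate is additionally multiplied by
#' `vessel_enhancement` when the sink is enabled.
#'
#' @param T a [temperature_field()].
#' @param damage a [damage_field()] on the same grid.
#' @param blood a [blood_model()].
#' @param vessel_mask logical array of vessel voxels (or `NULL` for none).
#' @param liver_mask logical array restricting perfusion (default: everywhere).
#' @param sink_enabled apply the vessel enhancement?
#' @return numeric array of perfusion rates, 1/s.
#' @export
perfusion_field <- function(T, damage, blood, vessel_mask = NULL,
                            liver_mask = NULL, sink_enabled = TRUE) {
  stop_if_grid_mismatch(T$grid, damage$grid)
  g <- if (blood$shutdown == "exp") exp(-damage$omega)
       else (damage$omega < 1) * 1
  om <- blood$omega0 * g
  if (!is.null(vessel_mask)) {
    stopifnot(all(dim(vessel_mask) == T$grid$shape))
    if (sink_enabled) om[vessel_mask] <- om[vessel_mask] * blood$vessel_enhancement
  }
  if (!is.null(liver_mask)) {
    stopifnot(all(dim(liver_mask) == T$grid$shape))
    om[!liver_mask] <- 0
  }
  om
}

# temperature-dependent absorption multiplier of the applicator source:
# sigmoid decay from 1 toward `floor` across the evaporation band
absorption_multiplier <- function(T, params) {
  params$absorption_floor + (1 - params$absorption_floor) /
    (1 + exp((T - params$absorption_Tmid) / params$absorption_width))
}
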