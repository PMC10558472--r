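tissue <- tissue_model()
blood <- blood_model()

test_that("uniform equilibrium is preserved to machine precision", {
  g <- centered_grid(9, 1)
  cfg <- solver_config(dt = 0.5, boundary = "dirichlet", boundary_T = 37)
  Tf <- temperature_field(g, 37)
  T1 <- step_temperature(Tf, 0, 0, tissue, blood, cfg)
  expect_equal(max(abs(T1$values - 37)), 0)
  expect_equal(T1$time, 0.5)
})

test_that("perfusion-only cooling follows the exact exponential", {
  g <- centered_grid(3, 1)
  t0 <- tissue_model(lam = 1e-12)  # conduction switched off
  cfg <- solver_config(dt = 2, boundary = "insulated", T_init = 80)
  a <- blood$omega0 * blood$rho_b * blood$cp_b / (t0$rho * t0$cp_base)
  Tf <- temperature_field(g, 80)
  Tf1 <- step_temperature(Tf, 0, blood$omega0, t0, blood, cfg)
  # single step: exponential relaxation factor, equal to (1 - a dt) + O((a dt)^2)
  expect_equal((Tf1$values[1] - 37) / (80 - 37), exp(-a * 2), tolerance = 1e-12)
  expect_equal((Tf1$values[1] - 37) / (80 - 37), 1 - a * 2, tolerance = 1e-4)
  # many steps still lie on the exact ODE solution
  for (i in 1:49) Tf1 <- step_temperature(Tf1, 0, blood$omega0, t0, blood, cfg)
  exact <- 37 + (80 - 37) * exp(-a * 100)
  expect_equal(Tf1$values[2], exact, tolerance = 1e-6 * abs(exact - 37))
})

slab_error <- function(h, dt, t_end = 400, omega = 0.02, Tw = 60, L = 20) {
  b <- blood_model(omega0 = omega)
  n <- round(L / h)
  g <- voxel_grid(c(n, 1, 1), c(h, 1, 1), origin = c(h / 2, 0, 0))
  cfg <- solver_config(dt = dt, boundary = "dirichlet", boundary_T = Tw,
                       T_init = Tw)
  Tf <- temperature_field(g, Tw)
  om <- array(omega, dim = g$shape)
  for (i in seq_len(ceiling(t_end / dt)))
    Tf <- step_temperature(Tf, 0, om, tissue, b, cfg)
  x <- grid_axes(g)$x
  delta <- sqrt(tissue$lam / (omega * b$rho_b * b$cp_b)) * 1000
  Tan <- b$T_b + (Tw - b$T_b) * cosh((x - L / 2) / delta) /
    cosh(L / 2 / delta)
  max(abs(Tf$values - Tan)) / (Tw - b$T_b)
}

test_that("steady perfused slab matches the cosh profile within 1%", {
  expect_lt(slab_error(h = 0.5, dt = 0.2), 0.01)
})

test_that("slab error decreases about second order under refinement", {
  e1 <- slab_error(h = 1, dt = 0.4)
  e2 <- slab_error(h = 0.5, dt = 0.1)
  expect_gt(e1 / e2, 2.5)
})

test_that("explicit stability violations are a configuration error", {
  g <- centered_grid(9, 1)
  cfg <- solver_config(dt = 10 * stable_dt(g, tissue))
  expect_error(step_temperature(temperature_field(g, 37), 0, 0, tissue,
                                blood, cfg), "stability")
})

test_that("adiabatic enthalpy rise equals the deposited energy", {
  g <- centered_grid(15, 1)
  cfg <- solver_config(dt = 0.9 * stable_dt(g, tissue),
                       boundary = "insulated", T_init = 37)
  plan <- applicator_plan(c(0, 0, 4), c(0, 0, 1), active_zone_length = 8)
  p <- source_params()
  Q <- source_field(plan, 25, params = p, grid = g)
  Tf <- temperature_field(g, 37)
  dV <- voxel_volume_mm3(g) * 1e-9
  dep <- 0
  for (i in 1:220) {
    Qi <- Q * mwaplan:::absorption_multiplier(Tf$values, p)
    dep <- dep + sum(Qi) * dV * cfg$dt
    Tf <- step_temperature(Tf, Qi, 0, tissue, blood, cfg)
  }
  expect_gt(max(Tf$values), 100)  # the band was crossed
  dH <- sum(mwaplan:::enthalpy_of_T(Tf$values, tissue) -
            mwaplan:::enthalpy_of_T(array(37, g$shape), tissue)) * dV
  expect_equal(dH, dep, tolerance = 0.01)
})

test_that("minimum principle holds for nonnegative sources", {
  g <- centered_grid(9, 2)
  cfg <- solver_config(dt = 0.8 * stable_dt(g, tissue), T_init = 37,
                       boundary = "dirichlet", boundary_T = 37)
  set.seed(21)
  Q <- array(runif(prod(g$shape), 0, 5e5), dim = g$shape)
  om <- array(runif(prod(g$shape), 0, 0.05), dim = g$shape)
  Tf <- temperature_field(g, 37)
  for (i in 1:40) {
    Tf <- step_temperature(Tf, Q, om, tissue, blood, cfg)
    expect_gte(min(Tf$values), 37 - 1e-9)
  }
})

test_that("implicit and explicit schemes agree on a reference case", {
  g <- centered_grid(15, 2)
  plan <- applicator_plan(c(0, 0, 5), c(0, 0, 1))
  Q <- source_field(plan, 15, grid = g)
  om <- array(blood$omega0, dim = g$shape)
  cfgE <- solver_config(dt = 0.5, scheme = "explicit")
  cfgI <- solver_config(dt = 0.5, scheme = "implicit")
  TE <- TI <- temperature_field(g, 37)
  for (i in 1:80) {
    TE <- step_temperature(TE, Q, om, tissue, blood, cfgE)
    TI <- step_temperature(TI, Q, om, tissue, blood, cfgI)
  }
  expect_gt(max(TE$values), 60)  # a real excursion was simulated
  expect_lt(max(abs(TE$values - TI$values)), 0.5)
})

test_that("the compiled loop reproduces the R stepper", {
  g <- centered_grid(13, 2)
  plan <- applicator_plan(c(0, 0, 5), c(0, 0, 1))
  p <- source_params()
  liver <- array(TRUE, g$shape)
  vessel <- array(FALSE, g$shape); vessel[6:8, 6:8, ] <- TRUE
  cfg <- solver_config(dt = 0.5, T_init = 37)
  res <- mwaplan:::run_single_ablation(g, plan, 20, 25, p, tissue, blood,
                                       cfg, liver, vessel)
  Q <- source_field(plan, 20, params = p, grid = g)
  Tf <- temperature_field(g, 37); dmg <- damage_field(g, 0)
  for (i in 1:50) {
    om <- perfusion_field(Tf, dmg, blood, vessel, liver)
    Qi <- Q * mwaplan:::absorption_multiplier(Tf$values, p)
    Tf <- step_temperature(Tf, Qi, om, tissue, blood, cfg)
    dmg <- arrhenius_update(dmg, Tf, 0.5)
  }
  expect_equal(res$T$values, Tf$values, tolerance = 1e-12)
  expect_equal(res$omega, dmg$omega, tolerance = 1e-12)
})

test_that("simulate_case handles zero power and sequential independence", {
  case <- simple_case(n = 17, h = 2, power = 0, duration_s = 60)
  sim <- simulate_case(case)
  expect_equal(max(abs(sim$ablations[[1]]$T_final$values - 37)), 0)
  expect_false(any(sim$union_mask))
  # a realistic setting produces a nonempty ablation
  case2 <- simple_case(n = 25, h = 2, power = 100, duration_s = 480)
  sim2 <- simulate_case(case2)
  expect_gt(sum(sim2$union_mask), 0)
  expect_identical(dim(tidy(sim2)), c(1L, 5L))
})

test_that("the vessel sink and its strength only shrink the ablation", {
  case <- simple_case(n = 25, h = 2, power = 90, duration_s = 300)
  case$vessel_mask <- mwaplan:::voxelize_segment(case$grid, c(-20, 4, 0),
                                                 c(20, 4, 0), 3) &
    case$liver_mask
  vol <- function(enh, sink = TRUE) {
    b <- blood_model(vessel_enhancement = enh)
    cfg <- solver_config(vessel_sink_enabled = sink)
    sum(simulate_case(case, blood = b, config = cfg)$union_mask)
  }
  v_off <- vol(50, sink = FALSE)
  vols <- c(vol(1), vol(10), vol(50))
  expect_lte(vols[1], v_off + 1e-9)
  expect_true(all(diff(vols) <= 0))
})
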