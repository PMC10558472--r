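test_that("Dice matches direct voxel counting and its boundary cases", {
  g <- centered_grid(10, 1)
  A <- array(FALSE, g$shape); A[2:3, 2, 2] <- TRUE; A[5, 5, 5] <- TRUE
  A[7, 7, 7] <- TRUE
  B <- array(FALSE, g$shape); B[2:3, 2, 2] <- TRUE; B[8, 8, 8] <- TRUE
  B[9, 9, 9] <- TRUE
  expect_equal(dice(A, B), 0.5)  # |A|=4, |B|=4, |A∩B|=2
  sph <- sphere_mask(g, 3)
  expect_equal(dice(sph, sph), 1)
  disj <- array(FALSE, g$shape); disj[1, 1, 1] <- TRUE
  expect_equal(dice(sph, disj), 0)
  expect_error(dice(array(FALSE, g$shape), array(FALSE, g$shape)),
               "undefined")
  # random masks agree exactly with the set-based oracle, symmetrically
  set.seed(3)
  for (i in 1:5) {
    X <- array(runif(1000) < 0.3, c(10, 10, 10))
    Y <- array(runif(1000) < 0.3, c(10, 10, 10))
    expect_identical(dice(X, Y), dice_oracle(X, Y))
    expect_identical(dice(X, Y), dice(Y, X))
  }
})

test_that("signed surface distances reproduce concentric-sphere geometry", {
  g <- centered_grid(41, 1)
  big <- sphere_mask(g, 15); small <- sphere_mask(g, 10)
  same <- signed_surface_distance(big, big, g)
  expect_equal(same$aae, 0)
  out <- signed_surface_distance(big, small, g)  # prediction encloses gt
  expect_equal(mean(out$distances), 5, tolerance = 0.25)
  expect_true(all(out$distances > 0))
  expect_equal(out$aae, 5, tolerance = 0.25)
  expect_lte(out$aae, out$max_abs)
  inn <- signed_surface_distance(small, big, g)  # gt extends beyond
  expect_equal(mean(inn$distances), -5, tolerance = 0.25)
  expect_true(all(inn$distances < 0))
  expect_error(signed_surface_distance(array(FALSE, g$shape), big, g),
               "nonempty")
})

test_that("dilating the prediction raises the mean signed distance", {
  g <- centered_grid(41, 1)
  gt <- sphere_mask(g, 10)
  means <- purrr::map_dbl(c(0, 2, 4), function(r) {
    pred <- if (r == 0) sphere_mask(g, 8) else
      dilate_mask(sphere_mask(g, 8), g, r)
    signed_surface_distance(pred, gt, g)$mean_signed
  })
  expect_true(all(diff(means) > 0))
})

test_that("vascular fraction counts vessel voxels inside the reference ellipsoid", {
  tb <- default_manufacturer_table()
  g <- centered_grid(41, 2)
  plan <- applicator_plan(c(0, 0, 5), c(0, 0, 1))
  none <- array(FALSE, g$shape)
  expect_equal(vascular_fraction(none, plan, 80, 300, tb, g), 0)
  expect_equal(vascular_fraction(!none, plan, 80, 300, tb, g), 1)
  # engineered crossing cylinder vs brute-force voxel counting
  ves <- mwaplan:::voxelize_segment(g, c(-40, 3, 0), c(40, 3, 0), 4)
  d <- manufacturer_lookup(tb, 80, 300)
  ell <- mwaplan:::voxelize_spheroid(g, plan$active_zone_center,
                                     d[["length_mm"]], d[["diameter_mm"]],
                                     plan$direction)
  expect_equal(vascular_fraction(ves, plan, 80, 300, tb, g),
               sum(ell & ves) / sum(ell), tolerance = 1e-9)
  # out-of-grid reference ellipsoid is a geometry error
  plan_edge <- applicator_plan(c(38, 0, 5), c(0, 0, 1))
  expect_error(vascular_fraction(ves, plan_edge, 80, 300, tb, g),
               "outside the grid")
})

test_that("vascular fraction is invariant under a joint rigid transform", {
  tb <- default_manufacturer_table()
  g <- centered_grid(41, 2)
  plan <- applicator_plan(c(0, 0, 5), c(0, 0, 1))
  ves <- mwaplan:::voxelize_segment(g, c(-40, 5, -2), c(40, 5, -2), 4)
  vf0 <- vascular_fraction(ves, plan, 90, 300, tb, g)
  # rotate vessels and applicator jointly by 90 degrees about z
  ves_rot <- perturb_alignment(ves, c(0, 0, 0), c(0, 0, 90), g)
  plan_rot <- applicator_plan(c(0, 0, 5), c(0, 0, 1))
  vf1 <- vascular_fraction(ves_rot, plan_rot, 90, 300, tb, g)
  expect_equal(vf1, vf0, tolerance = 0.01)
})

test_that("relative volume difference is plain voxel arithmetic", {
  g <- centered_grid(21, 1)
  gt <- sphere_mask(g, 6)
  expect_equal(relative_volume_difference(gt, gt), 0)
  expect_equal(relative_volume_difference(array(FALSE, g$shape), gt), 1)
  two <- array(FALSE, g$shape); two[which(gt)[1:10]] <- TRUE
  five <- array(FALSE, g$shape); five[which(gt)[1:20]] <- TRUE
  expect_equal(relative_volume_difference(five, two), 1)  # |pred| = 2 |gt|
  expect_error(relative_volume_difference(gt, array(FALSE, g$shape)),
               "empty")
})
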