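test_that("mask NIfTI round trips are exact across spacings", {
  set.seed(12)
  for (h in c(0.5, 1, 2)) {
    g <- voxel_grid(c(12, 10, 9), h, origin = c(-3, 2, 1))
    m <- array(runif(prod(g$shape)) > 0.5, dim = g$shape)
    f <- withr::local_tempfile(fileext = ".nii.gz")
    write_mask(m, g, f)
    back <- read_mask(f)
    expect_identical(back$mask, m)
    expect_true(same_grid(back$grid, g))
  }
})

test_that("oblique NIfTI affines are rejected with guidance", {
  img <- RNifti::asNifti(array(0L, dim = c(4, 4, 4)))
  aff <- rbind(cbind(matrix(c(1, 0.3, 0, -0.3, 1, 0, 0, 0, 1), 3),
                     c(0, 0, 0)), c(0, 0, 0, 1))
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, f)
  expect_error(read_mask(f), "oblique")
})

test_that("run configurations hash everything except output paths", {
  c1 <- run_config(list(n_cases = 3, seed = 5))
  c2 <- run_config(list(n_cases = 3, seed = 5, out_dir = "elsewhere"))
  c3 <- run_config(list(n_cases = 3, seed = 6))
  expect_identical(c1$hash, c2$hash)
  expect_false(identical(c1$hash, c3$hash))
  # YAML round trip
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(n_cases = 3, seed = 5, blood = list(omega0 = 0.006)),
                   f)
  cy <- run_config(f)
  expect_identical(cy$blood$omega0, 0.006)
  expect_identical(cy$n_cases, 3L)
})

test_that("a case evaluated against its own prediction is perfect", {
  cfg <- run_config(list(n_cases = 1, seed = 3, sink_enabled = FALSE))
  # liver large enough that the ablation stays strictly interior
  case <- simple_case(n = 29, h = 2, power = 80, duration_s = 180)
  sim <- simulate_case(case, cfg$tissue, cfg$blood,
                       mwaplan:::solver_from_config(cfg), cfg$source, cfg$dp)
  case <- synthesize_ground_truth(case, sim$union_mask, "none")
  res <- run_case(cfg, case)
  expect_equal(res$record$dice_model, 1)
  expect_equal(res$record$aae_model, 0)
  expect_equal(res$record$rel_vol_diff_model, 0)
})

test_that("case outputs are deterministic and structurally complete", {
  cfg <- run_config(list(n_cases = 1, seed = 11, sink_enabled = TRUE))
  case <- simple_case(n = 23, h = 2, power = 80, duration_s = 240)
  # two ablations: duplicate the plan with an offset
  case$plans[[2]] <- applicator_plan(c(8, 0, 5), c(0, 0, 1))
  case$settings <- tibble::tibble(power_W = c(80, 90),
                                  duration_s = c(240, 180))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  res1 <- run_case(cfg, case, out_dir = d1)
  res2 <- run_case(cfg, case, out_dir = d2)
  j1 <- file.path(d1, "case_metrics.json"); j2 <- file.path(d2, "case_metrics.json")
  expect_true(file.exists(j1))
  expect_identical(readBin(j1, "raw", file.size(j1)),
                   readBin(j2, "raw", file.size(j2)))
  manifest <- jsonlite::read_json(j1, simplifyVector = TRUE)
  expect_length(manifest$per_ablation_volumes_ml, 2)
  expect_identical(manifest$config_hash, cfg$hash)
  expect_gte(res1$record$volume_model_ml,
             max(res1$per_ablation_volumes_ml))
  expect_true(file.exists(file.path(d1, "case_prediction.nii.gz")))
})

test_that("small cohorts run clean, rerun identically, and log failures", {
  cfg <- run_config(list(n_cases = 3, seed = 21,
                         cohort = list(misalignment_rate = 0,
                                       wedge_rate = 0)))
  r1 <- run_cohort(cfg)
  expect_identical(nrow(r1$table), 3L)
  expect_identical(nrow(r1$failures), 0L)
  r2 <- run_cohort(cfg)
  expect_identical(r1$table, r2$table)
  # a poisoned case (setting outside the manufacturer table) is logged,
  # the rest of the cohort continues
  cases <- sample_cohort(3, 21, cfg$cohort)
  cases[[2]]$settings$power_W[1] <- 250
  r3 <- run_cohort(cfg, cases = cases)
  expect_identical(nrow(r3$table), 2L)
  expect_identical(nrow(r3$failures), 1L)
  expect_match(r3$failures$error, "power")
})

test_that("cohort runs resume from written case manifests", {
  cfg <- run_config(list(n_cases = 2, seed = 31,
                         cohort = list(misalignment_rate = 0,
                                       wedge_rate = 0)))
  d <- withr::local_tempdir()
  r1 <- run_cohort(cfg, out_dir = d)
  expect_true(file.exists(file.path(d, "cohort_table.csv")))
  expect_true(file.exists(file.path(d, "scatter_volume.csv")))
  t0 <- Sys.time()
  r2 <- run_cohort(cfg, out_dir = d)  # all cases reused from disk
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 30)
  expect_equal(r2$table$volume_model_ml, r1$table$volume_model_ml)
})
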