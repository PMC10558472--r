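#' Write a binary mask as NIfTI
#'
#' Axis-aligned affine built from the grid spacing and origin; values are
#' stored as 0/1 integers so the round trip is exact.
#'
#' @param mask logical array.
#' @param grid the [voxel_grid()].
#' @param path output `.nii` / `.nii.gz` path.
#' @return the path, invisibly.
#' @export
write_mask <- function(mask, grid, path) {
  stopifnot(all(dim(mask) == grid$shape))
  img <- RNifti::asNifti(array(as.integer(mask), dim = grid$shape))
  RNifti::pixdim(img) <- grid$spacing
  aff <- rbind(cbind(diag(grid$spacing), grid$origin), c(0, 0, 0, 1))
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a binary mask from NIfTI
#'
#' Only axis-aligned affines (diagonal 3x3 part, positive spacings) are
#' accepted; oblique orientations are rejected with guidance rather than
#' silently resampled.
#'
#' @param path NIfTI file.
#' @param tol relative tolerance on the off-diagonal affine entries.
#' @return list with `mask` (logical array) and `grid` ([voxel_grid()]).
#' @export
read_mask <- function(path, tol = 1e-4) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  rot <- aff[1:3, 1:3]
  sp <- sqrt(colSums(rot^2))
  off <- rot - diag(diag(rot))
  if (any(abs(off) > tol * max(sp)) || any(diag(rot) <= 0))
    stop("NIfTI affine is oblique or axis-flipped; resample the image to an ",
         "axis-aligned grid with positive spacings before loading")
  grid <- voxel_grid(dim(img)[1:3], spacing = diag(rot),
                     origin = aff[1:3, 4])
  list(mask = array(as.array(img) != 0, dim = grid$shape), grid = grid)
}

#' Assemble a run configuration
#'
#' Collects all tunable blocks of the retrospective pipeline. Accepts a
#' named list or a YAML/JSON file path; unspecified blocks fall back to the
#' package defaults. The configuration hash (over everything except output
#' paths) and the seed are embedded in every output manifest.
#'
#' @param x named list, YAML/JSON path, or `NULL` for all defaults.
#' @param seed integer seed overriding the configured one.
#' @return object of class `run_config`.
#' @export
run_config <- function(x = NULL, seed = NULL) {
  if (is.character(x)) {
    x <- if (grepl("[.]ya?ml$", x)) yaml::read_yaml(x)
         else jsonlite::read_json(x, simplifyVector = TRUE)
  }
  x <- x %||% list()
  cfg <- list(
    seed = as.integer(x$seed %||% 1L),
    n_cases = as.integer(x$n_cases %||% 20L),
    sink_enabled = x$sink_enabled %||% TRUE,
    tissue = do.call(tissue_model, x$tissue %||% list()),
    blood = do.call(blood_model, x$blood %||% list()),
    dp = do.call(damage_params, x$damage %||% list()),
    source = do.call(source_params, x$source %||% list()),
    solver = x$solver %||% list(),
    cohort = do.call(cohort_config, x$cohort %||% list()),
    gt_indent_mm = x$gt_indent_mm %||% 3,
    out_dir = x$out_dir %||% NULL)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  hash_input <- cfg[setdiff(names(cfg), "out_dir")]
  cfg$hash <- rlang::hash(hash_input)
  structure(cfg, class = "run_config")
}

solver_from_config <- function(cfg) {
  args <- cfg$solver
  args$vessel_sink_enabled <- cfg$sink_enabled
  do.call(solver_config, args)
}

# manufacturer baseline prediction: union of lookup spheroids on each plan
manufacturer_baseline_mask <- function(case, table) {
  masks <- purrr::map(seq_along(case$plans), function(i) {
    d <- manufacturer_lookup(table, case$settings$power_W[i],
                             case$settings$duration_s[i])
    voxelize_spheroid(case$grid, case$plans[[i]]$active_zone_center,
                      d[["length_mm"]], d[["diameter_mm"]],
                      case$plans[[i]]$direction)
  })
  unite_ablations(masks)
}

# per-case vascular fraction: maximum over the per-ablation reference
# ellipsoids (one value per case, as cohorts report it)
case_vascular_fraction <- function(case, table) {
  max(purrr::map_dbl(seq_along(case$plans), function(i)
    vascular_fraction(case$vessel_mask, case$plans[[i]],
                      case$settings$power_W[i], case$settings$duration_s[i],
                      table, case$grid)))
}

#' Run the full pipeline on one case
#'
#' Simulates every planned ablation, unites the per-ablation masks, builds
#' the manufacturer baseline (the union of tabulated ellipsoids placed on
#' each plan), and computes all per-case metrics against the ground truth
#' when one is present. Optionally writes the masks as NIfTI plus a JSON
#' manifest embedding the configuration hash and seed.
#'
#' @param config a [run_config()].
#' @param case a [phantom_case()].
#' @param table a [manufacturer_table()] (default: bundled synthetic table).
#' @param out_dir optional output directory.
#' @return object of class `case_result`: `record` (one-row tibble),
#'   `pred_mask`, `manufacturer_mask`, `simulation`.
#' @export
run_case <- function(config, case, table = NULL, out_dir = NULL) {
  if (is.null(table)) table <- config$cohort$table %||%
      default_manufacturer_table()
  sim <- simulate_case(case, config$tissue, config$blood,
                       solver_from_config(config), config$source, config$dp)
  pred <- sim$union_mask
  manu <- manufacturer_baseline_mask(case, table)
  vf <- case_vascular_fraction(case, table)
  rec <- tibble::tibble(
    case_id = case$id, n_ablations = length(case$plans),
    vascular_fraction = vf,
    volume_model_ml = mask_volume_ml(pred, case$grid),
    volume_manufacturer_ml = mask_volume_ml(manu, case$grid),
    sink_enabled = config$sink_enabled,
    gt_overestimated = isTRUE(case$flags$gt_overestimated),
    misaligned = isTRUE(case$flags$misaligned),
    seed = config$seed, config_hash = config$hash)
  if (!is.null(case$ground_truth_mask) && any(case$ground_truth_mask)) {
    mm <- case_metrics(pred, case$ground_truth_mask, case$grid)
    mb <- case_metrics(manu, case$ground_truth_mask, case$grid)
    rec$gt_volume_ml <- mm$gt_volume_ml
    rec$dice_model <- mm$dice; rec$dice_manufacturer <- mb$dice
    rec$aae_model <- mm$aae_mm; rec$aae_manufacturer <- mb$aae_mm
    rec$max_abs_model <- mm$max_abs_mm
    rec$max_abs_manufacturer <- mb$max_abs_mm
    rec$rel_vol_diff_model <- mm$rel_vol_diff
    rec$rel_vol_diff_manufacturer <- mb$rel_vol_diff
  }
  res <- structure(list(record = rec, pred_mask = pred,
                        manufacturer_mask = manu, simulation = sim,
                        per_ablation_volumes_ml =
                          purrr::map_dbl(sim$ablations,
                                         ~ mask_volume_ml(.x$mask, case$grid))),
                   class = "case_result")
  if (!is.null(out_dir)) write_case_result(res, case, config, out_dir)
  res
}

write_case_result <- function(res, case, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stem <- file.path(out_dir, case$id)
  write_mask(res$pred_mask, case$grid, paste0(stem, "_prediction.nii.gz"))
  write_mask(case$liver_mask, case$grid, paste0(stem, "_liver.nii.gz"))
  write_mask(case$vessel_mask, case$grid, paste0(stem, "_vessels.nii.gz"))
  if (!is.null(case$ground_truth_mask))
    write_mask(case$ground_truth_mask, case$grid,
               paste0(stem, "_ground_truth.nii.gz"))
  manifest <- c(as.list(res$record),
                list(per_ablation_volumes_ml = res$per_ablation_volumes_ml,
                     settings = case$settings,
                     damage_params = unclass(config$dp),
                     package_version =
                       as.character(utils::packageVersion("mwaplan"))))
  jsonlite::write_json(manifest, paste0(stem, "_metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(stem)
}

# ground truth for a synthetic cohort case: sink-enabled model prediction,
# vessel-indent distortion, then the case's artifact injectors
synthesize_case_ground_truth <- function(case, config) {
  cfg_on <- config
  cfg_on$sink_enabled <- TRUE
  sim <- simulate_case(case, cfg_on$tissue, cfg_on$blood,
                       solver_from_config(cfg_on), cfg_on$source, cfg_on$dp)
  case <- synthesize_ground_truth(case, sim$union_mask,
                                  distortion = "vessel_indent",
                                  indent_mm = config$gt_indent_mm)
  wedge_flag <- isTRUE(case$flags$gt_overestimated)
  misalign_flag <- isTRUE(case$flags$misaligned)
  if (wedge_flag && any(case$ground_truth_mask)) {
    surf <- surface_voxels(case$ground_truth_mask)
    if (any(surf)) {
      capsule <- surface_voxels(case$liver_mask)
      dcap <- distance_transform(capsule, case$grid)
      co <- grid_coord_arrays(case$grid)
      k <- which(surf)[which.min(dcap[surf])]
      apex <- c(co$x[k], co$y[k], co$z[k])
      case$flags$gt_overestimated <- FALSE  # re-set by the injector
      case <- inject_infarction_wedge(case, apex)
    }
  }
  if (misalign_flag && any(case$ground_truth_mask)) {
    shift <- withr::with_seed(case$seed,
                              stats::rnorm(3) * c(3, 3, 3))
    gt <- perturb_alignment(case$ground_truth_mask, shift, c(2, -2, 3),
                            case$grid)
    case$ground_truth_mask <- gt & case$liver_mask
  }
  list(case = case, sink_on_sim = sim)
}

#' Run the retrospective pipeline on a synthetic cohort
#'
#' Samples a cohort, synthesizes per-case ground truths (sink-enabled
#' prediction with vessel-indent distortion plus the flagged artifacts),
#' runs every case, and aggregates the cohort statistics. A single seed
#' reproduces everything; per-case failures are logged and the cohort
#' continues.
#'
#' @param config a [run_config()] (its `n_cases`, `seed`, `sink_enabled`
#'   and parameter blocks drive the run).
#' @param cases optional pre-sampled list of [phantom_case()] (skips
#'   sampling).
#' @param out_dir optional output directory for per-case files, tables,
#'   summaries and figures. When given, finished cases found on disk with a
#'   matching configuration hash are reused (resumability).
#' @return object of class `mwa_cohort_result`: `table` (tibble of class
#'   `mwa_cohort`), `summaries`, `identity_test`, `failures`, `config`.
#' @export
run_cohort <- function(config, cases = NULL, out_dir = config$out_dir) {
  table <- config$cohort$table %||% default_manufacturer_table()
  config$cohort$table <- table
  if (is.null(cases))
    cases <- sample_cohort(config$n_cases, config$seed, config$cohort)
  records <- list(); failures <- list()
  for (case in cases) {
    manifest <- if (!is.null(out_dir))
      file.path(out_dir, paste0(case$id, "_metrics.json")) else NULL
    if (!is.null(manifest) && file.exists(manifest)) {
      prev <- jsonlite::read_json(manifest, simplifyVector = TRUE)
      if (identical(prev$config_hash, config$hash)) {
        records[[case$id]] <- tibble::as_tibble(
          prev[setdiff(names(prev), c("per_ablation_volumes_ml", "settings",
                                      "damage_params", "package_version"))])
        next
      }
    }
    res <- tryCatch({
      gt <- synthesize_case_ground_truth(case, config)
      case <- gt$case
      if (config$sink_enabled) {
        # reuse the sink-enabled simulation made for the ground truth
        run_case_from_sim(config, case, gt$sink_on_sim, table, out_dir)
      } else {
        run_case(config, case, table, out_dir)
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[case$id]] <- tibble::tibble(case_id = case$id,
                                            error = conditionMessage(res))
    } else {
      records[[case$id]] <- res$record
    }
  }
  tab <- dplyr::bind_rows(records)
  class(tab) <- c("mwa_cohort", class(tab))
  out <- structure(list(table = tab,
                        summaries = if (nrow(tab) > 0) summarize_cohort(tab),
                        identity_test = tryCatch(cohort_identity_test(tab),
                                                 error = function(e) NULL),
                        failures = dplyr::bind_rows(failures),
                        config = config),
                   class = "mwa_cohort_result")
  if (!is.null(out_dir)) write_cohort_outputs(out, out_dir)
  out
}

# run_case but with the model simulation already available
run_case_from_sim <- function(config, case, sim, table, out_dir = NULL) {
  pred <- sim$union_mask
  manu <- manufacturer_baseline_mask(case, table)
  vf <- case_vascular_fraction(case, table)
  rec <- tibble::tibble(
    case_id = case$id, n_ablations = length(case$plans),
    vascular_fraction = vf,
    volume_model_ml = mask_volume_ml(pred, case$grid),
    volume_manufacturer_ml = mask_volume_ml(manu, case$grid),
    sink_enabled = config$sink_enabled,
    gt_overestimated = isTRUE(case$flags$gt_overestimated),
    misaligned = isTRUE(case$flags$misaligned),
    seed = config$seed, config_hash = config$hash)
  if (!is.null(case$ground_truth_mask) && any(case$ground_truth_mask)) {
    mm <- case_metrics(pred, case$ground_truth_mask, case$grid)
    mb <- case_metrics(manu, case$ground_truth_mask, case$grid)
    rec$gt_volume_ml <- mm$gt_volume_ml
    rec$dice_model <- mm$dice; rec$dice_manufacturer <- mb$dice
    rec$aae_model <- mm$aae_mm; rec$aae_manufacturer <- mb$aae_mm
    rec$max_abs_model <- mm$max_abs_mm
    rec$max_abs_manufacturer <- mb$max_abs_mm
    rec$rel_vol_diff_model <- mm$rel_vol_diff
    rec$rel_vol_diff_manufacturer <- mb$rel_vol_diff
  }
  res <- structure(list(record = rec, pred_mask = pred,
                        manufacturer_mask = manu, simulation = sim,
                        per_ablation_volumes_ml =
                          purrr::map_dbl(sim$ablations,
                                         ~ mask_volume_ml(.x$mask, case$grid))),
                   class = "case_result")
  if (!is.null(out_dir)) write_case_result(res, case, config, out_dir)
  res
}

write_cohort_outputs <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(out$table, file.path(out_dir, "cohort_table.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(config_hash = out$config$hash, seed = out$config$seed,
         summaries = out$summaries, identity_test = out$identity_test,
         n_failures = nrow(out$failures)),
    file.path(out_dir, "cohort_summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (nrow(out$table) > 0) {
    for (mode in c("volume", "rel_diff", "dice_vs_vf")) {
      sr <- scatter_report(out$table, mode)
      ggplot2::ggsave(file.path(out_dir, paste0("scatter_", mode, ".png")),
                      sr$plot, width = 6, height = 5, dpi = 150)
      utils::write.csv(sr$data,
                       file.path(out_dir, paste0("scatter_", mode, ".csv")),
                       row.names = FALSE)
    }
  }
  invisible(out_dir)
}

#' @export
print.mwa_cohort_result <- function(x, ...) {
  cat(sprintf("<mwa_cohort_result> %d case(s), %d failure(s), sink %s\n",
              nrow(x$table), nrow(x$failures),
              if (x$config$sink_enabled) "on" else "off"))
  invisible(x)
}

#' One-row cohort summary
#' @param x an `mwa_cohort_result`.
#' @param ... unused.
#' @export
glance.mwa_cohort_result <- function(x, ...) {
  tb <- x$table
  tibble::tibble(
    n_cases = nrow(tb), n_failures = nrow(x$failures),
    pearson_r_volumes = stats::cor(tb$volume_model_ml,
                                   tb$volume_manufacturer_ml),
    median_dice_model = stats::median(tb$dice_model, na.rm = TRUE),
    median_aae_model = stats::median(tb$aae_model, na.rm = TRUE),
    sink_enabled = x$config$sink_enabled)
}
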