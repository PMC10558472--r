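test_that("identity-line distance is the relative deviation from y = x", {
  expect_equal(identity_line_distance(1, 1), 0)
  expect_equal(identity_line_distance(1.5, 1.0), 0.5)
  expect_equal(identity_line_distance(c(2, 3), c(4, 2)), c(-0.5, 0.5))
  expect_error(identity_line_distance(1, 0), "x = 0")
})

test_that("Tukey two-group test is calibrated under the null and powered", {
  set.seed(101)
  null_cover <- mean(purrr::map_lgl(1:100, function(i) {
    v <- rnorm(16)
    g <- rep(c(TRUE, FALSE), each = 8)
    !tukey_two_group(v, g)$significant
  }))
  expect_gte(null_cover, 0.9)
  # ten pooled standard deviations apart is always detected
  set.seed(7)
  v <- c(rnorm(10, 0, 1), rnorm(10, 10, 1))
  res <- tukey_two_group(v, rep(c(FALSE, TRUE), each = 10))
  expect_true(res$significant)
  expect_gt(res$lwr, 0)
  expect_error(tukey_two_group(c(1, 2, 3), c(TRUE, FALSE, FALSE)),
               "at least 2")
  expect_error(tukey_two_group(1:4, rep(TRUE, 4)), "two levels")
})

test_that("two-group Tukey agrees with a permutation oracle", {
  set.seed(202)
  agree <- purrr::map_lgl(1:40, function(i) {
    n <- sample(4:6, 1)
    shift <- sample(c(0, 0, 2.5), 1)
    v <- c(rnorm(n), rnorm(n, shift))
    g <- rep(c(FALSE, TRUE), each = n)
    tk <- tukey_two_group(v, g)
    obs <- abs(mean(v[g]) - mean(v[!g]))
    perm <- purrr::map_dbl(1:2000, function(j) {
      gp <- sample(g)
      abs(mean(v[gp]) - mean(v[!gp]))
    })
    p_perm <- mean(perm >= obs - 1e-12)
    (p_perm < 0.05) == tk$significant
  })
  expect_gte(mean(agree), 0.9)
})

make_table <- function(n = 5, delta = 0) {
  tibble::tibble(
    case_id = sprintf("C%02d", seq_len(n)),
    vascular_fraction = seq(0, 0.2, length.out = n),
    volume_model_ml = seq(20, 40, length.out = n),
    volume_manufacturer_ml = seq(20, 40, length.out = n),
    rel_vol_diff_model = seq(0.1, 0.5, length.out = n) + delta,
    rel_vol_diff_manufacturer = seq(0.1, 0.5, length.out = n),
    aae_model = seq(1, 3, length.out = n) + delta,
    aae_manufacturer = seq(1, 3, length.out = n),
    dice_model = seq(0.6, 0.9, length.out = n) + delta,
    dice_manufacturer = seq(0.6, 0.9, length.out = n),
    gt_overestimated = FALSE, misaligned = FALSE)
}

test_that("exclusion criteria drop exactly the flagged rows", {
  tb <- make_table(21)
  expect_identical(nrow(apply_exclusions(tb)), 21L)
  tb$gt_overestimated[1:2] <- TRUE
  tb$misaligned[3] <- TRUE
  out <- apply_exclusions(tb)
  expect_identical(nrow(out), 18L)
  expect_identical(attr(out, "n_removed"), 3L)
  only_mis <- apply_exclusions(tb, "misaligned")
  expect_identical(nrow(only_mis), 20L)
  tb$misaligned <- TRUE
  expect_warning(apply_exclusions(tb), "all cases removed")
})

test_that("cohort summaries match hand-computed five-number statistics", {
  tb <- make_table(5)
  s <- summarize_cohort(tb)
  expect_true(all(s$paired$mean_difference == 0))
  aae_row <- dplyr::filter(s$five_number, indicator == "aae",
                           method == "model")
  bs <- grDevices::boxplot.stats(c(1, 1.5, 2, 2.5, 3))$stats
  expect_equal(unlist(aae_row[c("whisker_lo", "q1", "median", "q3",
                                "whisker_hi")], use.names = FALSE), bs)
  # permutation invariance over rows and the single-row degenerate case
  s2 <- summarize_cohort(tb[sample(5), ])
  expect_equal(s2$five_number, s$five_number)
  s1 <- summarize_cohort(make_table(1))
  expect_true(all(s1$five_number$median == s1$five_number$q1))
  expect_error(summarize_cohort(make_table(0)), "empty")
})

test_that("paired differences shift with a constant model offset", {
  s <- summarize_cohort(make_table(6, delta = 0.05))
  expect_equal(s$paired$mean_difference, rep(0.05, 3), tolerance = 1e-12)
})

test_that("scatter reports export exactly what they plot", {
  tb <- make_table(7)
  sr <- scatter_report(tb, "volume")
  expect_s3_class(sr$plot, "ggplot")
  expect_identical(nrow(sr$data), 7L)
  expect_true(all(identity_line_distance(sr$data$y, sr$data$x) == 0))
  sr2 <- scatter_report(tb, "dice_vs_vf")
  expect_identical(nrow(sr2$data), nrow(tb))  # one point per case
  f <- tempfile(fileext = ".csv")
  utils::write.csv(sr$data, f, row.names = FALSE)
  back <- utils::read.csv(f)
  expect_equal(back$x, sr$data$x)
  expect_equal(back$y, sr$data$y)
})

test_that("the cohort identity test reports the high-fraction contrast", {
  tb <- make_table(10)
  tb$vascular_fraction <- rep(c(0.01, 0.12), each = 5)
  tb$volume_model_ml <- tb$volume_manufacturer_ml *
    rep(c(1, 0.7), each = 5) + rep(c(0.01, -0.01), 5)
  res <- cohort_identity_test(tb)
  expect_true(res$significant)
  expect_lt(res$mean_high_group, 0)
  expect_lt(res$upr, 0)
})
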