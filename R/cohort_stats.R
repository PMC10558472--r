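#' Relative distance from the identity line
#'
#' For a scatter of predictions `y` against a reference `x`, the relative
#' deviation `(y - x) / x`; zero means the point lies on the identity line.
#'
#' @param y,x numeric vectors (recycled pairwise); `x` must be nonzero.
#' @return numeric vector of the same length.
#' @export
identity_line_distance <- function(y, x) {
  if (any(x == 0)) stop("identity-line distance undefined at x = 0")
  (y - x) / x
}

#' Tukey 95% range test between two groups
#'
#' Tukey's honestly-significant-difference confidence interval on the mean
#' difference of `values` between the two levels of `group`, via
#' `stats::aov` + `stats::TukeyHSD`. The difference is significant when the
#' interval excludes zero.
#'
#' @param values numeric vector.
#' @param group logical or two-level factor of the same length; the reported
#'   difference is `TRUE` (or second level) minus the other group.
#' @param alpha significance level (interval coverage `1 - alpha`).
#' @return one-row tibble: `diff`, `lwr`, `upr`, `p_adj`, `significant`,
#'   `n1`, `n2`.
#' @export
tukey_two_group <- function(values, group, alpha = 0.05) {
  stopifnot(length(values) == length(group))
  g <- factor(group)
  if (nlevels(g) != 2) stop("group must have exactly two levels")
  if (any(table(g) < 2))
    stop("each group needs at least 2 cases for the range test")
  fit <- stats::aov(values ~ g, data = data.frame(values = values, g = g))
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  tibble::tibble(diff = tk[1, "diff"], lwr = tk[1, "lwr"],
                 upr = tk[1, "upr"], p_adj = tk[1, "p adj"],
                 significant = tk[1, "lwr"] > 0 | tk[1, "upr"] < 0,
                 n1 = sum(g == levels(g)[1]), n2 = sum(g == levels(g)[2]))
}

#' Remove flagged cases from a cohort table
#'
#' Drops rows carrying any of the selected artifact flags (ground-truth
#' volume overestimated by infarction, or apparent applicator misalignment).
#'
#' @param table a cohort tibble with logical columns `gt_overestimated` and
#'   `misaligned`.
#' @param criteria character subset of `c("gt_overestimated", "misaligned")`.
#' @return the filtered tibble, with attribute `n_removed`; warns when every
#'   row is removed.
#' @export
apply_exclusions <- function(table,
                             criteria = c("gt_overestimated", "misaligned")) {
  criteria <- match.arg(criteria, several.ok = TRUE)
  stopifnot(all(criteria %in% names(table)))
  flagged <- rep(FALSE, nrow(table))
  for (cr in criteria) flagged <- flagged | table[[cr]]
  out <- table[!flagged, , drop = FALSE]
  if (nrow(out) == 0 && nrow(table) > 0)
    warning("all cases removed by the exclusion criteria")
  attr(out, "n_removed") <- sum(flagged)
  out
}

#' Whisker summaries and paired differences of cohort indicators
#'
#' For each performance indicator carried by both the biophysical model and
#' the manufacturer baseline (relative volume difference vs ground truth,
#' AAE, Dice), computes the five-number box-and-whisker summary per method
#' and the paired mean difference (model minus manufacturer).
#'
#' @param table a cohort tibble (see [run_cohort()]) with columns
#'   `rel_vol_diff_model`, `rel_vol_diff_manufacturer`, `aae_model`,
#'   `aae_manufacturer`, `dice_model`, `dice_manufacturer`.
#' @return list with tibbles `five_number` (indicator, method, whisker_lo,
#'   q1, median, q3, whisker_hi) and `paired` (indicator, mean_difference).
#' @export
summarize_cohort <- function(table) {
  if (nrow(table) == 0) stop("cannot summarize an empty cohort table")
  indicators <- c("rel_vol_diff", "aae", "dice")
  long <- tidyr::pivot_longer(
    table[paste0(rep(indicators, each = 2),
                 c("_model", "_manufacturer"))],
    dplyr::everything(),
    names_to = c("indicator", "method"),
    names_pattern = "(.*)_(model|manufacturer)")
  five <- dplyr::reframe(
    dplyr::group_by(long, .data$indicator, .data$method), {
      bs <- grDevices::boxplot.stats(.data$value)$stats
      tibble::tibble(whisker_lo = bs[1], q1 = bs[2], median = bs[3],
                     q3 = bs[4], whisker_hi = bs[5])
    })
  paired <- purrr::map_dfr(indicators, function(ind) {
    tibble::tibble(indicator = ind,
                   mean_difference = mean(table[[paste0(ind, "_model")]] -
                                          table[[paste0(ind, "_manufacturer")]]))
  })
  list(five_number = five, paired = paired)
}

#' Scatter report of cohort results
#'
#' Builds the cohort scatter figure and returns both the ggplot object and
#' the exact plotted points, so the figure can be reproduced from the data
#' export.
#'
#' @param table a cohort tibble (see [run_cohort()]).
#' @param mode `"volume"` (model vs manufacturer predicted volume, identity
#'   line), `"rel_diff"` (relative volume difference vs ground truth, model
#'   vs manufacturer, identity line), or `"dice_vs_vf"` (Dice difference
#'   model - manufacturer against vascular fraction, zero line).
#' @return list with elements `plot` (ggplot) and `data` (tibble of plotted
#'   points, one row per case).
#' @export
scatter_report <- function(table, mode = c("volume", "rel_diff",
                                           "dice_vs_vf")) {
  mode <- match.arg(mode)
  if (nrow(table) == 0) stop("empty cohort table")
  vf_grp <- factor(ifelse(table$vascular_fraction > 0.05,
                          "> 5%", "<= 5%"), levels = c("<= 5%", "> 5%"))
  if (mode == "volume") {
    dat <- tibble::tibble(case_id = table$case_id,
                          x = table$volume_manufacturer_ml,
                          y = table$volume_model_ml,
                          vascular_group = vf_grp)
    xl <- "manufacturer volume (mL)"; yl <- "model volume (mL)"
  } else if (mode == "rel_diff") {
    dat <- tibble::tibble(case_id = table$case_id,
                          x = table$rel_vol_diff_manufacturer,
                          y = table$rel_vol_diff_model,
                          vascular_group = vf_grp)
    xl <- "manufacturer |dV|/V_GT"; yl <- "model |dV|/V_GT"
  } else {
    dat <- tibble::tibble(case_id = table$case_id,
                          x = table$vascular_fraction,
                          y = table$dice_model - table$dice_manufacturer,
                          vascular_group = vf_grp)
    xl <- "vascular fraction"; yl <- "Dice difference (model - manufacturer)"
  }
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$y,
                                         colour = .data$vascular_group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = xl, y = yl, colour = "vascular fraction") +
    ggplot2::theme_minimal()
  p <- if (mode == "dice_vs_vf") {
    p + ggplot2::geom_hline(yintercept = 0, linetype = 2)
  } else {
    p + ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2)
  }
  list(plot = p, data = dat)
}

#' Cohort scatter autoplot
#' @param object a cohort tibble of class `mwa_cohort`.
#' @param mode see [scatter_report()].
#' @param ... unused.
#' @export
autoplot.mwa_cohort <- function(object, mode = "volume", ...) {
  scatter_report(object, mode)$plot
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tukey range test on a cohort's identity-line distances
#'
#' The pre-specified cohort contrast: relative distance from the identity
#' line of model vs manufacturer predicted volumes, compared between cases
#' with vascular fraction above the threshold and the rest of the cohort.
#'
#' @param table a cohort tibble (see [run_cohort()]).
#' @param vf_threshold vascular-fraction split point (default 5%).
#' @param alpha significance level.
#' @return one-row tibble as [tukey_two_group()], plus `vf_threshold` and
#'   `mean_high_group` (mean identity-line distance of the high-fraction
#'   group).
#' @export
cohort_identity_test <- function(table, vf_threshold = 0.05, alpha = 0.05) {
  d <- identity_line_distance(table$volume_model_ml,
                              table$volume_manufacturer_ml)
  grp <- table$vascular_fraction > vf_threshold
  res <- tukey_two_group(d, grp, alpha)
  res$vf_threshold <- vf_threshold
  res$mean_high_group <- mean(d[grp])
  res
}
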