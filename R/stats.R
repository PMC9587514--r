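#' Age-independent group comparison of a biomarker
#'
#' Two-sided Wilcoxon rank-sum test on the pooled (age-independent) values of
#' one metric between the control and knockout groups. The exact permutation
#' distribution is used whenever there are no ties and both groups are small
#' enough (the [stats::wilcox.test()] default); otherwise the normal
#' approximation with continuity correction.
#'
#' @param table a biomarker tibble with a `group` column.
#' @param metric metric column name.
#' @return One-row tibble: `metric`, group sizes, `statistic`, `p_value`.
#' @export
group_compare <- function(table, metric) {
  if (!metric %in% names(table)) abort(sprintf("no column `%s`", metric))
  g <- split(table[[metric]], table$group)
  if (length(g) != 2) abort("exactly two groups required")
  if (any(vapply(g, length, 1L) < 2)) abort("each group needs >= 2 observations")
  wt <- suppressWarnings(stats::wilcox.test(g[[1]], g[[2]]))
  tibble(metric = metric, n_a = length(g[[1]]), n_b = length(g[[2]]),
         statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Least-squares age trend of a biomarker
#'
#' Ordinary least squares of one metric on age (expressed in years, so
#' slopes are in units per year), with the 95% confidence half-width and the
#' two-sided t-test of zero slope.
#'
#' @param table a biomarker tibble with `age_months` (or `age_years`) and the
#'   metric column.
#' @param metric metric column name.
#' @param group optional group label to filter on.
#' @param conf_level confidence level for the interval.
#' @return An object of class `trend_fit`; see [tidy.trend_fit()].
#' @export
trend_fit <- function(table, metric, group = NULL, conf_level = 0.95) {
  if (!is.null(group)) table <- table[table$group == group, ]
  y <- table[[metric]]
  age <- if ("age_years" %in% names(table)) table$age_years
  else table$age_months / 12
  keep <- is.finite(y) & is.finite(age)
  y <- y[keep]; age <- age[keep]
  if (length(y) < 3) abort("need >= 3 points for a trend fit")
  if (diff(range(age)) == 0) abort("degenerate ages: all equal")
  fit <- lm(y ~ age)
  s <- summary(fit)$coefficients
  ci <- confint(fit, "age", level = conf_level)
  structure(list(
    lm = fit, metric = metric, group = group %||% NA_character_,
    n = length(y), slope = unname(coef(fit)["age"]),
    se = s["age", "Std. Error"],
    ci_half = unname(diff(ci[1, ]) / 2), conf_level = conf_level,
    p_slope = s["age", "Pr(>|t|)"], df = fit$df.residual,
    mean = mean(y), sd = sd(y)),
    class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf(
    "<trend_fit> %s%s: slope %.4g +/- %.4g per year (p = %.3g, n = %d)\n",
    x$metric, if (is.na(x$group)) "" else paste0(" [", x$group, "]"),
    x$slope, x$ci_half, x$p_slope, x$n))
  invisible(x)
}

#' Tidy a trend fit
#'
#' @param x a [trend_fit()].
#' @param ... unused.
#' @return `tidy()`: one-row tibble with the slope, its confidence
#'   half-width and p-value; `glance()`: fit-level summary.
#' @export
tidy.trend_fit <- function(x, ...) {
  tibble(metric = x$metric, group = x$group, slope_per_year = x$slope,
         ci_half = x$ci_half, p_slope = x$p_slope, n = x$n)
}

#' @rdname tidy.trend_fit
#' @export
glance.trend_fit <- function(x, ...) {
  s <- summary(x$lm)
  tibble(metric = x$metric, group = x$group, n = x$n,
         mean = x$mean, sd = x$sd, r_squared = s$r.squared,
         sigma = s$sigma, df_residual = x$df)
}

#' Compare the age slopes of two groups
#'
#' Two-sided t-test of the difference between two independently fitted
#' slopes, using the pooled standard error and Welch-Satterthwaite degrees
#' of freedom.
#'
#' @param fit_a,fit_b [trend_fit()] objects.
#' @return One-row tibble: `slope_diff`, `se`, `t`, `df`, `p_value`.
#' @export
slope_difference_test <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "trend_fit"), inherits(fit_b, "trend_fit"))
  se2 <- fit_a$se^2 + fit_b$se^2
  if (!is.finite(se2) || se2 <= 0) abort("missing residual information")
  t_stat <- (fit_a$slope - fit_b$slope) / sqrt(se2)
  df <- se2^2 / (fit_a$se^4 / fit_a$df + fit_b$se^4 / fit_b$df)
  tibble(slope_diff = fit_a$slope - fit_b$slope, se = sqrt(se2),
         t = t_stat, df = df, p_value = 2 * pt(-abs(t_stat), df))
}

#' Correlation between two biomarkers
#'
#' Pearson correlation with its two-sided p-value, plus the least-squares
#' regression slope of `metric_y` on `metric_x` with a 95% confidence
#' half-width.
#'
#' @param table a biomarker tibble.
#' @param metric_x,metric_y metric column names.
#' @param group optional group label to filter on.
#' @return One-row tibble: `r`, `p_value`, `slope`, `slope_ci_half`, `n`.
#' @export
metric_correlation <- function(table, metric_x, metric_y, group = NULL) {
  if (!is.null(group)) table <- table[table$group == group, ]
  x <- table[[metric_x]]; y <- table[[metric_y]]
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) abort("need >= 3 paired points")
  if (var(x) == 0 || var(y) == 0) abort("zero variance in a metric")
  ct <- stats::cor.test(x, y, method = "pearson")
  fit <- lm(y ~ x)
  ci <- confint(fit, "x")
  tibble(metric_x = metric_x, metric_y = metric_y,
         group = group %||% NA_character_,
         r = unname(ct$estimate), p_value = ct$p.value,
         slope = unname(coef(fit)["x"]),
         slope_ci_half = unname(diff(ci[1, ]) / 2), n = length(x))
}

#' Full per-metric group and trend summary
#'
#' For each biomarker: group means and standard deviations, the rank-sum
#' p-value between groups, each group's age slope with confidence half-width
#' and zero-slope p-value, and the slope-difference p-value -- the standard
#' longitudinal summary table.
#'
#' @param table a biomarker tibble with `group` and `age_months` columns.
#' @param metrics metric column names.
#' @return A tibble with one row per metric.
#' @export
biomarker_trend_table <- function(table,
                                  metrics = c("rc_ratio", "mean_1_dopu",
                                              "sscov_per_mm")) {
  groups <- sort(unique(table$group))
  if (length(groups) != 2) abort("exactly two groups required")
  purrr::map_dfr(metrics, function(m) {
    fits <- lapply(groups, function(g) trend_fit(table, m, g))
    gc <- group_compare(table, m)
    sd_test <- slope_difference_test(fits[[1]], fits[[2]])
    tibble(
      metric = m,
      mean_a = fits[[1]]$mean, sd_a = fits[[1]]$sd,
      mean_b = fits[[2]]$mean, sd_b = fits[[2]]$sd,
      p_group = gc$p_value,
      slope_a = fits[[1]]$slope, ci_a = fits[[1]]$ci_half,
      p_slope_a = fits[[1]]$p_slope,
      slope_b = fits[[2]]$slope, ci_b = fits[[2]]$ci_half,
      p_slope_b = fits[[2]]$p_slope,
      p_slope_diff = sd_test$p_value)
  })
}

#' Fast synthetic biomarker cohorts
#'
#' Direct tabular generator for calibrating the statistics layer (no image
#' simulation): per group, each eye's metric follows a linear age trend with
#' Gaussian noise around it.
#'
#' @param slopes named per-year slopes, one per group.
#' @param intercepts named intercepts (metric value at age 0), one per group.
#' @param noise_sd residual standard deviation of the metric.
#' @param eyes_per_group number of eyes per group.
#' @param ages_months acquisition ages.
#' @param metric name of the generated metric column.
#' @param seed RNG seed.
#' @return A biomarker tibble: `eye`, `group`, `age_months`, `age_years`,
#'   and the metric column.
#' @export
simulate_biomarker_table <- function(slopes = c(control = -0.69,
                                                knockout = -2.56),
                                     intercepts = c(control = 6.5,
                                                    knockout = 9.2),
                                     noise_sd = 0.75, eyes_per_group = 4,
                                     ages_months = seq(5, 17, length.out = 6),
                                     metric = "sscov_per_mm", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grid <- tidyr::crossing(group = names(slopes),
                          eye_i = seq_len(eyes_per_group),
                          age_months = ages_months)
  grid |>
    dplyr::mutate(
      eye = paste0(.data$group, "_eye", .data$eye_i),
      age_years = .data$age_months / 12,
      !!metric := intercepts[.data$group] +
        slopes[.data$group] * .data$age_years +
        stats::rnorm(dplyr::n(), sd = noise_sd)) |>
    dplyr::select(-"eye_i") |>
    dplyr::relocate("eye")
}
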