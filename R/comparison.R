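# ---- Precision and consistency diagnostics across estimators --------------

#' Coefficient of variation (percent)
#'
#' `100 * se / estimate`; `NA` (with a warning) where the estimate is not
#' strictly positive.
#'
#' @param estimate Point estimates.
#' @param se Their standard errors (or root MSEs).
#' @return Numeric vector of CVs in percent.
#' @export
coefficient_of_variation <- function(estimate, se) {
  stopifnot(length(estimate) == length(se))
  bad <- !is.na(estimate) & estimate <= 0
  if (any(bad))
    warning(sum(bad), " non-positive estimate(s): CV undefined",
            call. = FALSE)
  ifelse(bad, NA_real_, 100 * se / estimate)
}

#' Bias regression of model-based on direct estimates
#'
#' Ordinary least squares of the model-based series on the direct series
#' across districts. A slope near 1 (and high r-squared) indicates the
#' model-based estimates track the (design-unbiased) direct estimates; a
#' slope below 1 is the signature of shrinkage.
#'
#' @param model_est Model-based estimates.
#' @param direct_est Direct estimates, aligned by district.
#' @return List with `slope`, `intercept`, `r_squared`, `n` (complete
#'   pairs used).
#' @export
bias_regression <- function(model_est, direct_est) {
  ok <- stats::complete.cases(model_est, direct_est)
  if (sum(ok) < 3)
    stop("need at least 3 aligned districts", call. = FALSE)
  x <- direct_est[ok]
  y <- model_est[ok]
  if (stats::var(x) == 0)
    stop("direct estimates have zero variance", call. = FALSE)
  if (stats::var(y) == 0)  # constant model series: flat line, no fit
    return(list(slope = 0, intercept = mean(y), r_squared = 0, n = sum(ok)))
  fit <- stats::lm(y ~ x)
  r2 <- 1 - sum(stats::resid(fit)^2) / sum((y - mean(y))^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2, n = sum(ok))
}

#' Percent precision gain of a model-based estimator
#'
#' Per-district percent reduction in MSE relative to the direct estimator,
#' `100 * (1 - mse_model / mse_direct)`, and its mean across districts. The
#' direct estimator's MSE is taken to be its variance (design unbiasedness).
#'
#' @param mse_direct Direct-estimator variances (must be `> 0`).
#' @param mse_model Model-based MSEs, aligned by district.
#' @return List with `gain_pct` (per district) and `mean_gain_pct`.
#' @export
precision_gain <- function(mse_direct, mse_model) {
  stopifnot(length(mse_direct) == length(mse_model))
  if (any(mse_direct <= 0, na.rm = TRUE))
    stop("`mse_direct` must be strictly positive", call. = FALSE)
  g <- 100 * (1 - mse_model / mse_direct)
  list(gain_pct = g, mean_gain_pct = mean(g, na.rm = TRUE))
}

#' Classify districts as reliable by a CV threshold
#'
#' Counts districts whose coefficient of variation is strictly below the
#' threshold (default 20%), the conventional cut-off for estimates
#' considered reliable for decision-making.
#'
#' @param cv_pct Coefficients of variation in percent.
#' @param threshold Strict upper bound (default 20).
#' @return List with `n_reliable`, `n_total` (non-missing), `pct_reliable`.
#' @export
reliability_classification <- function(cv_pct, threshold = 20) {
  ok <- !is.na(cv_pct)
  n_rel <- sum(cv_pct[ok] < threshold)
  list(n_reliable = n_rel, n_total = sum(ok),
       pct_reliable = if (sum(ok)) 100 * n_rel / sum(ok) else NA_real_)
}

#' Seven-number summary of an estimate series
#'
#' Mean, SD, minimum, maximum and the three quartiles (linear-interpolation
#' type-7 quantiles), the summary used to compare estimate series across
#' methods.
#'
#' @param x Numeric series (missing values dropped).
#' @return Named numeric vector: `mean`, `sd`, `min`, `max`, `q1`, `q2`,
#'   `q3`.
#' @export
summary_table <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) stop("empty series", call. = FALSE)
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c(mean = mean(x), sd = stats::sd(x), min = min(x), max = max(x),
    q1 = q[1], q2 = q[2], q3 = q[3])
}

#' Compare direct, area-level and unit-level district estimates
#'
#' Aligns the three per-district estimate tables and computes the standard
#' SAE evaluation diagnostics: seven-number summaries of each series, CV summaries and
#' reliability fractions (CV < 20%), OLS bias regressions of each
#' model-based series on the direct series, and mean percent precision
#' gains (direct variance vs model MSE). Districts missing a series are
#' dropped pairwise per diagnostic; the number dropped is reported.
#'
#' @param direct A [direct_estimates()] table.
#' @param area An [fh_fit()] object or its `$estimates` table.
#' @param unit An [ebp_estimates()] table.
#' @param cv_threshold Reliability threshold in percent (default 20).
#' @return Object of class `"sae_comparison"`: list with `estimates` (the
#'   aligned per-district table), `summaries`, `cv_summaries`,
#'   `reliability`, `bias_regression`, `precision_gain`, `n_dropped`.
#' @export
compare_estimates <- function(direct, area, unit, cv_threshold = 20) {
  if (inherits(area, "fh_fit")) area <- area$estimates
  check_columns(direct, c("district_id", "p_hat", "se", "cv_pct"),
                "direct estimates")
  check_columns(area, c("district_id", "p_fh", "mse_p", "cv_pct"),
                "area-level estimates")
  check_columns(unit, c("district_id", "p_ebp", "mse_boot", "cv_pct"),
                "unit-level estimates")
  tab <- merge(merge(
    data.frame(district_id = direct$district_id, n_i = direct$n,
               p_direct = direct$p_hat, var_direct = direct$se^2,
               cv_direct = direct$cv_pct),
    data.frame(district_id = area$district_id, p_area = area$p_fh,
               mse_area = area$mse_p, cv_area = area$cv_pct),
    all = TRUE),
    data.frame(district_id = unit$district_id, p_unit = unit$p_ebp,
               mse_unit = unit$mse_boot, cv_unit = unit$cv_pct),
    all = TRUE)

  complete <- stats::complete.cases(tab[, c("p_direct", "p_area", "p_unit")])
  summaries <- rbind(direct = summary_table(tab$p_direct),
                     area = summary_table(tab$p_area),
                     unit = summary_table(tab$p_unit))
  cv_summaries <- rbind(direct = summary_table(tab$cv_direct),
                        area = summary_table(tab$cv_area),
                        unit = summary_table(tab$cv_unit))
  reliability <- list(
    direct = reliability_classification(tab$cv_direct, cv_threshold),
    area = reliability_classification(tab$cv_area, cv_threshold),
    unit = reliability_classification(tab$cv_unit, cv_threshold))
  bias <- list(area = bias_regression(tab$p_area, tab$p_direct),
               unit = bias_regression(tab$p_unit, tab$p_direct))
  ok_v <- !is.na(tab$var_direct) & tab$var_direct > 0
  gain <- list(
    area = precision_gain(tab$var_direct[ok_v], tab$mse_area[ok_v]),
    unit = precision_gain(tab$var_direct[ok_v], tab$mse_unit[ok_v]))
  structure(list(estimates = tab, summaries = summaries,
                 cv_summaries = cv_summaries, reliability = reliability,
                 bias_regression = bias, precision_gain = gain,
                 n_dropped = sum(!complete), cv_threshold = cv_threshold),
            class = "sae_comparison")
}

#' @export
print.sae_comparison <- function(x, ...) {
  cat("Comparison of district prevalence estimators\n\n")
  cat("Estimate summaries:\n")
  print(round(x$summaries, 4))
  cat("\nCV (%) summaries:\n")
  print(round(x$cv_summaries, 1))
  cat(sprintf("\nReliable districts (CV < %g%%): direct %d/%d, area %d/%d, unit %d/%d\n",
              x$cv_threshold,
              x$reliability$direct$n_reliable, x$reliability$direct$n_total,
              x$reliability$area$n_reliable, x$reliability$area$n_total,
              x$reliability$unit$n_reliable, x$reliability$unit$n_total))
  cat(sprintf("Bias regression on direct: area slope %.3f (r2 %.3f), unit slope %.3f (r2 %.3f)\n",
              x$bias_regression$area$slope, x$bias_regression$area$r_squared,
              x$bias_regression$unit$slope, x$bias_regression$unit$r_squared))
  cat(sprintf("Mean precision gain vs direct: area %.1f%%, unit %.1f%%\n",
              x$precision_gain$area$mean_gain_pct,
              x$precision_gain$unit$mean_gain_pct))
  if (x$n_dropped)
    cat(sprintf("(%d district(s) missing at least one series)\n", x$n_dropped))
  invisible(x)
}

#' Plot the estimator comparison
#'
#' Two-panel base-graphics display: model-based versus direct estimates
#' (with the identity line, mirroring the bias-regression diagnostic), and
#' per-district CVs against survey sample size on a log axis (with the 20%
#' reliability threshold).
#'
#' @param x An [compare_estimates()] result.
#' @param ... Passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.sae_comparison <- function(x, ...) {
  tab <- x$estimates
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  rng <- range(c(tab$p_direct, tab$p_area, tab$p_unit), na.rm = TRUE)
  plot(tab$p_direct, tab$p_area, xlim = rng, ylim = rng, col = "steelblue",
       pch = 16, xlab = "direct estimate", ylab = "model-based estimate",
       main = "Shrinkage", ...)
  graphics::points(tab$p_direct, tab$p_unit, col = "tomato", pch = 17)
  graphics::abline(0, 1, lty = 2)
  graphics::legend("topleft", legend = c("area-level", "unit-level"),
                   col = c("steelblue", "tomato"), pch = c(16, 17),
                   bty = "n")
  cv_rng <- range(c(tab$cv_direct, tab$cv_area, tab$cv_unit), na.rm = TRUE)
  plot(tab$n_i, tab$cv_direct, log = "x", ylim = cv_rng, pch = 1,
       col = "grey40", xlab = "district sample size",
       ylab = "CV (%)", main = "Precision", ...)
  graphics::points(tab$n_i, tab$cv_area, col = "steelblue", pch = 16)
  graphics::points(tab$n_i, tab$cv_unit, col = "tomato", pch = 17)
  graphics::abline(h = x$cv_threshold, lty = 3)
  graphics::legend("topright",
                   legend = c("direct", "area-level", "unit-level"),
                   col = c("grey40", "steelblue", "tomato"),
                   pch = c(1, 16, 17), bty = "n")
  invisible(x)
}
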