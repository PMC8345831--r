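#' Design-weighted (Hajek) prevalence for one domain
#'
#' The ratio estimator `sum(w * y) / sum(w)` over a single district's
#' records. Invariant to rescaling of the weights.
#'
#' @param y Binary outcome vector (0/1).
#' @param w Positive design weights.
#' @return The weighted proportion.
#' @examples
#' direct_prevalence(c(1, 0, 1), c(2, 1, 1))  # 0.75
#' @export
direct_prevalence <- function(y, w) {
  if (!length(y)) stop("no records for this district", call. = FALSE)
  stopifnot(length(y) == length(w))
  if (!all(y %in% c(0, 1))) stop("`y` must be binary 0/1", call. = FALSE)
  if (any(w <= 0) || !any(w > 0))
    stop("weights must be strictly positive", call. = FALSE)
  sum(w * y) / sum(w)
}

#' Taylor-linearization standard error of the Hajek prevalence
#'
#' Linearization variance of the ratio estimator for a single-stratum,
#' with-replacement approximation with PSU (cluster) totals as the
#' resampling units: with `z_j = w_j (y_j - p_hat) / sum(w)`, the variance
#' is `n_psu / (n_psu - 1) * sum_k (Z_k - mean(Z))^2` over PSU totals `Z_k`.
#'
#' @param y,w Outcome and weight vectors as in [direct_prevalence()].
#' @param psu PSU (cluster) identifier per record; at least two distinct
#'   PSUs are required for the variance to be estimable.
#' @return The standard error (square root of the linearized variance).
#' @export
linearization_se <- function(y, w, psu) {
  stopifnot(length(y) == length(w), length(y) == length(psu))
  p_hat <- direct_prevalence(y, w)
  f <- factor(psu)
  n_psu <- nlevels(f)
  if (n_psu < 2)
    stop("only one PSU: variance not estimable for this district",
         call. = FALSE)
  z <- w * (y - p_hat) / sum(w)
  Z <- as.vector(rowsum(z, f))
  v <- n_psu / (n_psu - 1) * sum((Z - mean(Z))^2)
  if (v < 1e-14) v <- 0          # snap cancellation noise to an exact zero
  sqrt(max(v, 0))
}

#' Logit transform of a direct estimate with delta-method variance
#'
#' Maps a prevalence and its standard error to the logit scale:
#' `theta = logit(p)` and sampling variance
#' `psi = se^2 / (p * (1 - p))^2`, the inputs of the area-level model.
#'
#' @param p_hat Prevalence strictly inside (0, 1).
#' @param se Standard error of `p_hat`.
#' @return List with `theta_hat` and `psi`.
#' @export
logit_transform <- function(p_hat, se) {
  if (!is.finite(p_hat) || p_hat <= 0 || p_hat >= 1)
    stop("logit transform requires 0 < p_hat < 1", call. = FALSE)
  list(theta_hat = logit(p_hat), psi = se^2 / (p_hat * (1 - p_hat))^2)
}

#' Direct survey estimates of district prevalence
#'
#' Computes, for every district in a survey dataset, the design-weighted
#' (Hajek) prevalence, its Taylor-linearization standard error (district as
#' stratum, cluster as PSU, with-replacement approximation), a normal-theory
#' confidence interval truncated to `[0, 1]`, the coefficient of variation,
#' and the logit-scale transform `(theta_hat, psi)` that feeds the
#' area-level model.
#'
#' Districts with a single sampled PSU get `NA` standard errors (with a
#' warning); districts whose weighted prevalence is exactly 0 or 1 are
#' flagged `fh_eligible = FALSE` and get `NA` logit-scale values, since the
#' logit-scale sampling variance is undefined there. Such districts keep
#' their direct estimate in the output but are excluded from area-level
#' model input.
#'
#' @param data A `data.frame` of survey records, or a `"survey_sample"` as
#'   produced by [draw_two_stage_sample()].
#' @param outcome,weight,domain,psu Column names of the binary outcome,
#'   design weight, district identifier and cluster/PSU identifier.
#' @param level Confidence level (default 0.95).
#' @return `data.frame` of class `"direct_estimates"` with one row per
#'   district: `district_id`, `n`, `n_psu`, `p_hat`, `se`, `ci_low`,
#'   `ci_high`, `cv_pct`, `theta_hat`, `psi`, `fh_eligible`.
#' @examples
#' toy <- data.frame(district_id = "d1", cluster_id = c("a", "a", "b"),
#'                   weight = c(2, 1, 1), y = c(1, 0, 1))
#' direct_estimates(toy)
#' @export
direct_estimates <- function(data, outcome = "y", weight = "weight",
                             domain = "district_id", psu = "cluster_id",
                             level = 0.95) {
  if (inherits(data, "survey_sample")) data <- data$records
  check_columns(data, c(outcome, weight, domain, psu), "survey data")
  if (any(data[[weight]] <= 0))
    stop("all weights must be strictly positive", call. = FALSE)
  zq <- stats::qnorm(1 - (1 - level) / 2)
  doms <- unique(as.character(data[[domain]]))
  single_psu <- character(0)

  rows <- lapply(doms, function(d) {
    sub <- data[data[[domain]] == d, , drop = FALSE]
    y <- sub[[outcome]]; w <- sub[[weight]]
    p <- direct_prevalence(y, w)
    n_psu <- length(unique(sub[[psu]]))
    se <- if (n_psu >= 2) linearization_se(y, w, sub[[psu]]) else {
      single_psu <<- c(single_psu, d)
      NA_real_
    }
    eligible <- p > 0 && p < 1 && is.finite(se)
    lt <- if (p > 0 && p < 1 && is.finite(se)) logit_transform(p, se) else
      list(theta_hat = NA_real_, psi = NA_real_)
    data.frame(district_id = d, n = length(y), n_psu = n_psu,
               p_hat = p, se = se,
               ci_low = max(0, p - zq * se), ci_high = min(1, p + zq * se),
               cv_pct = if (p > 0) 100 * se / p else NA_real_,
               theta_hat = lt$theta_hat, psi = lt$psi,
               fh_eligible = eligible)
  })
  if (length(single_psu))
    warning("single-PSU district(s), SE not estimable: ",
            paste(single_psu, collapse = ", "), call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("direct_estimates", "data.frame")
  out
}
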