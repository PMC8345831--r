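# ---- Fay-Herriot area-level model on the logit scale ----------------------
#
# Sampling model:  theta_hat_i = theta_i + e_i,   e_i ~ N(0, psi_i), psi known
# Linking model:   theta_i     = z_i' beta + v_i, v_i ~ N(0, sigma_v^2)
# EBLUP:           theta_fh_i  = gamma_i theta_hat_i + (1 - gamma_i) z_i' beta
#                  gamma_i     = sigma_v^2 / (sigma_v^2 + psi_i)

# Gaussian log-likelihood (ML profiled over beta, or REML) in sigma_v2.
fh_loglik <- function(sigma_v2, theta, psi, Z, reml = TRUE) {
  V <- sigma_v2 + psi
  Vinv <- 1 / V
  A <- crossprod(Z, Z * Vinv)            # Z' V^-1 Z
  beta <- solve(A, crossprod(Z, theta * Vinv))
  r <- theta - drop(Z %*% beta)
  ll <- -0.5 * (sum(log(V)) + sum(r^2 * Vinv) + length(theta) * log(2 * pi))
  if (reml)
    ll <- ll - 0.5 * determinant(A, logarithm = TRUE)$modulus +
      0.5 * ncol(Z) * log(2 * pi)
  as.numeric(ll)
}

#' Estimate the area-model variance component
#'
#' Maximizes the (restricted) Gaussian likelihood of the area-level model in
#' `sigma_v2 >= 0` by bounded one-dimensional profile maximization,
#' truncating at zero when the unconstrained optimum is negative (the
#' boundary is always compared against the interior optimum).
#'
#' @param theta_hat Direct logit-scale estimates.
#' @param psi Known logit-scale sampling variances (`>= 0`, finite).
#' @param Z Full-column-rank design matrix of area-level covariates
#'   (including the intercept column).
#' @param method `"REML"` (default) or `"ML"`.
#' @param tol Convergence tolerance on `sigma_v2`.
#' @return List with `sigma_v2`, the maximized `loglik`, and `converged`.
#' @export
fh_variance <- function(theta_hat, psi, Z, method = c("REML", "ML"),
                        tol = 1e-10) {
  method <- match.arg(method)
  reml <- method == "REML"
  stopifnot(length(theta_hat) == length(psi), nrow(Z) == length(theta_hat))
  if (length(theta_hat) < ncol(Z) + 2)
    stop("need at least p + 2 districts to estimate the variance component",
         call. = FALSE)
  if (any(!is.finite(psi)) || any(psi < 0))
    stop("`psi` must be finite and >= 0", call. = FALSE)
  fh_check_rank(Z)
  upper <- max(10 * stats::var(theta_hat), 10 * mean(psi), 1)
  # with any psi ~ 0 the model is degenerate at sigma_v2 = 0; keep the
  # search (and the boundary comparison) away from the singular point
  lower <- if (min(psi) < 1e-6) 1e-6 else 0
  for (round in 1:5) {
    opt <- stats::optimize(fh_loglik, c(lower, upper), theta = theta_hat,
                           psi = psi, Z = Z, reml = reml, maximum = TRUE,
                           tol = tol)
    if (opt$maximum < 0.99 * upper) break
    upper <- upper * 10
  }
  ll0 <- fh_loglik(lower, theta_hat, psi, Z, reml)
  if (ll0 >= opt$objective)
    list(sigma_v2 = if (lower == 0) 0 else lower, loglik = ll0,
         converged = TRUE)
  else
    list(sigma_v2 = opt$maximum, loglik = opt$objective, converged = TRUE)
}

fh_check_rank <- function(Z) {
  q <- qr(Z)
  if (q$rank < ncol(Z)) {
    bad <- colnames(Z)[q$pivot[(q$rank + 1):ncol(Z)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(Z)
}

#' Generalized least squares coefficients of the linking model
#'
#' Weighted least squares of `theta_hat` on `Z` with weights
#' `1 / (sigma_v2 + psi_i)`.
#'
#' @inheritParams fh_variance
#' @param sigma_v2 Variance component (fixed).
#' @return List with `beta` (named) and `cov` (its covariance matrix).
#' @export
fh_gls_beta <- function(theta_hat, psi, Z, sigma_v2) {
  fh_check_rank(Z)
  Vinv <- 1 / (sigma_v2 + psi)
  A <- crossprod(Z, Z * Vinv)
  beta <- solve(A, crossprod(Z, theta_hat * Vinv))
  list(beta = stats::setNames(drop(beta), colnames(Z)), cov = solve(A))
}

#' Empirical best linear unbiased predictor (area level)
#'
#' The convex combination
#' `theta_fh_i = gamma_i * theta_hat_i + (1 - gamma_i) * z_i' beta` with
#' shrinkage factor `gamma_i = sigma_v2 / (sigma_v2 + psi_i)`. Districts
#' with missing `theta_hat` (no usable direct estimate) receive the
#' regression-synthetic value `z_i' beta` with `gamma = 0`.
#'
#' @inheritParams fh_gls_beta
#' @param beta Fitted coefficient vector.
#' @return List with `gamma` and `theta_fh`.
#' @export
fh_eblup <- function(theta_hat, psi, Z, beta, sigma_v2) {
  synth <- drop(Z %*% beta)
  gamma <- ifelse(is.na(theta_hat) | is.na(psi), 0,
                  if (sigma_v2 == 0) 0 else sigma_v2 / (sigma_v2 + psi))
  theta_fh <- ifelse(gamma > 0, gamma * theta_hat + (1 - gamma) * synth,
                     synth)
  list(gamma = gamma, theta_fh = theta_fh)
}

#' Prasad-Rao mean squared error of the area-level EBLUP
#'
#' The standard first-order-unbiased decomposition
#' `MSE_i = g1_i + g2_i + 2 g3_i`, with `g1 = gamma_i psi_i` (shrinkage
#' variance), `g2` the contribution of estimating `beta`, and `g3` the
#' contribution of estimating `sigma_v2` through its asymptotic variance.
#' With ML variance estimation the Datta-Lahiri bias-correction term
#' `- b(sigma_v2) * dg1/dsigma_v2` is added. Districts without a direct
#' estimate (`theta_hat` missing) get the synthetic-prediction MSE
#' `sigma_v2 + z_i' cov(beta) z_i`.
#'
#' @inheritParams fh_eblup
#' @param theta_missing Logical per district: no usable direct estimate.
#' @param method `"REML"` or `"ML"` (selects the bias correction).
#' @return Numeric vector of logit-scale MSEs.
#' @export
fh_mse <- function(psi, Z, sigma_v2, method = c("REML", "ML"),
                   theta_missing = rep(FALSE, length(psi))) {
  method <- match.arg(method)
  psi_fit <- psi[!theta_missing]
  V <- sigma_v2 + psi_fit
  A <- crossprod(Z[!theta_missing, , drop = FALSE],
                 Z[!theta_missing, , drop = FALSE] / V)
  covb <- solve(A)
  var_sv <- 2 / sum(V^-2)                 # asymptotic var of sigma_v2 hat
  lev <- rowSums((Z %*% covb) * Z)        # z_i' cov(beta) z_i

  gamma <- if (sigma_v2 == 0) rep(0, length(psi)) else
    sigma_v2 / (sigma_v2 + psi)
  g1 <- gamma * psi
  g2 <- (1 - gamma)^2 * lev
  g3 <- psi^2 / (sigma_v2 + psi)^3 * var_sv
  mse <- g1 + g2 + 2 * g3
  if (method == "ML") {
    b <- -sum(diag(covb %*% crossprod(Z[!theta_missing, , drop = FALSE],
                                      Z[!theta_missing, , drop = FALSE] / V^2))) /
      sum(V^-2)
    mse <- mse - b * psi^2 / (sigma_v2 + psi)^2
  }
  # synthetic-only districts: prediction variance of a new area
  mse[theta_missing] <- sigma_v2 + lev[theta_missing]
  pmax(mse, 0)
}

#' Back-transform logit-scale EBLUPs to the prevalence scale
#'
#' `p = expit(theta_fh)`; delta-method prevalence-scale MSE
#' `mse_p = mse_logit * (p (1 - p))^2`; confidence limits are the expit of
#' logit-scale normal limits, hence always strictly inside (0, 1).
#'
#' @param theta_fh Logit-scale EBLUPs.
#' @param mse_logit Their logit-scale MSEs.
#' @param level Confidence level (default 0.95).
#' @return `data.frame` with `p_fh`, `mse_p`, `ci_low`, `ci_high`.
#' @export
fh_back_transform <- function(theta_fh, mse_logit, level = 0.95) {
  zq <- stats::qnorm(1 - (1 - level) / 2)
  p <- expit(theta_fh)
  hw <- zq * sqrt(mse_logit)
  data.frame(p_fh = p, mse_p = mse_logit * (p * (1 - p))^2,
             ci_low = expit(theta_fh - hw), ci_high = expit(theta_fh + hw))
}

#' Fit the Fay-Herriot area-level model
#'
#' Fits the logit-scale area-level model to direct estimates and their known
#' sampling variances: estimates `sigma_v2` by REML (default) or ML profile
#' likelihood, `beta` by GLS, forms the EBLUP for every district, attaches
#' Prasad-Rao MSEs, and back-transforms to the prevalence scale.
#'
#' Rows whose response or `vardir` is `NA` (districts excluded at the direct
#' stage) are not used in fitting; they receive the regression-synthetic
#' prediction with `gamma = 0` and a synthetic-prediction MSE.
#'
#' @param formula Linking-model formula, e.g. `theta_hat ~ z_anc`; the
#'   response is the logit-scale direct estimate.
#' @param vardir Name of the column holding the known sampling variance
#'   `psi_i` (or a numeric vector).
#' @param data `data.frame` with one row per district, e.g. a
#'   [direct_estimates()] table merged with area-level covariates.
#' @param domain Name of the district identifier column (default
#'   `"district_id"`; set `NULL` to use row numbers).
#' @param method `"REML"` (default) or `"ML"`.
#' @param level Confidence level for prevalence-scale intervals.
#' @return An object of class `"fh_fit"`: list with `estimates` (per
#'   district: `district_id`, `theta_hat`, `psi`, `gamma`, `theta_fh`,
#'   `mse_logit`, `p_fh`, `mse_p`, `ci_low`, `ci_high`, `cv_pct`), `beta`,
#'   `cov_beta`, `sigma_v2`, `loglik` (criterion maximized), `loglik_ml`,
#'   `aic` (from the ML likelihood), `method`, `converged`.
#' @examples
#' d <- data.frame(district_id = sprintf("d%02d", 1:12),
#'                 theta_hat = rnorm(12, -2.7, 0.4),
#'                 psi = runif(12, 0.05, 0.2), z = rnorm(12))
#' fit <- fh_fit(theta_hat ~ z, vardir = "psi", data = d)
#' fit$sigma_v2
#' @export
fh_fit <- function(formula, vardir, data, domain = "district_id",
                   method = c("REML", "ML"), level = 0.95) {
  method <- match.arg(method)
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  theta <- stats::model.response(mf)
  Z <- stats::model.matrix(formula, mf)
  psi <- if (is.character(vardir)) {
    check_columns(data, vardir, "FH input")
    data[[vardir]]
  } else vardir
  if (any(stats::complete.cases(Z) & is.finite(psi) & psi < 0))
    stop("`vardir` must be >= 0", call. = FALSE)
  ids <- if (!is.null(domain) && domain %in% names(data))
    as.character(data[[domain]]) else as.character(seq_along(theta))

  usable <- is.finite(theta) & is.finite(psi)
  if (!all(stats::complete.cases(Z)))
    stop("missing values in area-level covariates", call. = FALSE)
  fit_v <- fh_variance(theta[usable], psi[usable],
                       Z[usable, , drop = FALSE], method)
  gls <- fh_gls_beta(theta[usable], psi[usable], Z[usable, , drop = FALSE],
                     fit_v$sigma_v2)
  bl <- fh_eblup(theta, psi, Z, gls$beta, fit_v$sigma_v2)
  mse <- fh_mse(ifelse(usable, psi, 0), Z, fit_v$sigma_v2, method,
                theta_missing = !usable)
  bt <- fh_back_transform(bl$theta_fh, mse, level)

  ll_ml <- if (method == "ML") fit_v$loglik else
    fh_loglik(fh_variance(theta[usable], psi[usable],
                          Z[usable, , drop = FALSE], "ML")$sigma_v2,
              theta[usable], psi[usable], Z[usable, , drop = FALSE],
              reml = FALSE)
  est <- data.frame(district_id = ids, theta_hat = theta, psi = psi,
                    gamma = bl$gamma, theta_fh = bl$theta_fh,
                    mse_logit = mse, bt,
                    cv_pct = 100 * sqrt(bt$mse_p) / bt$p_fh,
                    row.names = NULL)
  structure(list(estimates = est, beta = gls$beta, cov_beta = gls$cov,
                 sigma_v2 = fit_v$sigma_v2, loglik = fit_v$loglik,
                 loglik_ml = ll_ml,
                 aic = -2 * ll_ml + 2 * (ncol(Z) + 1),
                 method = method, converged = fit_v$converged,
                 formula = formula, n_fitted = sum(usable)),
            class = "fh_fit")
}

#' @export
print.fh_fit <- function(x, ...) {
  cat(sprintf("Fay-Herriot area-level fit (%s), %d districts\n",
              x$method, nrow(x$estimates)))
  cat("  sigma_v2 =", format(x$sigma_v2, digits = 4),
      " loglik =", format(x$loglik, digits = 6),
      " AIC(ML) =", format(x$aic, digits = 6), "\n")
  cat("  beta:\n")
  print(round(x$beta, 4))
  invisible(x)
}

#' Rank candidate area-level linking models by AIC
#'
#' Fits each candidate formula by maximum likelihood (ML rather than REML so
#' that likelihoods are comparable across fixed-effect structures) and ranks
#' them by `AIC = -2 loglik + 2 (p + 1)`, counting the variance component as
#' one parameter. Ties are broken in favour of fewer parameters.
#'
#' @param candidates List of linking-model formulas.
#' @param vardir,data,domain As in [fh_fit()].
#' @return List with `table` (one row per candidate: formula, `p`, `loglik`,
#'   `aic`, ordered best first), `best` (the winning formula) and
#'   `best_fit` (its refit under REML).
#' @export
fh_select_aic <- function(candidates, vardir, data, domain = "district_id") {
  if (!length(candidates)) stop("no candidate models", call. = FALSE)
  rows <- lapply(seq_along(candidates), function(i) {
    f <- candidates[[i]]
    fit <- tryCatch(fh_fit(f, vardir, data, domain, method = "ML"),
                    error = function(e) e)
    if (inherits(fit, "error"))
      data.frame(candidate = i, formula = deparse1(f), p = NA, loglik = NA,
                 aic = NA, converged = FALSE)
    else
      data.frame(candidate = i, formula = deparse1(f),
                 p = length(fit$beta), loglik = fit$loglik_ml, aic = fit$aic,
                 converged = fit$converged)
  })
  tab <- do.call(rbind, rows)
  ok <- which(is.finite(tab$aic))
  if (!length(ok)) stop("all candidate models failed to fit", call. = FALSE)
  ord <- ok[order(tab$aic[ok], tab$p[ok])]
  tab <- tab[c(ord, setdiff(seq_len(nrow(tab)), ord)), ]
  rownames(tab) <- NULL
  best <- candidates[[tab$candidate[1]]]
  list(table = tab, best = best,
       best_fit = fh_fit(best, vardir, data, domain, method = "REML"))
}
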