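# ---- Unit-level logistic mixed model, EBP and parametric-bootstrap MSE ----
#
# Model:  logit P(y_ij = 1) = X_ij' beta + v_i,   v_i ~ N(0, sigma_v^2)
# EBP:    p_i = ( sum_{j in S} y_ij + sum_{j in S'} p_ij_hat ) / N_i
# with p_ij_hat the plug-in prediction at the empirical-Bayes mode v_i_hat.

# Newton mode-finding for all district random effects at once, with
# per-district step halving so the (concave) penalized log-likelihood
# increases monotonically — plain Newton can cycle in the flat logistic
# tails. Rows must be grouped by district (callers sort once); halving
# re-evaluates only the districts still violating ascent, over their own
# contiguous row ranges. Returns modes v and curvatures h per district.
re_modes <- function(y, eta0, did, m, sigma_v2, v = rep(0, m)) {
  ends <- cumsum(tabulate(did, m))
  starts <- c(1L, ends[-m] + 1L)
  obj <- function(v) {
    eta <- eta0 + v[did]
    rowsum_vec(y * eta - log1pexp(eta), did, m) - v^2 / (2 * sigma_v2)
  }
  obj_one <- function(d, vd) {
    rows <- starts[d]:ends[d]
    eta <- eta0[rows] + vd
    sum(y[rows] * eta - log1pexp(eta)) - vd^2 / (2 * sigma_v2)
  }
  o <- NULL
  for (it in 1:100) {
    mu <- stats::plogis(eta0 + v[did])
    g <- rowsum_vec(y - mu, did, m) - v / sigma_v2
    h <- rowsum_vec(mu * (1 - mu), did, m) + 1 / sigma_v2
    step <- g / h
    if (max(abs(step)) > 0.25) {
      # far from the mode: enforce ascent — small steps are always
      # accepted (the local basin, where Newton is monotone)
      if (is.null(o)) o <- obj(v)
      cand <- v + step
      oc <- obj(cand)
      bad <- which(oc < o - 1e-12 & ends >= starts)
      tries <- 0
      while (length(bad) && tries < 30) {
        step[bad] <- step[bad] / 2
        for (d in bad) {
          cand[d] <- v[d] + step[d]
          oc[d] <- obj_one(d, cand[d])
        }
        bad <- bad[oc[bad] < o[bad] - 1e-12]
        tries <- tries + 1
      }
      v <- cand
      o <- oc
    } else {
      v <- v + step
      o <- NULL
    }
    if (max(abs(step)) < 1e-10) break
  }
  mu <- stats::plogis(eta0 + v[did])
  list(v = v, h = rowsum_vec(mu * (1 - mu), did, m) + 1 / sigma_v2)
}

rowsum_vec <- function(x, g, m) {
  if (!is.unsorted(g)) {
    # grouped rows: per-group totals from one cumulative sum
    ends <- cumsum(tabulate(g, m))
    cs <- cumsum(x)
    vals <- cs[pmax(ends, 1L)]
    vals[ends == 0L] <- 0
    return(diff(c(0, vals)))
  }
  out <- numeric(m)
  s <- rowsum(x, g)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Per-district marginal log-likelihood by adaptive Gauss-Hermite quadrature
#'
#' Evaluates, at given parameter values, the marginal log-likelihood
#' contribution of each district of a random-intercept logistic model:
#' `log integral prod_j Bernoulli(y_ij; expit(X_ij' beta + v)) phi(v; 0,
#' sigma_v^2) dv`, by Gauss-Hermite quadrature recentred and rescaled at the
#' Laplace mode of each district (adaptive quadrature).
#'
#' @param beta Coefficient vector aligned with the columns of `X`.
#' @param sigma_v Random-effect standard deviation (`> 0`).
#' @param y Binary outcomes.
#' @param X Model matrix.
#' @param district District identifier per row.
#' @param nodes Number of quadrature nodes (default 50).
#' @return Named vector of per-district log-marginal-likelihoods.
#' @export
unit_marginal_loglik <- function(beta, sigma_v, y, X, district, nodes = 50) {
  stopifnot(sigma_v > 0, length(y) == nrow(X))
  f <- factor(district)
  did <- as.integer(f)
  m <- nlevels(f)
  if (is.unsorted(did)) {      # re_modes expects district-grouped rows
    ord <- order(did)
    y <- y[ord]
    X <- X[ord, , drop = FALSE]
    did <- did[ord]
  }
  gh <- pracma::gaussHermite(nodes)
  eta0 <- drop(X %*% beta)
  md <- re_modes(y, eta0, did, m, sigma_v^2)
  sd_i <- 1 / sqrt(md$h)
  acc <- matrix(NA_real_, m, nodes)
  for (k in seq_len(nodes)) {
    vk <- md$v + sqrt(2) * sd_i * gh$x[k]
    eta <- eta0 + vk[did]
    ll_data <- rowsum_vec(y * eta - log1pexp(eta), did, m)
    acc[, k] <- log(gh$w[k]) + gh$x[k]^2 + ll_data +
      stats::dnorm(vk, 0, sigma_v, log = TRUE)
  }
  mx <- apply(acc, 1, max)
  ll <- mx + log(rowSums(exp(acc - mx))) + log(sqrt(2) * sd_i)
  stats::setNames(ll, levels(f))
}

# total marginal log-likelihood and its gradient in par = c(beta, log
# sigma_v); used by the internal "agq" fitting engine (fast refits inside
# the bootstrap). The gradient is the posterior-expected score, computed
# with the same quadrature: d/dbeta = sum_i E[ sum_j (y - mu) x_j | y ],
# d/dlog sigma = sum_i E[ v^2 / sigma^2 - 1 | y ].
agq_nll_core <- function(par, y, X, did, m, gh, v_start = rep(0, m)) {
  p <- length(par) - 1
  beta <- par[seq_len(p)]
  sv <- exp(par[p + 1])
  eta0 <- drop(X %*% beta)
  md <- re_modes(y, eta0, did, m, sv^2, v = v_start)
  sd_i <- 1 / sqrt(md$h)
  nodes <- length(gh$x)
  acc <- matrix(NA_real_, m, nodes)
  vks <- matrix(NA_real_, m, nodes)
  for (k in seq_len(nodes)) {
    vk <- md$v + sqrt(2) * sd_i * gh$x[k]
    vks[, k] <- vk
    eta <- eta0 + vk[did]
    acc[, k] <- log(gh$w[k]) + gh$x[k]^2 +
      rowsum_vec(y * eta - log1pexp(eta), did, m) +
      stats::dnorm(vk, 0, sv, log = TRUE)
  }
  mx <- apply(acc, 1, max)
  ll_i <- mx + log(rowSums(exp(acc - mx))) + log(sqrt(2) * sd_i)
  W <- exp(acc - ll_i + log(sqrt(2) * sd_i))       # posterior node weights
  # gradient: accumulate quadrature-weighted residuals over nodes
  wres <- numeric(length(y))
  for (k in seq_len(nodes)) {
    mu <- stats::plogis(eta0 + vks[did, k])
    wres <- wres + W[did, k] * (y - mu)
  }
  g_beta <- -drop(crossprod(X, wres))
  g_ls <- -sum(W * (vks^2 / sv^2 - 1))
  list(value = -sum(ll_i), gradient = c(g_beta, g_ls), v = md$v)
}

# optim-ready closures sharing one evaluation cache and warm-started modes
agq_fit <- function(y, X, did, m, nAGQ = 15, start = NULL,
                    reltol = 1e-10) {
  if (is.unsorted(did)) {      # re_modes expects district-grouped rows
    ord <- order(did)
    y <- y[ord]
    X <- X[ord, , drop = FALSE]
    did <- did[ord]
  }
  gh <- pracma::gaussHermite(nAGQ)
  if (is.null(start)) {
    b0 <- stats::coef(stats::glm.fit(X, y, family = stats::binomial()))
    start <- c(b0, log(0.3))
  }
  cache <- list(par = NULL, res = NULL)
  v_last <- rep(0, m)
  eval_at <- function(par) {
    if (is.null(cache$par) || !identical(par, cache$par)) {
      res <- agq_nll_core(par, y, X, did, m, gh, v_start = v_last)
      v_last <<- res$v
      cache <<- list(par = par, res = res)
    }
    cache$res
  }
  opt <- stats::nlminb(start, function(p) eval_at(p)$value,
                       gradient = function(p) eval_at(p)$gradient,
                       control = list(iter.max = 300, rel.tol = reltol))
  par <- opt$par
  val <- opt$objective
  conv <- opt$convergence == 0
  if (!conv) {
    # "false convergence" and kin: polish with a quasi-Newton pass and
    # accept whichever point has the better objective
    opt2 <- stats::optim(par, fn = function(p) eval_at(p)$value,
                         gr = function(p) eval_at(p)$gradient,
                         method = "BFGS",
                         control = list(maxit = 100, reltol = reltol))
    if (opt2$value <= val) {
      par <- opt2$par
      val <- opt2$value
      conv <- opt2$convergence == 0
    }
  }
  beta <- stats::setNames(par[-length(par)], colnames(X))
  sv <- unname(exp(par[length(par)]))
  md <- re_modes(y, drop(X %*% beta), did, m, sv^2, v = v_last)
  list(beta = beta, sigma_v2 = sv^2, v = md$v, loglik = -val,
       converged = conv, par = par)
}

# crude complete-separation screen: a model-matrix column whose support has
# constant outcome makes the MLE diverge
check_separation <- function(y, X) {
  for (j in seq_len(ncol(X))[-1]) {
    on <- X[, j] != 0
    if (any(on) && (all(y[on] == 1) || all(y[on] == 0)))
      stop("complete separation: outcome constant where `", colnames(X)[j],
           "` is active", call. = FALSE)
  }
  invisible(NULL)
}

#' Fit the unit-level random-intercept logistic model
#'
#' Maximum-likelihood fit of `logit P(y = 1) = X' beta + v_district`,
#' `v ~ N(0, sigma_v^2)`, with the likelihood integrated over the random
#' effects by adaptive Gauss-Hermite quadrature. The default engine is
#' [lme4::glmer()]; the `"agq"` engine is the package's own quadrature
#' fitter (used internally for fast bootstrap refits). Survey weights are
#' deliberately not used: the model is an unweighted unit-level
#' superpopulation model, so fitted parameters describe the model, not the
#' design (see the package vignette).
#'
#' @param formula Fixed-effects formula, e.g. `y ~ sex + age_group` (no
#'   random-effect term; the district intercept is added internally).
#' @param data `data.frame` of sampled records (a `"survey_sample"` is also
#'   accepted).
#' @param domain District identifier column (default `"district_id"`).
#' @param nAGQ Number of quadrature nodes (default 15).
#' @param engine `"glmer"` (default) or `"agq"`.
#' @param start Optional optimizer start `c(beta, log sigma_v)` for the
#'   `"agq"` engine — useful to warm-start repeated fits in simulation
#'   studies (ignored by `"glmer"`).
#' @return An object of class `"unit_fit"`: list with `beta`, `sigma_v2`,
#'   `v_hat` (empirical-Bayes modes, named by district), `loglik`,
#'   `converged`, plus the terms/levels needed for prediction.
#' @export
fit_unit_model <- function(formula, data, domain = "district_id",
                           nAGQ = 15, engine = c("glmer", "agq"),
                           start = NULL) {
  engine <- match.arg(engine)
  if (inherits(data, "survey_sample")) data <- data$records
  check_columns(data, c(all.vars(formula), domain), "unit-level data")
  data[[domain]] <- factor(data[[domain]])
  if (nlevels(data[[domain]]) < 2)
    stop("need at least two districts", call. = FALSE)
  y <- stats::model.response(stats::model.frame(formula, data))
  if (length(unique(y)) < 2)
    stop("outcome is constant; model not identifiable", call. = FALSE)
  X <- stats::model.matrix(formula[-2], data)
  check_separation(y, X)

  if (engine == "glmer") {
    gf <- stats::update(formula, stats::as.formula(
      paste(". ~ . + (1 |", domain, ")")))
    gm <- lme4::glmer(gf, data = data, family = stats::binomial(),
                      nAGQ = nAGQ)
    if (isTRUE(gm@optinfo$conv$opt != 0))
      stop("glmer failed to converge", call. = FALSE)
    beta <- lme4::fixef(gm)
    sigma_v2 <- unname(lme4::VarCorr(gm)[[domain]][1, 1])
    re <- lme4::ranef(gm)[[domain]]
    v_hat <- stats::setNames(re[, 1], rownames(re))
    ll <- as.numeric(stats::logLik(gm))
    conv <- TRUE
    par <- c(beta, log(max(sqrt(sigma_v2), 1e-8)))
  } else {
    did <- as.integer(data[[domain]])
    af <- agq_fit(y, X, did, nlevels(data[[domain]]), nAGQ, start = start)
    beta <- af$beta
    sigma_v2 <- af$sigma_v2
    v_hat <- stats::setNames(af$v, levels(data[[domain]]))
    ll <- af$loglik
    conv <- af$converged
    par <- af$par
  }
  structure(list(beta = beta, sigma_v2 = sigma_v2, v_hat = v_hat,
                 loglik = ll, converged = conv, formula = formula,
                 domain = domain, nAGQ = nAGQ, engine = engine, par = par,
                 xlevels = stats::.getXlevels(stats::terms(formula[-2],
                                                           data = data),
                                              data)),
            class = "unit_fit")
}

`%||%` <- function(a, b) if (is.null(a) || !length(a)) b else a

#' @export
print.unit_fit <- function(x, ...) {
  cat(sprintf("Unit-level logistic mixed model (%s, %d districts)\n",
              x$engine, length(x$v_hat)))
  cat("  sigma_v2 =", format(x$sigma_v2, digits = 4),
      " loglik =", format(x$loglik, digits = 6), "\n  beta:\n")
  print(round(x$beta, 4))
  invisible(x)
}

# model matrix for new data under the fitted factor levels; errors on
# unseen levels
unit_model_matrix <- function(fit, newdata) {
  for (nm in names(fit$xlevels)) {
    if (!nm %in% names(newdata)) next
    bad <- setdiff(unique(as.character(newdata[[nm]])), fit$xlevels[[nm]])
    if (length(bad))
      stop("unseen level(s) in `", nm, "`: ", paste(bad, collapse = ", "),
           call. = FALSE)
    newdata[[nm]] <- factor(newdata[[nm]], levels = fit$xlevels[[nm]])
  }
  stats::model.matrix(fit$formula[-2], newdata)
}

#' Predict unit-level outcome probabilities
#'
#' Plug-in predictions `p_ij = expit(X_ij' beta + v_i)` at the fitted
#' coefficients and empirical-Bayes district modes; districts absent from
#' the fitting sample use `v_i = 0`.
#'
#' @param fit A [fit_unit_model()] result.
#' @param newdata Covariate rows to predict (must use the fitted levels).
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_units <- function(fit, newdata) {
  X <- unit_model_matrix(fit, newdata)
  v <- fit$v_hat[as.character(newdata[[fit$domain]])]
  v[is.na(v)] <- 0
  expit(drop(X %*% fit$beta) + unname(v))
}

#' Assemble a district prediction frame
#'
#' Pairs each district's sampled records (with outcome) with its
#' non-sampled covariate-only units; the district population size is
#' `N_i = n_sampled_i + n_nonsampled_i`.
#'
#' @param sampled `data.frame` of sampled records including the outcome (a
#'   `"survey_sample"` is also accepted).
#' @param nonsampled `data.frame` of covariate-only units (e.g. an
#'   [lqas_style_frame()]).
#' @param domain District identifier column present in both.
#' @param outcome Outcome column in `sampled`.
#' @return Object of class `"district_frame"`: list with `sampled`,
#'   `nonsampled`, `domain`, `outcome` and a `districts` table
#'   (`district_id`, `n_i`, `N_i`).
#' @export
district_frame <- function(sampled, nonsampled, domain = "district_id",
                           outcome = "y") {
  if (inherits(sampled, "survey_sample")) sampled <- sampled$records
  check_columns(sampled, c(domain, outcome), "sampled records")
  check_columns(nonsampled, domain, "non-sampled frame")
  if (outcome %in% names(nonsampled))
    stop("non-sampled frame must not carry the outcome column", call. = FALSE)
  ids <- sort(unique(c(as.character(sampled[[domain]]),
                       as.character(nonsampled[[domain]]))))
  n_i <- table(factor(sampled[[domain]], levels = ids))
  r_i <- table(factor(nonsampled[[domain]], levels = ids))
  structure(list(sampled = sampled, nonsampled = nonsampled,
                 domain = domain, outcome = outcome,
                 districts = data.frame(district_id = ids,
                                        n_i = as.integer(n_i),
                                        N_i = as.integer(n_i + r_i))),
            class = "district_frame")
}

#' Empirical best predictor of district prevalence
#'
#' For each district, sums the observed outcomes of sampled units and the
#' model-predicted probabilities of non-sampled units, divided by the
#' district population size:
#' `p_i = (sum_{j in S} y_ij + sum_{j in S'} p_ij) / N_i`.
#'
#' @param fit A [fit_unit_model()] result.
#' @param frame A [district_frame()].
#' @return `data.frame` with `district_id`, `p_ebp`, `n_i`, `N_i`.
#' @export
ebp_prevalence <- function(fit, frame) {
  stopifnot(inherits(frame, "district_frame"))
  ids <- frame$districts$district_id
  if (any(frame$districts$N_i == 0))
    stop("district with N_i = 0", call. = FALSE)
  ysum <- rep(0, length(ids))
  names(ysum) <- ids
  if (nrow(frame$sampled)) {
    s <- tapply(frame$sampled[[frame$outcome]],
                factor(frame$sampled[[frame$domain]], levels = ids), sum)
    ysum[!is.na(s)] <- s[!is.na(s)]
  }
  psum <- rep(0, length(ids))
  names(psum) <- ids
  if (nrow(frame$nonsampled)) {
    p_ij <- predict_units(fit, frame$nonsampled)
    s <- tapply(p_ij, factor(frame$nonsampled[[frame$domain]], levels = ids),
                sum)
    psum[!is.na(s)] <- s[!is.na(s)]
  }
  data.frame(district_id = ids,
             p_ebp = (ysum + psum) / frame$districts$N_i,
             n_i = frame$districts$n_i, N_i = frame$districts$N_i,
             row.names = NULL)
}

#' Parametric-bootstrap MSE of the empirical best predictor
#'
#' Finite-population parametric bootstrap: for each replicate, district
#' effects `v*_i ~ N(0, sigma_v2_hat)` and outcomes
#' `y*_ij ~ Bernoulli(expit(X_ij' beta_hat + v*_i))` are generated for
#' every unit of every district (sampled and non-sampled); the bootstrap
#' finite-population truth is the mean of `y*` over the whole district; the
#' model is refitted on the original sampled unit positions and the EBP is
#' recomputed. The MSE estimate is the mean squared deviation of the
#' bootstrap EBP from the bootstrap truth.
#'
#' Refits use the package's fast adaptive-quadrature engine, warm-started at
#' the original estimates. An error is thrown if more than 20% of
#' replicates fail to refit.
#'
#' @param fit A converged [fit_unit_model()] result.
#' @param frame A [district_frame()].
#' @param B Number of bootstrap replicates (default 200).
#' @param seed Integer seed (the whole bootstrap is reproducible).
#' @param nAGQ Quadrature nodes for the refits (default 7).
#' @return `data.frame` with `district_id`, `mse_boot`, `B_used`.
#' @export
bootstrap_mse <- function(fit, frame, B = 200, seed = 1L, nAGQ = 7) {
  stopifnot(inherits(fit, "unit_fit"), inherits(frame, "district_frame"))
  B <- check_count(B, "B", min = 2L)
  if (!isTRUE(fit$converged)) stop("fit did not converge", call. = FALSE)
  ids <- frame$districts$district_id
  m <- length(ids)
  dom <- frame$domain

  # one model matrix over the full finite population; sampled rows first
  cov_cols <- setdiff(union(all.vars(fit$formula[-2]), dom),
                      frame$outcome)
  full <- rbind(frame$sampled[, cov_cols, drop = FALSE],
                frame$nonsampled[, cov_cols, drop = FALSE])
  n_s <- nrow(frame$sampled)
  X <- unit_model_matrix(fit, full)
  did <- as.integer(factor(as.character(full[[dom]]), levels = ids))
  eta0 <- drop(X %*% fit$beta)
  N_i <- frame$districts$N_i
  sv <- sqrt(fit$sigma_v2)
  Xs <- X[seq_len(n_s), , drop = FALSE]
  dids <- did[seq_len(n_s)]
  gh <- pracma::gaussHermite(nAGQ)
  warm <- c(fit$beta, log(max(sv, 1e-4)))

  withr::with_seed(as.integer(seed), {
    sq <- matrix(0, m, 1)
    acc <- numeric(m)
    used <- integer(m)
    failed <- 0
    for (b in seq_len(B)) {
      v_star <- stats::rnorm(m, 0, sv)
      y_star <- stats::rbinom(length(eta0), 1, expit(eta0 + v_star[did]))
      p_truth <- rowsum_vec(y_star, did, m) / N_i
      res <- tryCatch({
        ys <- y_star[seq_len(n_s)]
        rf <- agq_fit(ys, Xs, dids, m, nAGQ = nAGQ, start = warm,
                      reltol = 1e-8)
        if (!all(is.finite(c(rf$beta, rf$sigma_v2, rf$v))))
          stop("non-finite refit")
        # EBP on the bootstrap sample: observed y* for sampled units,
        # refitted plug-in predictions for the rest
        eta_ns <- drop(X[-seq_len(n_s), , drop = FALSE] %*% rf$beta) +
          rf$v[did[-seq_len(n_s)]]
        psum <- rowsum_vec(expit(eta_ns), did[-seq_len(n_s)], m)
        (rowsum_vec(ys, dids, m) + psum) / N_i
      }, error = function(e) NULL)
      if (is.null(res)) {
        failed <- failed + 1
        next
      }
      acc <- acc + (res - p_truth)^2
      used <- used + 1L
    }
    if (failed > 0.2 * B)
      stop(sprintf("bootstrap refit failure rate too high: %d of %d",
                   failed, B), call. = FALSE)
    data.frame(district_id = ids, mse_boot = acc / used, B_used = used,
               row.names = NULL)
  })
}

#' District prevalence by empirical best prediction, with bootstrap MSE
#'
#' Convenience wrapper combining [ebp_prevalence()] and [bootstrap_mse()]
#' into the unit-level analogue of a [direct_estimates()] table, with
#' normal-theory intervals truncated to `[0, 1]` and coefficients of
#' variation based on the bootstrap root-MSE.
#'
#' @inheritParams bootstrap_mse
#' @param level Confidence level (default 0.95).
#' @return `data.frame` of class `"ebp_estimates"`: `district_id`, `p_ebp`,
#'   `mse_boot`, `ci_low`, `ci_high`, `cv_pct`, `n_i`, `N_i`.
#' @export
ebp_estimates <- function(fit, frame, B = 200, seed = 1L, nAGQ = 7,
                          level = 0.95) {
  pe <- ebp_prevalence(fit, frame)
  mb <- bootstrap_mse(fit, frame, B = B, seed = seed, nAGQ = nAGQ)
  zq <- stats::qnorm(1 - (1 - level) / 2)
  rmse <- sqrt(mb$mse_boot)
  out <- data.frame(district_id = pe$district_id, p_ebp = pe$p_ebp,
                    mse_boot = mb$mse_boot,
                    ci_low = pmax(0, pe$p_ebp - zq * rmse),
                    ci_high = pmin(1, pe$p_ebp + zq * rmse),
                    cv_pct = ifelse(pe$p_ebp > 0, 100 * rmse / pe$p_ebp,
                                    NA_real_),
                    n_i = pe$n_i, N_i = pe$N_i, row.names = NULL)
  class(out) <- c("ebp_estimates", "data.frame")
  out
}
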