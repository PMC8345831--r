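# Small fixtures shared across test files. Everything is generated in code;
# sizes are kept small so the whole suite runs quickly.

# a compact population: equal district sizes, few clusters
tiny_pop_config <- function(n_districts = 8, size = 600, seed = 101,
                            sigma_v_true = 0.5, ...) {
  population_config(n_districts = n_districts,
                    district_sizes = rep(size, n_districts),
                    clusters_per_district = 6, seed = seed,
                    sigma_v_true = sigma_v_true, ...)
}

# simulate area-level (Fay-Herriot) data directly from the mixed model
sim_fh_data <- function(m = 70, sigma_v2 = 0.1, beta = c(0, 1),
                        psi_range = c(0.02, 0.3)) {
  z <- stats::rnorm(m)
  psi <- stats::runif(m, psi_range[1], psi_range[2])
  theta_true <- beta[1] + beta[2] * z + stats::rnorm(m, 0, sqrt(sigma_v2))
  theta_hat <- theta_true + stats::rnorm(m, 0, sqrt(psi))
  data.frame(district_id = sprintf("d%03d", seq_len(m)), z = z, psi = psi,
             theta_true = theta_true, theta_hat = theta_hat)
}

# simulate unit-level random-intercept logistic data with one binary covariate
sim_unit_data <- function(m = 20, n = 100, beta = c(-2.7, 0.5),
                          sigma_v2 = 0.25) {
  ids <- sprintf("d%03d", seq_len(m))
  v <- stats::rnorm(m, 0, sqrt(sigma_v2))
  df <- data.frame(district_id = rep(ids, each = n),
                   x = stats::rbinom(m * n, 1, 0.5))
  eta <- beta[1] + beta[2] * df$x + v[as.integer(factor(df$district_id))]
  df$y <- stats::rbinom(m * n, 1, stats::plogis(eta))
  attr(df, "v") <- v
  df
}

# brute-force trapezoid integration of the per-district marginal likelihood,
# independent of the package's quadrature path
trapezoid_loglik <- function(beta, sigma_v, y, X, district,
                             lim = 6, npts = 201) {
  eta0 <- drop(X %*% beta)
  vapply(split(seq_along(y), district), function(rows) {
    v <- seq(-lim, lim, length.out = npts)
    lj <- vapply(v, function(vk) {
      eta <- eta0[rows] + vk
      sum(y[rows] * eta - log(1 + exp(eta))) +
        dnorm(vk, 0, sigma_v, log = TRUE)
    }, 1)
    h <- v[2] - v[1]
    mx <- max(lj)
    # trapezoid rule in log space
    mx + log(h * (sum(exp(lj - mx)) - 0.5 * exp(lj[1] - mx) -
                    0.5 * exp(lj[npts] - mx)))
  }, 1)
}

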