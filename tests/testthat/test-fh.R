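test_that("ML variance matches the equal-psi closed form", {
  # with equal psi and intercept-only design, the profile ML maximizer is
  # sigma_v2 = max(0, SS/m - psi) with SS the centred sum of squares
  withr::with_seed(101, theta <- rnorm(25, -2.5, 0.5))
  psi <- rep(0.04, 25)
  Z <- matrix(1, 25, 1, dimnames = list(NULL, "(Intercept)"))
  SS <- sum((theta - mean(theta))^2)
  closed <- max(0, SS / 25 - 0.04)
  est <- fh_variance(theta, psi, Z, method = "ML")
  expect_equal(est$sigma_v2, closed, tolerance = 1e-6)
})

test_that("optimizer matches a fine grid search of the profile likelihood", {
  for (s in 1:4) {
    withr::with_seed(200 + s, {
      d <- sim_fh_data(m = 10, sigma_v2 = 0.15)
    })
    Z <- cbind(1, d$z)
    for (meth in c("REML", "ML")) {
      est <- fh_variance(d$theta_hat, d$psi, Z, method = meth)
      grid <- seq(0, 1.5, by = 1e-4)
      ll <- vapply(grid, fh_loglik, 1, theta = d$theta_hat, psi = d$psi,
                   Z = Z, reml = meth == "REML")
      expect_lt(abs(est$sigma_v2 - grid[which.max(ll)]), 1.5e-4)
    }
  }
})

test_that("variance estimate piles up at zero when there is no heterogeneity", {
  hits <- vapply(1:40, function(s) {
    withr::with_seed(300 + s, {
      d <- sim_fh_data(m = 30, sigma_v2 = 0)
    })
    fh_variance(d$theta_hat, d$psi, cbind(1, d$z), method = "ML")$sigma_v2
  }, 1)
  expect_gt(mean(hits < 1e-6), 0.5)
})

test_that("GLS coefficients match the normal-equations oracle", {
  withr::with_seed(110, d <- sim_fh_data(m = 40))
  Z <- cbind(`(Intercept)` = 1, z = d$z)
  sv2 <- 0.08
  gls <- fh_gls_beta(d$theta_hat, d$psi, Z, sv2)
  W <- diag(1 / (sv2 + d$psi))
  oracle <- solve(t(Z) %*% W %*% Z) %*% t(Z) %*% W %*% d$theta_hat
  expect_equal(unname(gls$beta), unname(drop(oracle)), tolerance = 1e-8)
  # intercept-only: precision-weighted mean
  Z1 <- matrix(1, 40, 1)
  g1 <- fh_gls_beta(d$theta_hat, d$psi, Z1, sv2)
  w <- 1 / (sv2 + d$psi)
  expect_equal(unname(g1$beta), sum(w * d$theta_hat) / sum(w))
  # constant total variance reduces to OLS
  g2 <- fh_gls_beta(d$theta_hat, rep(0.1, 40), Z, 0.05)
  expect_equal(unname(g2$beta), unname(coef(lm(d$theta_hat ~ d$z))),
               tolerance = 1e-8)
  expect_error(fh_gls_beta(d$theta_hat, d$psi, cbind(Z, z2 = 2 * d$z), sv2),
               "z2")
})

test_that("EBLUP limiting cases hold to machine precision", {
  withr::with_seed(120, d <- sim_fh_data(m = 15))
  Z <- cbind(1, d$z)
  beta <- c(-0.1, 0.9)
  synth <- drop(Z %*% beta)
  # psi = 0: gamma = 1, estimate equals the direct value
  e1 <- fh_eblup(d$theta_hat, rep(0, 15), Z, beta, sigma_v2 = 0.1)
  expect_identical(e1$gamma, rep(1, 15))
  expect_equal(e1$theta_fh, d$theta_hat)
  # sigma_v2 = 0: gamma = 0, estimate equals the synthetic value
  e2 <- fh_eblup(d$theta_hat, d$psi, Z, beta, sigma_v2 = 0)
  expect_identical(e2$gamma, rep(0, 15))
  expect_equal(e2$theta_fh, synth)
  # sigma_v2 = psi: the midpoint
  e3 <- fh_eblup(d$theta_hat, rep(0.1, 15), Z, beta, sigma_v2 = 0.1)
  expect_equal(e3$theta_fh, (d$theta_hat + synth) / 2)
  # missing direct estimate: synthetic with gamma 0
  th <- d$theta_hat; th[3] <- NA
  e4 <- fh_eblup(th, d$psi, Z, beta, sigma_v2 = 0.1)
  expect_equal(e4$gamma[3], 0)
  expect_equal(e4$theta_fh[3], synth[3])
})

test_that("shrinkage factor is exact, monotone in psi, and the EBLUP convex", {
  withr::with_seed(130, d <- sim_fh_data(m = 30))
  fit <- fh_fit(theta_hat ~ z, vardir = "psi", data = d)
  est <- fit$estimates
  expect_equal(est$gamma, fit$sigma_v2 / (fit$sigma_v2 + est$psi))
  # larger psi -> smaller gamma
  o <- order(est$psi)
  expect_true(all(diff(est$gamma[o]) < 0))
  # theta_fh between theta_hat and the synthetic part
  synth <- drop(cbind(1, d$z) %*% fit$beta)
  lo <- pmin(est$theta_hat, synth); hi <- pmax(est$theta_hat, synth)
  expect_true(all(est$theta_fh >= lo - 1e-12 & est$theta_fh <= hi + 1e-12))
})

test_that("Prasad-Rao MSE components behave as required", {
  withr::with_seed(140, d <- sim_fh_data(m = 30))
  Z <- cbind(1, d$z)
  sv2 <- 0.1
  # psi = 0 means the direct estimate is exact: MSE = 0
  mse0 <- fh_mse(rep(0, 30), Z, sv2)
  expect_equal(mse0, rep(0, 30))
  # g1 = gamma psi never exceeds psi
  gamma <- sv2 / (sv2 + d$psi)
  expect_true(all(gamma * d$psi <= d$psi))
  mse <- fh_mse(d$psi, Z, sv2)
  expect_true(all(mse >= gamma * d$psi))  # g2, g3 are non-negative
  # estimated MSE tracks the empirical MSE of the EBLUP
  withr::with_seed(141, {
    m <- 70
    z <- rnorm(m)
    psi <- runif(m, 0.02, 0.3)
    Zs <- cbind(1, z)
    err2 <- matrix(0, 500, m)
    mse_hat <- matrix(0, 500, m)
    for (r in 1:500) {
      th <- 0 + 1 * z + rnorm(m, 0, sqrt(0.1))
      th_hat <- th + rnorm(m, 0, sqrt(psi))
      f <- fh_fit(theta_hat ~ z, vardir = "psi",
                  data = data.frame(theta_hat = th_hat, psi = psi, z = z))
      err2[r, ] <- (f$estimates$theta_fh - th)^2
      mse_hat[r, ] <- f$estimates$mse_logit
    }
    ratio <- mean(colMeans(mse_hat)) / mean(colMeans(err2))
    expect_gt(ratio, 0.75)
    expect_lt(ratio, 1.25)
  })
})

test_that("back transform is exact at the centre and calibrated by delta method", {
  bt <- fh_back_transform(0, 0.04)
  expect_equal(bt$p_fh, 0.5)
  expect_true(bt$ci_low > 0 && bt$ci_high < 1)
  # extreme inputs stay strictly inside (0, 1)
  bt2 <- fh_back_transform(c(-10, 10), c(4, 4))
  expect_true(all(bt2$ci_low > 0 & bt2$ci_high < 1))
  # delta-method variance against Monte-Carlo for moderate mse
  theta <- -2.5; mse <- 0.05
  withr::with_seed(150, sim <- var(expit(rnorm(2e5, theta, sqrt(mse)))))
  delta <- fh_back_transform(theta, mse)$mse_p
  expect_lt(abs(delta - sim) / sim, 0.10)
})

test_that("AIC selection prefers the true linking covariate", {
  withr::with_seed(160, d <- sim_fh_data(m = 40, sigma_v2 = 0.05))
  d$noise <- rnorm(40)
  sel <- fh_select_aic(list(theta_hat ~ z, theta_hat ~ z), vardir = "psi",
                       data = d)
  expect_equal(sel$table$aic[1], sel$table$aic[2])
  # selection consistency over replicates; pure-noise covariate raises AIC
  withr::with_seed(161, {
    wins <- 0; d_aic <- numeric(60)
    for (r in 1:60) {
      dd <- sim_fh_data(m = 40, sigma_v2 = 0.05)
      dd$noise <- rnorm(40)
      s <- fh_select_aic(list(theta_hat ~ z, theta_hat ~ 1,
                              theta_hat ~ z + noise),
                         vardir = "psi", data = dd)
      wins <- wins + (deparse1(s$best) == "theta_hat ~ z")
      aics <- s$table$aic[match(c("theta_hat ~ z", "theta_hat ~ z + noise"),
                                s$table$formula)]
      d_aic[r] <- aics[2] - aics[1]
    }
    expect_gt(wins / 60, 0.5)
    expect_gt(mean(d_aic), 0)
  })
})

test_that("fh_fit carries synthetic-only districts and reports the model", {
  withr::with_seed(170, d <- sim_fh_data(m = 25))
  d$theta_hat[c(4, 9)] <- NA
  d$psi[4] <- NA
  fit <- fh_fit(theta_hat ~ z, vardir = "psi", data = d)
  est <- fit$estimates
  expect_equal(est$gamma[c(4, 9)], c(0, 0))
  expect_equal(est$theta_fh[c(4, 9)],
               drop(cbind(1, d$z[c(4, 9)]) %*% fit$beta))
  expect_true(all(est$mse_logit[c(4, 9)] >= fit$sigma_v2))
  expect_equal(fit$n_fitted, 23)
  expect_true(fit$converged)
  expect_error(fh_fit(theta_hat ~ z, vardir = "psi", data = d[1:3, ]),
               "p \\+ 2")
})
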