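test_that("adaptive quadrature matches brute-force integration on a toy", {
  withr::with_seed(201, d <- sim_unit_data(m = 5, n = 30))
  X <- cbind(1, d$x)
  beta <- c(-2.5, 0.4)
  ll_q <- unit_marginal_loglik(beta, 0.5, d$y, X, d$district_id, nodes = 50)
  ll_t <- trapezoid_loglik(beta, 0.5, d$y, X, d$district_id)
  expect_equal(unname(ll_q), unname(ll_t[names(ll_q)]), tolerance = 1e-6)
})

test_that("the two fitting engines agree with each other and with glm at sigma=0", {
  withr::with_seed(202, d <- sim_unit_data(m = 20, n = 120, sigma_v2 = 0.25))
  f1 <- fit_unit_model(y ~ x, d, nAGQ = 7)
  f2 <- fit_unit_model(y ~ x, d, nAGQ = 7, engine = "agq")
  expect_equal(unname(f1$beta), unname(f2$beta), tolerance = 1e-3)
  expect_equal(f1$sigma_v2, f2$sigma_v2, tolerance = 1e-3)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-5)
  expect_equal(unname(f1$v_hat), unname(f2$v_hat), tolerance = 1e-2)
  # no heterogeneity: random-intercept fit collapses onto plain logistic
  withr::with_seed(203, d0 <- sim_unit_data(m = 20, n = 150, sigma_v2 = 0))
  f0 <- fit_unit_model(y ~ x, d0, nAGQ = 7)
  g0 <- glm(y ~ x, data = d0, family = binomial())
  expect_lt(f0$sigma_v2, 0.05)
  expect_equal(unname(f0$beta), unname(coef(g0)), tolerance = 5e-3)
})

test_that("degenerate inputs are rejected with informative errors", {
  withr::with_seed(204, d <- sim_unit_data(m = 6, n = 40))
  d1 <- d; d1$district_id <- "d001"
  expect_error(fit_unit_model(y ~ x, d1), "two districts")
  d2 <- d; d2$y <- 0
  expect_error(fit_unit_model(y ~ x, d2), "constant")
  d3 <- d; d3$y[d3$x == 1] <- 1
  expect_error(fit_unit_model(y ~ x, d3), "separation.*x")
})

test_that("unit predictions follow the fitted linear predictor exactly", {
  withr::with_seed(205, d <- sim_unit_data(m = 10, n = 80))
  fit <- fit_unit_model(y ~ x, d, nAGQ = 7)
  toy <- data.frame(district_id = c("d001", "d003", "absent"),
                    x = c(1, 0, 0))
  p <- predict_units(fit, toy)
  eta_hand <- c(fit$beta[1] + fit$beta[2] + fit$v_hat["d001"],
                fit$beta[1] + fit$v_hat["d003"],
                fit$beta[1])          # unknown district: v = 0
  expect_equal(unname(p), unname(expit(eta_hand)), tolerance = 1e-12)
  expect_true(all(p > 0 & p < 1))
})

test_that("unseen factor levels are refused by name", {
  withr::with_seed(206, {
    d <- sim_unit_data(m = 6, n = 60)
    d$grp <- factor(sample(c("a", "b"), nrow(d), replace = TRUE))
  })
  fit <- fit_unit_model(y ~ x + grp, d, nAGQ = 7)
  nd <- data.frame(district_id = "d001", x = 0, grp = "c")
  expect_error(predict_units(fit, nd), "unseen level.*grp.*c")
})

test_that("EBP arithmetic matches its definition on hand-computable cases", {
  # fabricated fit with known parameters: intercept 0, no covariates
  fit <- structure(list(beta = c(`(Intercept)` = 0), sigma_v2 = 0.25,
                        v_hat = c(A = 0), formula = y ~ 1,
                        domain = "district_id", xlevels = list(),
                        converged = TRUE, engine = "agq", nAGQ = 7),
                   class = "unit_fit")
  sampled <- data.frame(district_id = c("A", "A"), y = c(1, 0))
  nonsampled <- data.frame(district_id = c("A", "A"))
  fr <- district_frame(sampled, nonsampled)
  expect_equal(fr$districts$N_i, 4)
  # (1 + 0 + 0.5 + 0.5) / 4
  expect_equal(ebp_prevalence(fit, fr)$p_ebp, 0.5)
  # census district: EBP is exactly the sample mean
  fr2 <- district_frame(sampled, nonsampled[0, , drop = FALSE])
  expect_equal(ebp_prevalence(fit, fr2)$p_ebp, 0.5)
  # unsampled district: mean of synthetic predictions with v = 0
  fr3 <- district_frame(sampled, data.frame(district_id = c("B", "B")))
  out <- ebp_prevalence(fit, fr3)
  expect_equal(out$p_ebp[out$district_id == "B"], expit(0))
  # outcome column must not leak into the frame
  expect_error(district_frame(sampled, sampled), "outcome")
})

test_that("bootstrap MSE is deterministic, non-negative, and zero for censuses", {
  withr::with_seed(207, d <- sim_unit_data(m = 8, n = 60))
  fit <- fit_unit_model(y ~ x, d, nAGQ = 7)
  # census: every unit sampled; EBP equals bootstrap truth each replicate
  fr_census <- district_frame(d, d[0, c("district_id", "x")])
  mb0 <- bootstrap_mse(fit, fr_census, B = 10, seed = 3)
  expect_equal(mb0$mse_boot, rep(0, 8))
  # half sampled
  idx <- unlist(lapply(split(seq_len(nrow(d)), d$district_id), head, 30))
  fr <- district_frame(d[idx, ], d[-idx, c("district_id", "x")])
  mb1 <- bootstrap_mse(fit, fr, B = 25, seed = 4)
  mb2 <- bootstrap_mse(fit, fr, B = 25, seed = 4)
  expect_identical(mb1, mb2)
  expect_true(all(mb1$mse_boot >= 0))
  expect_false(identical(mb1$mse_boot,
                         bootstrap_mse(fit, fr, B = 25, seed = 5)$mse_boot))
  # full table wrapper
  est <- ebp_estimates(fit, fr, B = 25, seed = 4)
  expect_true(all(est$ci_low >= 0 & est$ci_high <= 1))
  expect_true(all(est$ci_low <= est$p_ebp & est$p_ebp <= est$ci_high))
  expect_equal(est$mse_boot, mb1$mse_boot)
})

test_that("EBP gains precision over the direct estimator on synthetic data", {
  # qualitative precision/consistency mirror on one moderate simulation
  withr::with_seed(208, {
    pop <- generate_population(tiny_pop_config(n_districts = 12, size = 900,
                                               seed = 209))
    smp <- draw_two_stage_sample(pop, 3, 25, seed = 210)   # n_i = 75
    fr <- lqas_style_frame(pop, 400, seed = 211)
    dir <- direct_estimates(smp)
    fit <- fit_unit_model(y ~ sex + age_group, smp, nAGQ = 7)
    dfm <- district_frame(smp, fr)
    est <- ebp_estimates(fit, dfm, B = 40, seed = 212)
  })
  tab <- merge(as.data.frame(dir), est, by = "district_id")
  expect_lt(mean(tab$mse_boot), mean(tab$se^2))
  # consistency: slope of EBP on direct in (0, 1]
  sl <- bias_regression(tab$p_ebp, tab$p_hat)$slope
  expect_gt(sl, 0)
  expect_lte(sl, 1)
})
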