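test_that("population_config validates its invariants", {
  expect_error(population_config(sigma_v_true = -0.1), "sigma_v_true")
  expect_error(population_config(n_districts = 2,
                                 district_sizes = c(100, 0)),
               ">= 1")
  bad <- default_covariate_marginals()
  bad$sex <- c(male = 0.6, female = 0.5)
  expect_error(population_config(covariate_marginals = bad), "sum to 1")
  expect_error(population_config(n_districts = 3,
                                 district_sizes = rep(10, 4)),
               "length")
})

test_that("population generation is deterministic under a fixed seed", {
  cfg <- tiny_pop_config(seed = 11)
  p1 <- generate_population(cfg)
  p2 <- generate_population(cfg)
  expect_identical(p1$units, p2$units)
  expect_identical(p1$district_effects, p2$district_effects)
})

test_that("true prevalence is the finite-population mean outcome", {
  pop <- generate_population(tiny_pop_config(seed = 3))
  by_hand <- tapply(pop$units$y, pop$units$district_id, mean)
  expect_equal(as.numeric(pop$true_prevalence),
               as.numeric(by_hand[names(pop$true_prevalence)]))
  expect_true(all(pop$units$district_id %in% names(pop$district_effects)))
})

test_that("no-heterogeneity case concentrates prevalence at expit(b0)", {
  beta0 <- default_beta_true() * 0
  beta0["(Intercept)"] <- logit(0.06)
  cfg <- population_config(n_districts = 10, district_sizes = rep(3000, 10),
                           clusters_per_district = 5, beta_true = beta0,
                           sigma_v_true = 0, seed = 21)
  pop <- generate_population(cfg)
  # districtwise binomial sampling error around 0.06 at N_i = 3000
  se_i <- sqrt(0.06 * 0.94 / 3000)
  expect_true(all(abs(pop$true_prevalence - 0.06) < 4 * se_i))
  # pooled rate: law of large numbers at N = 30000
  pooled <- mean(pop$units$y)
  expect_lt(abs(pooled - 0.06), 3 * sqrt(0.06 * 0.94 / 30000))
})

test_that("simulated covariate marginals match the configured shares", {
  # homogeneous composition: the pooled share is the configured marginal
  cfg <- population_config(n_districts = 1, district_sizes = 20000,
                           clusters_per_district = 10, composition_sd = 0,
                           seed = 31)
  pop <- generate_population(cfg)
  male_share <- mean(pop$units$sex == "male")
  expect_lt(abs(male_share - 0.479), 3 * sqrt(0.479 * 0.521 / 20000))
})

test_that("composition heterogeneity varies district covariate structure", {
  base <- list(n_districts = 30, district_sizes = rep(1000, 30),
               clusters_per_district = 4, seed = 32)
  pop0 <- generate_population(do.call(population_config,
                                      c(base, composition_sd = 0)))
  pop1 <- generate_population(do.call(population_config,
                                      c(base, composition_sd = 0.2)))
  share_by_d <- function(pop) tapply(pop$units$sex == "male",
                                     pop$units$district_id, mean)
  # tilted districts vary far more than binomial noise alone
  expect_gt(sd(share_by_d(pop1)), 2 * sd(share_by_d(pop0)))
  # but the pooled (national) share is preserved
  expect_lt(abs(mean(pop1$units$sex == "male") - 0.479), 0.03)
})

test_that("district heterogeneity grows with sigma_v_true", {
  # mean across replicates of the between-district variance of
  # logit(true prevalence), over a 3-point grid of sigma_v_true
  grid <- c(0.1, 0.4, 0.8)
  mean_var <- vapply(seq_along(grid), function(g) {
    vv <- vapply(1:200, function(r) {
      pop <- generate_population(population_config(
        n_districts = 20, district_sizes = rep(250, 20),
        clusters_per_district = 4, sigma_v_true = grid[g],
        seed = 1000 * g + r))
      p <- pmin(pmax(pop$true_prevalence, 1e-4), 1 - 1e-4)
      stats::var(logit(p))
    }, 1)
    mean(vv)
  }, 1)
  expect_true(all(diff(mean_var) > 0))
})

test_that("two-stage sampling yields valid, calibrated weights", {
  # PPS first stage with an equal second-stage take is self-weighting:
  # weights are positive and sum to N_i exactly in every draw
  pop <- generate_population(tiny_pop_config(n_districts = 2, size = 600,
                                             seed = 41))
  withr::with_seed(46, {
    wsums <- replicate(100, {
      s <- draw_two_stage_sample(pop, 3, 20, seed = sample.int(1e6, 1))
      expect_true(all(s$records$weight > 0))
      tapply(s$records$weight, s$records$district_id, sum)
    })
  })
  expect_true(all(abs(wsums - pop$districts$N_i) < 1e-6))
})

test_that("Hajek mean over replicate samples is approximately unbiased", {
  withr::with_seed(43, {
    pop <- generate_population(tiny_pop_config(n_districts = 2, size = 600,
                                               seed = 42))
    phat <- replicate(500, {
      s <- draw_two_stage_sample(pop, 3, 20, seed = sample.int(1e6, 1))
      vapply(split(s$records, s$records$district_id),
             function(d) direct_prevalence(d$y, d$weight), 1)
    })
    mc_se <- apply(phat, 1, sd) / sqrt(ncol(phat))
    bias <- rowMeans(phat) - pop$true_prevalence
    expect_true(all(abs(bias) < 3 * mc_se))
  })
})

test_that("exhaustive sampling is a census with unit weights", {
  pop <- generate_population(tiny_pop_config(n_districts = 2, size = 120,
                                             seed = 44))
  s <- draw_two_stage_sample(pop, 6, 120, seed = 1)   # all clusters, all units
  expect_equal(nrow(s$records), nrow(pop$units))
  expect_equal(s$records$weight, rep(1, nrow(s$records)))
})

test_that("requesting more clusters than a district has fails by name", {
  pop <- generate_population(tiny_pop_config(n_districts = 2, seed = 45))
  expect_error(draw_two_stage_sample(pop, 7, 10, seed = 1), "d001")
})

test_that("ANC-style proxy is exact when noiseless and recovers its noise SD", {
  pop <- generate_population(tiny_pop_config(n_districts = 8, seed = 51))
  z0 <- compute_anc_covariate(pop, anc_bias = 0, anc_noise_sd = 0, seed = 1)
  expect_equal(z0$z_anc, as.numeric(logit(pop$true_prevalence)))
  z1 <- compute_anc_covariate(pop, anc_bias = 0.3, anc_noise_sd = 0.5,
                              seed = 2)
  expect_identical(z1, compute_anc_covariate(pop, anc_bias = 0.3,
                                             anc_noise_sd = 0.5, seed = 2))
  # pooled residual SD over replicate proxy draws
  resid <- unlist(lapply(1:40, function(s)
    compute_anc_covariate(pop, anc_bias = 0.3, anc_noise_sd = 0.5,
                          seed = s)$z_anc - logit(pop$true_prevalence)))
  expect_lt(abs(sd(resid) - 0.5), 3 * 0.5 / sqrt(2 * (length(resid) - 1)))
})

test_that("auxiliary covariate frame strips the outcome and matches marginals", {
  pop <- generate_population(tiny_pop_config(n_districts = 6, size = 1000,
                                             seed = 61))
  fr <- lqas_style_frame(pop, 500, seed = 3)
  expect_false("y" %in% names(fr))
  expect_false("eta" %in% names(fr))
  expect_equal(nrow(fr), 6 * 500)
  # covariate marginals of the frame track the population's
  pop_share <- prop.table(table(pop$units$age_group))
  chi <- suppressWarnings(stats::chisq.test(table(fr$age_group),
                                            p = pop_share))
  expect_gt(chi$p.value, 1e-4)
  # census frame is the population minus outcomes
  fr_all <- lqas_style_frame(pop, 1000, seed = 4)
  expect_equal(nrow(fr_all), nrow(pop$units))
  expect_error(lqas_style_frame(pop, 1001, seed = 5), "exceeds")
})
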