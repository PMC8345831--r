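#' Default covariate marginals for the synthetic population
#'
#' Marginal category frequencies for the five categorical risk covariates
#' (sex, age group, education, marital status, number of sexual partners in
#' the last 12 months) used when generating synthetic populations. The
#' defaults are the weighted respondent percentages of a national
#' population-based HIV survey in Uganda; columns that do not sum exactly to
#' 100% (rounding in the source table) are renormalized. The first level of
#' each covariate is the reference category of the unit-level model (male,
#' age 15-19, no education, single, 0 partners).
#'
#' @return Named list of named probability vectors, each summing to 1.
#' @export
default_covariate_marginals <- function() {
  norm <- function(x) x / sum(x)
  list(
    sex = norm(c(male = 0.479, female = 0.521)),
    age_group = norm(c(`15-19` = 0.239, `20-24` = 0.186, `25-34` = 0.252,
                       `35-44` = 0.163, `45-64` = 0.144)),
    education = norm(c(none = 0.078, primary_incomplete = 0.437,
                       primary = 0.162, secondary_incomplete = 0.240,
                       secondary_plus = 0.083)),
    marital = norm(c(single = 0.311, married = 0.557, widowed = 0.035,
                     separated = 0.098)),
    partners = norm(c(`0` = 0.141, `1` = 0.702, `2plus` = 0.156))
  )
}

#' Default logit-scale coefficients for the synthetic outcome model
#'
#' Named coefficient vector aligned with the treatment-contrast model matrix
#' of `~ sex + age_group + education + marital + partners` under
#' [default_covariate_marginals()]. The intercept and effects are chosen so
#' the population prevalence is about 6% (the national adult HIV prevalence
#' scale), higher for women than men, increasing with age, and increasing
#' with number of partners.
#'
#' @return Named numeric vector of logit-scale coefficients.
#' @export
default_beta_true <- function() {
  c(`(Intercept)` = -4.75,
    sexfemale = 0.5,
    `age_group20-24` = 0.6, `age_group25-34` = 1.2,
    `age_group35-44` = 1.5, `age_group45-64` = 1.3,
    educationprimary_incomplete = 0.1, educationprimary = 0.0,
    educationsecondary_incomplete = -0.1, educationsecondary_plus = -0.2,
    maritalmarried = 0.2, maritalwidowed = 1.0, maritalseparated = 0.8,
    partners1 = 0.3, partners2plus = 0.7)
}

#' Configuration of a synthetic finite population
#'
#' Bundles and validates the parameters of the synthetic-population
#' generator: number of districts, district population sizes, number of
#' enumeration-area-like clusters per district, the logit-scale outcome
#' model (`beta_true`, district-effect standard deviation `sigma_v_true`),
#' covariate marginals, and the bias/noise of the antenatal-care-style
#' area-level proxy covariate.
#'
#' @param n_districts Number of districts (default 70).
#' @param district_sizes Integer vector of district population sizes `N_i`
#'   (length `n_districts`), or `NULL` to draw them uniformly from
#'   `size_range` when the population is generated.
#' @param size_range Range district sizes are drawn from when
#'   `district_sizes` is `NULL` (default 2,000-20,000 individuals).
#' @param clusters_per_district Number of clusters each district's
#'   population is partitioned into (default 40). Cluster sizes are drawn
#'   log-normally around `N_i / clusters_per_district`, so
#'   probability-proportional-to-size sampling is non-trivial.
#' @param beta_true Named logit-scale coefficient vector for the outcome
#'   model; must match the model matrix implied by `covariate_marginals`.
#' @param sigma_v_true Standard deviation (logit scale) of the district
#'   random effects; must be `>= 0`.
#' @param covariate_marginals Named list of category-probability vectors,
#'   each summing to 1 (within 1e-9); these are the national marginals.
#' @param composition_sd District-level covariate-composition heterogeneity:
#'   each district draws its own category probabilities by tilting the
#'   national marginals with independent `N(0, composition_sd^2)` log-odds
#'   perturbations (renormalized). Districts therefore differ in age,
#'   education, and similar structure, the way urban and rural districts
#'   do; `0` gives identical composition everywhere. The default 0.2
#'   makes district sex shares vary by a few percentage points and age or
#'   education structure by ~10-20% in relative terms.
#' @param anc_bias Logit-scale offset of the area-level proxy covariate
#'   relative to true prevalence (default 0.3).
#' @param anc_noise_sd Logit-scale noise SD of the proxy (default 1.0,
#'   making the proxy weakly informative: routine antenatal surveillance
#'   tracks general-population prevalence poorly — selection into ANC,
#'   facility coverage and reporting all distort it — so the area-level
#'   model smooths hard toward a flat synthetic component, as observed in
#'   the motivating study).
#' @param seed Integer seed used by [generate_population()].
#' @return An object of class `"population_config"`.
#' @seealso [generate_population()], [draw_two_stage_sample()]
#' @export
population_config <- function(n_districts = 70,
                              district_sizes = NULL,
                              size_range = c(2000, 20000),
                              clusters_per_district = 40,
                              beta_true = default_beta_true(),
                              sigma_v_true = 0.5,
                              covariate_marginals = default_covariate_marginals(),
                              composition_sd = 0.2,
                              anc_bias = 0.3,
                              anc_noise_sd = 1.0,
                              seed = 1L) {
  n_districts <- check_count(n_districts, "n_districts")
  clusters_per_district <- check_count(clusters_per_district,
                                       "clusters_per_district")
  if (!is.null(district_sizes)) {
    if (length(district_sizes) != n_districts)
      stop("`district_sizes` must have length `n_districts`", call. = FALSE)
    if (any(district_sizes < 1))
      stop("all district sizes must be >= 1", call. = FALSE)
    district_sizes <- as.integer(district_sizes)
  }
  if (!is.finite(sigma_v_true) || sigma_v_true < 0)
    stop("`sigma_v_true` must be >= 0", call. = FALSE)
  if (!is.finite(composition_sd) || composition_sd < 0)
    stop("`composition_sd` must be >= 0", call. = FALSE)
  for (nm in names(covariate_marginals)) {
    p <- covariate_marginals[[nm]]
    if (is.null(names(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-9)
      stop(sprintf("marginals for `%s` must be named, non-negative and sum to 1",
                   nm), call. = FALSE)
  }
  if (!all(is.finite(beta_true)))
    stop("`beta_true` must be finite", call. = FALSE)
  structure(
    list(n_districts = n_districts, district_sizes = district_sizes,
         size_range = size_range,
         clusters_per_district = clusters_per_district,
         beta_true = beta_true, sigma_v_true = sigma_v_true,
         covariate_marginals = covariate_marginals,
         composition_sd = composition_sd,
         anc_bias = anc_bias, anc_noise_sd = anc_noise_sd,
         seed = as.integer(seed)),
    class = "population_config")
}

# partition N into k cluster sizes, log-normal around N/k, summing to N
draw_cluster_sizes <- function(N, k, sdlog = 0.4) {
  if (k == 1) return(N)
  raw <- stats::rlnorm(k, meanlog = log(N / k) - sdlog^2 / 2, sdlog = sdlog)
  sizes <- pmax(1L, as.integer(round(raw * N / sum(raw))))
  # fix rounding so sizes sum exactly to N
  diff <- N - sum(sizes)
  while (diff > 0) { i <- which.min(sizes); sizes[i] <- sizes[i] + 1L; diff <- diff - 1L }
  while (diff < 0) { i <- which.max(sizes); sizes[i] <- sizes[i] - 1L; diff <- diff + 1L }
  sizes
}

#' Generate a synthetic finite population
#'
#' Builds a finite population of individuals nested in clusters nested in
#' districts. Each district `i` receives a random effect
#' `v_i ~ N(0, sigma_v_true^2)` on the logit scale; each individual's
#' covariates are drawn independently from the configured marginals and the
#' binary outcome from `Bernoulli(expit(X'beta_true + v_i))`. The district
#' finite-population prevalence is the mean outcome over all its units.
#'
#' @param config A [population_config()].
#' @return An object of class `"sae_population"`: a list with `units` (one
#'   row per individual: `district_id`, `cluster_id`, covariates, linear
#'   predictor `eta`, outcome `y`), `district_effects`, `true_prevalence`,
#'   a `districts` table (`district_id`, `N_i`), and the `config`.
#' @examples
#' pop <- generate_population(population_config(
#'   n_districts = 4, district_sizes = rep(500, 4), seed = 7))
#' pop$true_prevalence
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "population_config"))
  withr::with_seed(config$seed, {
    m <- config$n_districts
    ids <- sprintf("d%03d", seq_len(m))
    N <- config$district_sizes
    if (is.null(N))
      N <- as.integer(round(stats::runif(m, config$size_range[1],
                                         config$size_range[2])))
    v <- stats::rnorm(m, 0, config$sigma_v_true)
    names(v) <- ids

    k <- config$clusters_per_district
    sizes_by_d <- lapply(seq_len(m), function(i)
      draw_cluster_sizes(N[i], min(k, N[i])))
    n_total <- sum(N)
    district_id <- factor(rep(ids, N), levels = ids)
    cluster_id <- unlist(lapply(seq_len(m), function(i)
      rep(sprintf("%s_c%03d", ids[i], seq_along(sizes_by_d[[i]])),
          sizes_by_d[[i]])), use.names = FALSE)

    marg <- config$covariate_marginals
    cs <- config$composition_sd %||% 0
    rows_by_d <- split(seq_len(n_total), district_id)
    covs <- lapply(marg, function(p) {
      if (cs == 0) {
        draws <- sample(names(p), n_total, replace = TRUE, prob = p)
      } else {
        # district-specific composition: log-odds tilt of the national
        # marginals, drawn once per district and category
        draws <- character(n_total)
        for (i in seq_len(m)) {
          tilt <- p * exp(stats::rnorm(length(p), 0, cs))
          rows <- rows_by_d[[i]]
          draws[rows] <- sample(names(p), length(rows), replace = TRUE,
                                prob = tilt / sum(tilt))
        }
      }
      factor(draws, levels = names(p))
    })
    units <- data.frame(district_id = district_id, cluster_id = cluster_id,
                        covs, stringsAsFactors = FALSE)

    X <- stats::model.matrix(
      stats::reformulate(names(marg)), data = units)
    beta <- config$beta_true
    if (!setequal(colnames(X), names(beta)))
      stop("`beta_true` names do not match the model matrix columns: ",
           paste(setdiff(colnames(X), names(beta)), collapse = ", "),
           call. = FALSE)
    eta <- drop(X %*% beta[colnames(X)]) + v[as.integer(district_id)]
    if (!all(is.finite(eta)))
      stop("non-finite linear predictor; check `beta_true`", call. = FALSE)
    units$eta <- eta
    units$y <- stats::rbinom(n_total, 1, expit(eta))

    p_true <- tapply(units$y, units$district_id, mean)
    structure(
      list(units = units, district_effects = v,
           true_prevalence = p_true[ids],
           districts = data.frame(district_id = ids, N_i = N),
           config = config),
      class = "sae_population")
  })
}

#' @export
print.sae_population <- function(x, ...) {
  cat(sprintf("Synthetic population: %d districts, %d units\n",
              nrow(x$districts), nrow(x$units)))
  cat(sprintf("  true prevalence: %.3f-%.3f (mean %.3f)\n",
              min(x$true_prevalence), max(x$true_prevalence),
              mean(x$true_prevalence)))
  invisible(x)
}

# PPS inclusion probabilities with iterative certainty handling;
# returns pi_k for selecting n of the clusters with sizes M
pps_inclusion_prob <- function(M, n) {
  pi <- rep(0, length(M))
  remaining <- seq_along(M)
  n_r <- n
  repeat {
    p <- n_r * M[remaining] / sum(M[remaining])
    certain <- p >= 1
    if (!any(certain) || n_r == 0) {
      pi[remaining] <- p
      break
    }
    pi[remaining[certain]] <- 1
    n_r <- n_r - sum(certain)
    remaining <- remaining[!certain]
    if (!length(remaining) || n_r == 0) break
  }
  pi
}

# systematic PPS draw of the non-certainty clusters given target probs
pps_systematic <- function(pi) {
  sel <- which(pi >= 1)
  rest <- which(pi < 1 & pi > 0)
  if (length(rest)) {
    rest <- sample(rest)                     # randomize order
    cum <- cumsum(pi[rest])
    n_r <- round(cum[length(cum)])
    if (n_r > 0) {
      start <- stats::runif(1)
      hits <- start + seq_len(n_r) - 1
      idx <- findInterval(hits, c(0, cum), left.open = TRUE)
      sel <- c(sel, rest[idx])
    }
  }
  sort(sel)
}

#' Draw a two-stage cluster sample from a synthetic population
#'
#' First stage: within each district (the stratum), clusters are selected by
#' systematic probability-proportional-to-size sampling (size = number of
#' individuals), with clusters whose scaled size exceeds the sampling
#' interval included with certainty. Second stage: a simple random sample of
#' individuals within each selected cluster. Each record's design weight is
#' the inverse of its overall inclusion probability, so weights sum to
#' (approximately) the district population size.
#'
#' @param pop An [generate_population()] result.
#' @param clusters_per_district Number of clusters to select per district;
#'   scalar or one value per district.
#' @param units_per_cluster Number of individuals to sample per selected
#'   cluster; clusters smaller than this are taken completely.
#' @param seed Integer seed.
#' @return An object of class `"survey_sample"`: list with `records` (one
#'   row per respondent: `district_id`, `cluster_id`, `stratum_id`,
#'   `weight`, covariates, `y`) and `design` (stratum and PSU column names).
#' @export
draw_two_stage_sample <- function(pop, clusters_per_district,
                                  units_per_cluster, seed = 1L) {
  stopifnot(inherits(pop, "sae_population"))
  units_per_cluster <- check_count(units_per_cluster, "units_per_cluster")
  ids <- pop$districts$district_id
  m <- length(ids)
  n_c <- rep(as.integer(clusters_per_district), length.out = m)

  rows_by_d <- split(seq_len(nrow(pop$units)), pop$units$district_id)
  withr::with_seed(as.integer(seed), {
    rec <- vector("list", m)
    for (i in seq_len(m)) {
      du <- pop$units[rows_by_d[[ids[i]]], , drop = FALSE]
      cl <- unique(du$cluster_id)
      if (length(cl) < n_c[i])
        stop(sprintf("district %s has %d clusters, %d requested",
                     ids[i], length(cl), n_c[i]), call. = FALSE)
      M <- as.vector(table(factor(du$cluster_id, levels = cl)))
      pi1 <- pps_inclusion_prob(M, n_c[i])
      sel <- pps_systematic(pi1)
      picked <- lapply(sel, function(k) {
        in_cl <- which(du$cluster_id == cl[k])
        m_k <- min(units_per_cluster, M[k])
        j <- if (m_k == M[k]) in_cl else sample(in_cl, m_k)
        w <- (1 / pi1[k]) * (M[k] / m_k)
        cbind(du[j, , drop = FALSE], weight = w)
      })
      rec[[i]] <- do.call(rbind, picked)
    }
    records <- do.call(rbind, rec)
    rownames(records) <- NULL
    records$stratum_id <- as.character(records$district_id)
    records$eta <- NULL
    structure(list(records = records,
                   design = list(strata = "stratum_id",
                                 psu = "cluster_id")),
              class = "survey_sample")
  })
}

#' @export
print.survey_sample <- function(x, ...) {
  cat(sprintf("Two-stage survey sample: %d records, %d districts, %d PSUs\n",
              nrow(x$records), length(unique(x$records$district_id)),
              length(unique(x$records$cluster_id))))
  invisible(x)
}

#' Area-level proxy covariate emulating routine ANC prevalence
#'
#' Produces, for each district, a biased and noisy logit-scale proxy of the
#' true prevalence: `z_i = logit(p_i) + anc_bias + N(0, anc_noise_sd^2)`.
#' This emulates an antenatal-care (routine surveillance) prevalence series
#' used as the auxiliary covariate of the area-level model: correlated with
#' true prevalence but systematically offset and noisy.
#'
#' @param pop An [generate_population()] result with all true prevalences
#'   strictly inside (0, 1).
#' @param anc_bias,anc_noise_sd Logit-scale offset and noise SD; default to
#'   the values in `pop$config`.
#' @param seed Integer seed.
#' @return `data.frame` with columns `district_id`, `z_anc`.
#' @export
compute_anc_covariate <- function(pop, anc_bias = NULL, anc_noise_sd = NULL,
                                  seed = 1L) {
  stopifnot(inherits(pop, "sae_population"))
  if (is.null(anc_bias)) anc_bias <- pop$config$anc_bias
  if (is.null(anc_noise_sd)) anc_noise_sd <- pop$config$anc_noise_sd
  p <- pop$true_prevalence
  if (any(p <= 0 | p >= 1))
    stop("true prevalence of 0 or 1: logit proxy undefined for district(s) ",
         paste(names(p)[p <= 0 | p >= 1], collapse = ", "), call. = FALSE)
  withr::with_seed(as.integer(seed), {
    z <- logit(p) + anc_bias + stats::rnorm(length(p), 0, anc_noise_sd)
    data.frame(district_id = names(p), z_anc = as.numeric(z),
               row.names = NULL)
  })
}

#' Covariate-only unit frame emulating an auxiliary community survey
#'
#' Draws a per-district simple random subsample of population units and
#' strips the outcome (and latent linear predictor), mimicking an auxiliary
#' unit-level covariate source — such as annual lot-quality-assurance-style
#' community surveys — that records risk factors but not the outcome. The
#' unit-level model predicts outcome probabilities over this frame.
#'
#' @param pop An [generate_population()] result.
#' @param per_district_n Units to draw per district; scalar or one value per
#'   district; must not exceed any district's population size.
#' @param seed Integer seed.
#' @return `data.frame` of sampled units with `district_id`, `cluster_id`
#'   and covariate columns only.
#' @export
lqas_style_frame <- function(pop, per_district_n, seed = 1L) {
  stopifnot(inherits(pop, "sae_population"))
  ids <- pop$districts$district_id
  n <- rep(as.integer(per_district_n), length.out = length(ids))
  if (any(n > pop$districts$N_i))
    stop("`per_district_n` exceeds the population size of district(s) ",
         paste(ids[n > pop$districts$N_i], collapse = ", "), call. = FALSE)
  rows_by_d <- split(seq_len(nrow(pop$units)), pop$units$district_id)
  withr::with_seed(as.integer(seed), {
    take <- unlist(lapply(seq_along(ids), function(i) {
      rows <- rows_by_d[[ids[i]]]
      if (n[i] == length(rows)) rows else sample(rows, n[i])
    }), use.names = FALSE)
    frame <- pop$units[take, , drop = FALSE]
    frame$y <- NULL
    frame$eta <- NULL
    rownames(frame) <- NULL
    frame
  })
}
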