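# ---- End-to-end pipeline: simulate -> direct -> FH -> EBP -> compare ------

#' Pipeline configuration
#'
#' Assembles and validates the configuration of [run_pipeline()]: the
#' synthetic-population block, the two-stage sample design, the area-level
#' candidate models, the unit-level model formula, the bootstrap size and
#' the master seed. Can also be read from / written to YAML (formulas are
#' stored as strings).
#'
#' @param population A [population_config()] (its `seed` is overridden by a
#'   seed derived from `master_seed`).
#' @param clusters_per_district Clusters sampled per district; `NULL`
#'   (default) selects `pmax(2, round(N_i / 1000))`, giving survey sample
#'   sizes that grow with district population size.
#' @param units_per_cluster Individuals sampled per selected cluster
#'   (default 25, a typical household-survey cluster take).
#' @param frame_per_district Units per district in the auxiliary
#'   covariate-only frame (default 475, the scale of an annual
#'   community-survey round across population groups).
#' @param fh_candidates List of area-level linking-model formulas (or
#'   strings); with more than one candidate the pipeline picks the lowest
#'   ML-AIC model.
#' @param unit_formula Fixed-effects formula (or string) of the unit-level
#'   model.
#' @param bootstrap_B Parametric-bootstrap replicates (default 200).
#' @param unit_engine Fitting engine for the unit-level model, `"glmer"`
#'   (default) or the package's `"agq"` fitter (see [fit_unit_model()]).
#' @param master_seed Master seed; every stochastic stage uses
#'   [derive_seed()] of this seed and its stage name.
#' @return Object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(population = population_config(),
                            clusters_per_district = NULL,
                            units_per_cluster = 25,
                            frame_per_district = 475,
                            fh_candidates = list(theta_hat ~ z_anc),
                            unit_formula = y ~ sex + age_group + education +
                              marital + partners,
                            bootstrap_B = 200,
                            unit_engine = c("glmer", "agq"),
                            master_seed = 1L) {
  stopifnot(inherits(population, "population_config"))
  if (!is.list(fh_candidates)) fh_candidates <- list(fh_candidates)
  fh_candidates <- lapply(fh_candidates, stats::as.formula)
  unit_formula <- stats::as.formula(unit_formula)
  structure(list(population = population,
                 clusters_per_district = clusters_per_district,
                 units_per_cluster = check_count(units_per_cluster,
                                                 "units_per_cluster"),
                 frame_per_district = check_count(frame_per_district,
                                                  "frame_per_district"),
                 fh_candidates = fh_candidates,
                 unit_formula = unit_formula,
                 bootstrap_B = check_count(bootstrap_B, "bootstrap_B",
                                           min = 2L),
                 unit_engine = match.arg(unit_engine),
                 master_seed = as.integer(master_seed)),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config A [pipeline_config()].
#' @return `read_pipeline_config()` returns a `"pipeline_config"`;
#'   `write_pipeline_config()` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pc <- y$population
  marg <- if (!is.null(pc$covariate_marginals))
    lapply(pc$covariate_marginals, unlist) else default_covariate_marginals()
  beta <- if (!is.null(pc$beta_true)) unlist(pc$beta_true) else
    default_beta_true()
  pop <- population_config(
    n_districts = pc$n_districts %||% 70,
    district_sizes = pc$district_sizes,
    size_range = unlist(pc$size_range) %||% c(2000, 20000),
    clusters_per_district = pc$clusters_per_district %||% 40,
    beta_true = beta, sigma_v_true = pc$sigma_v_true %||% 0.5,
    covariate_marginals = marg,
    composition_sd = pc$composition_sd %||% 0.2,
    anc_bias = pc$anc_bias %||% 0.3, anc_noise_sd = pc$anc_noise_sd %||% 1.0)
  pipeline_config(
    population = pop,
    clusters_per_district = y$clusters_per_district,
    units_per_cluster = y$units_per_cluster %||% 25,
    frame_per_district = y$frame_per_district %||% 475,
    fh_candidates = lapply(y$fh_candidates %||% list("theta_hat ~ z_anc"),
                           stats::as.formula),
    unit_formula = stats::as.formula(
      y$unit_formula %||%
        "y ~ sex + age_group + education + marital + partners"),
    bootstrap_B = y$bootstrap_B %||% 200,
    unit_engine = y$unit_engine %||% "glmer",
    master_seed = y$master_seed %||% 1L)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  pc <- config$population
  y <- list(
    population = list(
      n_districts = pc$n_districts, district_sizes = pc$district_sizes,
      size_range = pc$size_range,
      clusters_per_district = pc$clusters_per_district,
      beta_true = as.list(pc$beta_true), sigma_v_true = pc$sigma_v_true,
      covariate_marginals = lapply(pc$covariate_marginals, as.list),
      composition_sd = pc$composition_sd,
      anc_bias = pc$anc_bias, anc_noise_sd = pc$anc_noise_sd),
    clusters_per_district = config$clusters_per_district,
    units_per_cluster = config$units_per_cluster,
    frame_per_district = config$frame_per_district,
    fh_candidates = lapply(config$fh_candidates, deparse1),
    unit_formula = deparse1(config$unit_formula),
    bootstrap_B = config$bootstrap_B,
    unit_engine = config$unit_engine,
    master_seed = config$master_seed)
  yaml::write_yaml(y, path, precision = 15)
  invisible(path)
}

#' Validate pipeline input tables
#'
#' Schema and cross-reference checks on user-supplied tables: required
#' columns, strictly positive weights, binary outcome, and district
#' alignment between the sampled records and the auxiliary tables. Returns
#' a machine-readable issue list instead of failing, so callers can report
#' all problems at once.
#'
#' @param records Survey records table (`district_id`, `cluster_id`,
#'   `weight`, `y`, covariates).
#' @param frame Optional covariate-only frame (`district_id`, covariates).
#' @param anc Optional area-level covariate table (`district_id`, `z_anc`).
#' @return `data.frame` with columns `table`, `row`, `column`, `problem`
#'   (zero rows when everything is clean).
#' @export
validate_inputs <- function(records, frame = NULL, anc = NULL) {
  issues <- list()
  add <- function(table, row, column, problem)
    issues[[length(issues) + 1]] <<- data.frame(
      table = table, row = row, column = column, problem = problem)

  need <- c("district_id", "cluster_id", "weight", "y")
  for (col in setdiff(need, names(records)))
    add("records", NA, col, "missing column")
  if ("weight" %in% names(records))
    for (r in which(!is.finite(records$weight) | records$weight <= 0))
      add("records", r, "weight", "non-positive or non-finite weight")
  if ("y" %in% names(records))
    for (r in which(!records$y %in% c(0, 1)))
      add("records", r, "y", "outcome not in {0, 1}")
  if ("district_id" %in% names(records)) {
    rec_d <- unique(as.character(records$district_id))
    if (!is.null(frame) && "district_id" %in% names(frame))
      for (d in setdiff(rec_d, unique(as.character(frame$district_id))))
        add("frame", NA, "district_id",
            paste0("district ", d, " sampled but absent from frame"))
    if (!is.null(anc) && "district_id" %in% names(anc))
      for (d in setdiff(rec_d, unique(as.character(anc$district_id))))
        add("anc", NA, "district_id",
            paste0("district ", d, " sampled but absent from covariates"))
  }
  if (!is.null(frame) && !"district_id" %in% names(frame))
    add("frame", NA, "district_id", "missing column")
  if (!is.null(anc) && !all(c("district_id", "z_anc") %in% names(anc)))
    add("anc", NA, "district_id/z_anc", "missing column")
  if (!length(issues))
    return(data.frame(table = character(), row = integer(),
                      column = character(), problem = character()))
  out <- do.call(rbind, issues)
  rownames(out) <- NULL
  out
}

#' Run the full small-area-estimation pipeline
#'
#' Executes, in order: synthetic-population generation, two-stage sampling,
#' direct estimation, area-level (Fay-Herriot) modelling on the synthetic
#' ANC-style covariate, unit-level modelling with empirical best prediction
#' and bootstrap MSE, and the comparison diagnostics. All stage seeds are
#' derived deterministically from the master seed, so identical
#' configurations give identical outputs. When `out_dir` is given, all
#' estimate tables are written as CSV together with the configuration
#' (YAML) and a JSON manifest (seeds, record counts, package version).
#'
#' @param config A [pipeline_config()] or a path to its YAML form.
#' @param out_dir Optional output directory (created if needed).
#' @param quiet Suppress per-stage progress messages.
#' @return List with `population`, `sample`, `direct`, `anc`, `fh`
#'   (and `fh_selection` when several candidates were given), `unit_fit`,
#'   `unit`, `comparison`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(...)
  seeds <- vapply(c("population", "sample", "anc", "frame", "bootstrap"),
                  function(s) derive_seed(config$master_seed, s), 1L)

  say("simulate: generating population")
  popcfg <- config$population
  popcfg$seed <- seeds[["population"]]
  pop <- generate_population(popcfg)

  say("simulate: drawing two-stage sample")
  n_c <- config$clusters_per_district %||%
    pmax(2, round(pop$districts$N_i / 1000))
  smp <- draw_two_stage_sample(pop, n_c, config$units_per_cluster,
                               seed = seeds[["sample"]])

  say("direct: design-weighted estimates")
  direct <- direct_estimates(smp)

  say("fh: area-level model")
  anc <- compute_anc_covariate(pop, seed = seeds[["anc"]])
  fh_in <- merge(as.data.frame(direct), anc, by = "district_id")
  if (length(config$fh_candidates) > 1) {
    sel <- fh_select_aic(config$fh_candidates, vardir = "psi", data = fh_in)
    fh <- sel$best_fit
  } else {
    sel <- NULL
    fh <- fh_fit(config$fh_candidates[[1]], vardir = "psi", data = fh_in)
  }

  say("unit: logistic mixed model and EBP")
  frame <- lqas_style_frame(pop, config$frame_per_district,
                            seed = seeds[["frame"]])
  ufit <- fit_unit_model(config$unit_formula, smp,
                         engine = config$unit_engine %||% "glmer")
  dframe <- district_frame(smp, frame)
  unit <- ebp_estimates(ufit, dframe, B = config$bootstrap_B,
                        seed = seeds[["bootstrap"]])

  say("compare: precision and consistency diagnostics")
  comparison <- compare_estimates(direct, fh, unit)

  manifest <- list(
    package_version = as.character(utils::packageVersion("saeprev")),
    master_seed = config$master_seed, stage_seeds = as.list(seeds),
    n_districts = nrow(pop$districts), n_units = nrow(pop$units),
    n_records = nrow(smp$records), n_frame = nrow(frame),
    bootstrap_B = config$bootstrap_B,
    fh_formula = deparse1(fh$formula),
    unit_formula = deparse1(config$unit_formula),
    fh_sigma_v2 = fh$sigma_v2, unit_sigma_v2 = ufit$sigma_v2)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(smp$records, file.path(out_dir, "survey_sample.csv"),
                     row.names = FALSE)
    utils::write.csv(anc, file.path(out_dir, "anc_covariate.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(direct),
                     file.path(out_dir, "direct_estimates.csv"),
                     row.names = FALSE)
    utils::write.csv(fh$estimates, file.path(out_dir, "fh_estimates.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(unit),
                     file.path(out_dir, "unit_estimates.csv"),
                     row.names = FALSE)
    utils::write.csv(comparison$estimates,
                     file.path(out_dir, "comparison.csv"), row.names = FALSE)
    write_pipeline_config(config, file.path(out_dir, "config.yaml"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(population = pop, sample = smp, direct = direct, anc = anc,
                 fh = fh, fh_selection = sel, unit_fit = ufit, unit = unit,
                 comparison = comparison, manifest = manifest))
}
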