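# Pipeline orchestration: staged, file-based, deterministic. Each stage
# reads its predecessors' serialized outputs and writes its own, so any
# stage can be rerun in isolation.

#' Default pipeline configuration
#'
#' A flat list of every tunable in the pipeline, each with a default.
#' The configuration used for a run is serialized into the output directory
#' for provenance.
#'
#' @param seed Integer seed driving all randomness.
#' @param outdir Output directory.
#' @return Named list of settings.
#' @export
default_config <- function(seed = 1L, outdir = "growthfpca-run") {
  list(
    seed = as.integer(seed),
    outdir = outdir,
    # generator
    n_male = 330L,
    n_female = 296L,
    noise_sd = 0.3,
    use_covariate_effects = TRUE,
    # filtering
    min_obs = 5L,
    # fpca
    grid_points = 101L,
    bandwidth_mean = "auto",
    bandwidth_cov = "auto",
    n_components = 2L,
    # reference system
    percentiles = c(2, 5, 10, 25, 50, 75, 90, 95, 98),
    n_times = 18L,
    stratum_percentiles = c(2, 5, 10, 25),
    merged_top = c(50, 75, 90, 95, 98),
    # report
    figures = TRUE
  )
}

#' Load a pipeline configuration from a YAML file
#'
#' Keys present in the file override the defaults; unknown keys are an
#' error (they are almost always typos).
#'
#' @param path YAML file.
#' @param ... Further overrides applied after the file.
#' @return Named list of settings.
#' @export
load_config <- function(path = NULL, ...) {
  config <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(config))
    if (length(unknown) > 0) {
      stop("unknown config key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    config[names(user)] <- user
  }
  dots <- list(...)
  config[names(dots)] <- dots
  config$seed <- as.integer(config$seed)
  config
}

config_paths <- function(config) {
  o <- config$outdir
  list(
    config = file.path(o, "config.yaml"),
    observations = file.path(o, "observations.csv"),
    covariates = file.path(o, "covariates.csv"),
    truth = file.path(o, "truth.csv"),
    model = function(sex) file.path(o, sprintf("model_%s.json", sex)),
    scores = function(sex) file.path(o, sprintf("scores_%s.csv", sex)),
    reference = function(sex) file.path(o, sprintf("reference_%s.json", sex)),
    faltering = function(sex) file.path(o, sprintf("faltering_%s.csv", sex)),
    strata = function(sex) file.path(o, sprintf("strata_summary_%s.csv", sex)),
    regression = function(sex) file.path(o, sprintf("regression_%s.csv", sex)),
    diagnostics = function(sex) file.path(o, sprintf("diagnostics_%s.csv", sex)),
    fig = function(name) file.path(o, sprintf("fig_%s.png", name))
  )
}

require_artifact <- function(path) {
  if (!file.exists(path)) {
    stop("missing upstream artifact: ", path,
         " (run the earlier pipeline stages first)", call. = FALSE)
  }
  path
}

present_sexes <- function(cohort) {
  intersect(c("male", "female"), unique(cohort$observations$sex))
}

#' Run pipeline stages
#'
#' Stages: `"simulate"` (write observation/covariate/truth CSVs from the
#' seeded generator), `"fit"` (per-sex sparse FPCA after the minimum-visit
#' filter), `"score"` (reference system + adj-FPC2), `"regress"`
#' (risk-factor regression), `"report"` (diagnostic tables and figures), or
#' `"all"`.
#'
#' @param config See [default_config()] / [load_config()].
#' @param stage Stage name.
#' @return Invisibly, the list of files written.
#' @export
run_pipeline <- function(config = default_config(), stage = "all") {
  stages <- c("simulate", "fit", "score", "regress", "report")
  stage <- match.arg(stage, c(stages, "all"))
  todo <- if (stage == "all") stages else stage
  if (!dir.exists(config$outdir) &&
      !dir.create(config$outdir, recursive = TRUE)) {
    stop("cannot create output directory ", config$outdir, call. = FALSE)
  }
  yaml::write_yaml(config, config_paths(config)$config)
  written <- character(0)
  for (s in todo) {
    written <- c(written, switch(s,
      simulate = stage_simulate(config),
      fit = stage_fit(config),
      score = stage_score(config),
      regress = stage_regress(config),
      report = stage_report(config)
    ))
  }
  invisible(written)
}

stage_simulate <- function(config) {
  p <- config_paths(config)
  effects <- if (isTRUE(config$use_covariate_effects)) {
    default_covariate_effects()
  } else NULL
  sims <- list(
    male = simulate_cohort(default_generative_model(
      "male", n_children = config$n_male, noise_sd = config$noise_sd,
      grid = default_grid(config$grid_points),
      covariate_effects = effects), seed = config$seed),
    female = simulate_cohort(default_generative_model(
      "female", n_children = config$n_female, noise_sd = config$noise_sd,
      grid = default_grid(config$grid_points),
      covariate_effects = effects), seed = config$seed + 1000L)
  )
  obs <- rbind(sims$male$cohort$observations, sims$female$cohort$observations)
  covs <- rbind(sims$male$cohort$covariates, sims$female$cohort$covariates)
  truth <- rbind(sims$male$truth, sims$female$truth)
  cohort <- haz_cohort(obs, covariates = covs)
  write_cohort(cohort, p$observations,
               covariate_path = if (!is.null(covs)) p$covariates else NULL)
  write_truth(truth, p$truth)
  message("simulate: ", n_children(cohort), " children enrolled (seed ",
          config$seed, ")")
  c(p$observations, if (!is.null(covs)) p$covariates, p$truth)
}

load_stage_cohort <- function(config) {
  p <- config_paths(config)
  require_artifact(p$observations)
  cov_path <- if (file.exists(p$covariates)) p$covariates else NULL
  read_cohort(p$observations, covariate_path = cov_path)
}

stage_fit <- function(config) {
  p <- config_paths(config)
  cohort <- load_stage_cohort(config)
  n_before <- n_children(cohort)
  cohort <- filter_min_observations(cohort, config$min_obs)
  message("fit: ", n_before, " children enrolled, ", n_children(cohort),
          " with >= ", config$min_obs, " observations")
  parts <- split_by_sex(cohort)
  written <- character(0)
  settings <- fpca_settings(grid = default_grid(config$grid_points),
                            bandwidth_mean = config$bandwidth_mean,
                            bandwidth_cov = config$bandwidth_cov,
                            n_components = config$n_components)
  for (sex in present_sexes(cohort)) {
    fit <- fit_fpca(parts[[sex]], settings)
    message("fit [", sex, "]: FVE(2) = ",
            round(100 * fit$model$fve[min(2, length(fit$model$fve))], 1),
            "%, sigma^2 = ", signif(fit$model$noise_var, 3))
    write_fpca_model(fit$model, p$model(sex))
    write_scores(fit$scores, p$scores(sex))
    written <- c(written, p$model(sex), p$scores(sex))
  }
  written
}

# Rebuild an fpca_scores object for a cohort from a serialized model
# (deterministic given the model, so the score stage can rerun in isolation).
rescore <- function(cohort, model) {
  estimate_scores(cohort, model)
}

stage_score <- function(config) {
  p <- config_paths(config)
  cohort <- filter_min_observations(load_stage_cohort(config), config$min_obs)
  written <- character(0)
  parts <- split_by_sex(cohort)
  for (sex in present_sexes(cohort)) {
    model <- read_fpca_model(require_artifact(p$model(sex)))
    ref <- build_reference_system(model,
                                  percentiles = config$percentiles,
                                  n_times = config$n_times,
                                  stratum_percentiles = config$stratum_percentiles,
                                  merged_top = config$merged_top)
    scores <- rescore(parts[[sex]], model)
    falter <- compute_adj_fpc2(scores, ref)
    write_reference_system(ref, p$reference(sex))
    write_faltering(falter, p$faltering(sex))
    summ <- summarize_strata(falter)
    occupancy <- paste(sprintf("S%d:%d", summ$stratum, summ$n), collapse = " ")
    message("score [", sex, "]: stratum occupancy ", occupancy)
    out <- summ
    for (col in c("share", "mean_adj_fpc2", "sd_adj_fpc2")) {
      out[[col]] <- format_full(out[[col]])
    }
    utils::write.csv(out, p$strata(sex), row.names = FALSE, quote = FALSE)
    written <- c(written, p$reference(sex), p$faltering(sex), p$strata(sex))
  }
  written
}

read_faltering <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  attr(df, "fitted") <- NULL
  class(df) <- c("faltering_result", "data.frame")
  df
}

stage_regress <- function(config) {
  p <- config_paths(config)
  cohort <- filter_min_observations(load_stage_cohort(config), config$min_obs)
  written <- character(0)
  for (sex in present_sexes(cohort)) {
    falter <- read_faltering(require_artifact(p$faltering(sex)))
    res <- fit_risk_model(falter, cohort$covariates, sex = sex)
    message("regress [", sex, "]: n = ", res$n_used,
            ", R^2 = ", round(res$r_squared, 3))
    write_regression(res, p$regression(sex))
    written <- c(written, p$regression(sex))
  }
  written
}

stage_report <- function(config) {
  p <- config_paths(config)
  cohort <- filter_min_observations(load_stage_cohort(config), config$min_obs)
  parts <- split_by_sex(cohort)
  written <- character(0)
  for (sex in present_sexes(cohort)) {
    model <- read_fpca_model(require_artifact(p$model(sex)))
    ref <- read_reference_system(require_artifact(p$reference(sex)))
    scores <- rescore(parts[[sex]], model)
    falter <- compute_adj_fpc2(scores, ref)
    diag_tab <- diagnostic_correlations(falter, model)
    out <- diag_tab
    out$corr_s1 <- format_full(out$corr_s1)
    out$corr_adj_fpc2 <- format_full(out$corr_adj_fpc2)
    utils::write.csv(out, p$diagnostics(sex), row.names = FALSE, quote = FALSE)
    written <- c(written, p$diagnostics(sex))
    if (isTRUE(config$figures)) {
      figs <- list(
        trajectories = plot_trajectories(parts[[sex]], model, ref),
        components = plot_components(model),
        score_histograms = plot_score_histograms(falter)
      )
      for (nm in names(figs)) {
        f <- p$fig(paste0(nm, "_", sex))
        ggplot2::ggsave(f, figs[[nm]], width = 7, height = 5, dpi = 120)
        written <- c(written, f)
      }
    }
  }
  written
}
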