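#' Pipeline configuration
#'
#' Single configuration object for the end-to-end run. Defaults follow the
#' study protocol: analysis window 1992-2018, minimum series length 5,
#' imputation R-squared threshold 0.5, sensitivity thresholds
#' 0.3/0.5/0.7/0.9, percentile trim 0.025.
#'
#' @param sim a [sim_config()] for the synthetic-data stage.
#' @param window inclusive analysis year interval.
#' @param min_length minimum series length.
#' @param r2_threshold baseline imputation R-squared threshold.
#' @param r2_thresholds thresholds for the sensitivity scan.
#' @param trim_q percentile-trimming tail probability.
#' @param trait_seed seed for the trait-imputation forests.
#' @param select run backward AICc selection (otherwise the full model is
#'   fitted as-is).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            window = c(1992L, 2018L),
                            min_length = 5L,
                            r2_threshold = 0.5,
                            r2_thresholds = c(0.3, 0.5, 0.7, 0.9),
                            trim_q = 0.025,
                            trait_seed = 42L,
                            select = TRUE) {
  structure(list(sim = sim, window = as.integer(window),
                 min_length = as.integer(min_length),
                 r2_threshold = r2_threshold,
                 r2_thresholds = r2_thresholds,
                 trim_q = trim_q, trait_seed = as.integer(trait_seed),
                 select = isTRUE(select)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors [pipeline_config()] with an optional `sim` section
#' mirroring [sim_config()].
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  if (!is.null(sim_args$beta)) sim_args$beta <- unlist(sim_args$beta)
  y$sim <- do.call(sim_config, sim_args)
  do.call(pipeline_config, y)
}

stage_files <- function(dir, stage) file.path(dir, paste0(stage, ".csv"))

write_stage <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order -- simulate, trends, env,
#' traits, model, sensitivity -- writing each stage's output and a
#' manifest (seeds, row counts, md5 checksums, package version) to the
#' run directory. A failed stage halts the run; the manifest is still
#' written with a FAILED marker for that stage.
#'
#' @param config a [pipeline_config()].
#' @param out_dir run directory, created if needed.
#' @return invisibly, a list with the stage outputs (`study`, `lambdas`,
#'   `env`, `scores`, `model`, `sensitivity`) and the `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package = as.character(utils::packageVersion("fastslowpop")),
    seeds = list(sim = config$sim$seed, traits = config$trait_seed),
    stages = list())
  results <- list()
  record <- function(stage, rows, paths) {
    manifest$stages[[stage]] <<- list(
      status = "complete", rows = rows,
      checksums = as.list(tools::md5sum(paths)))
  }
  fail <- function(stage, err) {
    manifest$stages[[stage]] <<- list(status = "FAILED",
                                      error = conditionMessage(err))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    abort(sprintf("pipeline stage `%s` failed: %s", stage,
                  conditionMessage(err)))
  }

  ## simulate
  tryCatch({
    study <- simulate_study(config$sim)
    paths <- write_sim_study(study, file.path(out_dir, "simulate"))
    results$study <- study
    record("simulate", nrow(study$populations), unname(paths))
  }, error = function(e) fail("simulate", e))

  ## trends
  tryCatch({
    imputed <- impute_populations(replace_zeros(results$study$populations),
                                  window = config$window)
    kept <- filter_populations(imputed, min_length = config$min_length,
                               r2_threshold = config$r2_threshold,
                               window = config$window)
    lambdas <- lambda_table(kept)
    p <- write_stage(lambdas, stage_files(out_dir, "lambdas"))
    results$imputed <- imputed
    results$lambdas <- lambdas
    record("trends", nrow(lambdas), p)
  }, error = function(e) fail("trends", e))

  ## env: cover every population that survives the length filter at any
  ## fit threshold, so sensitivity scenarios keep their covariates
  tryCatch({
    all_kept <- filter_populations(results$imputed,
                                   min_length = config$min_length,
                                   r2_threshold = 0,
                                   window = config$window)
    windows <- lambda_table(all_kept)[c("population_id", "site",
                                        "first_year", "last_year")]
    env <- env_change(windows, results$study$temperature,
                      results$study$landcover)
    p <- write_stage(env, stage_files(out_dir, "env"))
    results$env <- env
    record("env", nrow(env), p)
  }, error = function(e) fail("env", e))

  ## traits
  tryCatch({
    pca <- life_history_scores(results$study$traits,
                               tree = results$study$tree,
                               seed = config$trait_seed)
    p <- write_stage(pca$scores, stage_files(out_dir, "scores"))
    results$scores <- pca
    record("traits", nrow(pca$scores), p)
  }, error = function(e) fail("traits", e))

  ## model
  tryCatch({
    frame <- assemble_model_frame(results$lambdas, results$env,
                                  results$scores$scores)
    model <- if (config$select) stepwise_aicc(frame)
             else list(fit = fit_lmm(frame), spec = build_full_spec(frame),
                       path = NULL)
    p <- write_stage(tidy(model$fit), stage_files(out_dir, "model"))
    pj <- file.path(out_dir, "model.json")
    jsonlite::write_json(list(
      n = model$fit$n,
      terms = model$fit$spec$fixed,
      varcomp = as.list(model$fit$varcomp),
      aicc = model$fit$aicc,
      pseudo_r2 = as.list(model$fit$pseudo_r2),
      aicc_path = model$path), pj, auto_unbox = TRUE, digits = NA,
      dataframe = "columns")
    results$frame <- frame
    results$model <- model
    record("model", nrow(frame), c(p, pj))
  }, error = function(e) fail("model", e))

  ## sensitivity
  tryCatch({
    scan <- r2_threshold_scan(results$imputed, results$env,
                              results$scores$scores,
                              results$model$fit$spec,
                              thresholds = config$r2_thresholds,
                              min_length = config$min_length,
                              window = config$window)
    trims <- trim_scenarios(results$frame, results$model$fit,
                            q = config$trim_q)
    p1 <- write_stage(scan$summary, stage_files(out_dir, "sensitivity_r2"))
    p2 <- write_stage(trims$comparison,
                      stage_files(out_dir, "sensitivity_trim"))
    results$sensitivity <- list(r2 = scan, trim = trims)
    record("sensitivity", nrow(scan$summary), c(p1, p2))
  }, error = function(e) fail("sensitivity", e))

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}
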