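#' Run the full simulate-reduce-analyse pipeline
#'
#' Executes, in order: synthetic-data generation for the requested design
#' and strategy, trial-log reduction, the repeated-measures ANOVA with
#' consecutive contrasts on initial click positions, and the hysteresis
#' mixed model. All stage outputs are written as CSV under `output_dir`
#' together with a JSON run manifest; the run is deterministic given the
#' seed (per-stage child seeds are derived by stage name).
#'
#' @param config a named list with elements `experiment` ("exp1"/"exp2"),
#'   `n_participants`, `seed`, `output_dir`, and optionally `strategy`
#'   (default "heuristic"), `params` (arguments to [strategy_params()]),
#'   `motor` (arguments to [motor_params()]), `analysis` (list with `alpha`
#'   and `grouping`). Unknown keys are rejected before any computation.
#' @return Invisibly, a list with the written file paths and the in-memory
#'   stage results.
#' @export
run_pipeline <- function(config) {
  allowed <- c("experiment", "n_participants", "seed", "output_dir",
               "strategy", "params", "motor", "analysis")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown) > 0) {
    abort_domain("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  required <- c("experiment", "n_participants", "seed", "output_dir")
  miss <- setdiff(required, names(config))
  if (length(miss) > 0) {
    abort_domain("missing config key(s): %s", paste(miss, collapse = ", "))
  }
  strategy <- config$strategy %||% "heuristic"
  params <- do.call(strategy_params, config$params %||% list())
  motor <- do.call(motor_params, config$motor %||% list())
  analysis <- config$analysis %||% list()
  alpha <- analysis$alpha %||% 0.05
  grouping <- analysis$grouping %||%
    if (config$experiment == "exp1") {
      c("target_number", "start_vertical")
    } else {
      c("target_number", "eccentricity_condition")
    }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(config$output_dir, f)
  task_cfg <- task_config(config$experiment)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort_domain("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  # simulate
  design <- stage("design", switch(config$experiment,
    exp1 = generate_exp1_design(config$n_participants,
                                derive_seed(config$seed, "design")),
    exp2 = generate_exp2_design(config$n_participants,
                                derive_seed(config$seed, "design"))
  ))
  ds <- stage("simulate", generate_dataset(
    design, strategy = strategy, params = params, motor = motor,
    seed = derive_seed(config$seed, "simulate")
  ))
  stage("write_logs",
        write_trial_logs(ds$events, path("trial_logs.csv"),
                         manifest = c(ds$manifest, list(master_seed = config$seed))))

  # reduce
  summaries <- stage("reduce", reduce_trials(ds$events, task_cfg))
  stage("write_summaries",
        utils::write.csv(summaries, path("trial_summaries.csv"),
                         row.names = FALSE))
  # the second design's inducer targets differ across block types, so the
  # factorial analysis uses the test trials common to every block type
  aov_input <- if (config$experiment == "exp2") {
    summaries[summaries$condition == "test", , drop = FALSE]
  } else {
    summaries
  }
  cells <- stage("summarize", summarize_conditions(aov_input, grouping))
  stage("write_cells",
        utils::write.csv(cells, path("condition_means.csv"), row.names = FALSE))

  # anova + contrasts on initial click position
  aov_tab <- stage("anova", rm_anova_gg(cells, dv = "initial_click_y",
                                        within = grouping))
  aov_tab$significant <- aov_tab$p < alpha
  stage("write_anova",
        utils::write.csv(aov_tab, path("anova_initial_click.csv"),
                         row.names = FALSE))
  contr <- stage("contrasts", consecutive_contrasts(
    cells, dv = "initial_click_y", factor_name = grouping[1]
  ))
  stage("write_contrasts",
        utils::write.csv(contr, path("contrasts_initial_click.csv"),
                         row.names = FALSE))

  # hysteresis mixed model
  ptab <- stage("lmm_predictors",
                build_hysteresis_predictors(summaries, task_cfg))
  lmm <- stage("lmm", fit_mixed_model(ptab))
  lmm_tab <- lmm$fixed
  lmm_tab$r2_marginal <- lmm$r2_marginal
  lmm_tab$r2_conditional <- lmm$r2_conditional
  stage("write_lmm",
        utils::write.csv(lmm_tab, path("lmm_fixed_effects.csv"),
                         row.names = FALSE))

  manifest <- list(
    config = config[setdiff(names(config), "output_dir")],
    strategy = strategy, params = unclass(params), motor = unclass(motor),
    alpha = alpha, grouping = grouping,
    r_version = as.character(getRversion())
  )
  jsonlite::write_json(manifest, path("run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(
    paths = list(
      trial_logs = path("trial_logs.csv"),
      trial_summaries = path("trial_summaries.csv"),
      condition_means = path("condition_means.csv"),
      anova = path("anova_initial_click.csv"),
      contrasts = path("contrasts_initial_click.csv"),
      lmm = path("lmm_fixed_effects.csv"),
      manifest = path("run_manifest.json")
    ),
    summaries = summaries, cells = cells, anova = aov_tab,
    contrasts = contr, lmm = lmm
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
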