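# End-to-end pipeline: score -> norms -> calibrate -> match -> compare,
# with delimited-text inputs/outputs, an exclusion log and a run manifest.

#' Assemble a pipeline run configuration
#'
#' @param survey Path to the survey CSV, or a survey data frame.
#' @param out_dir Output directory (created if absent).
#' @param norm_table Path to a norm-table CSV, or a `"norm_table"` object.
#' @param norm_pool Path to a normative-pool CSV, or a pool data frame; used
#'   to build the table when `norm_table` is not given.
#' @param weights Path to a weights JSON, or a named list of
#'   [behavior_weights()]; when absent, weights are calibrated from the
#'   treatment pretests.
#' @param battery Path to a battery JSON, or an [item_battery()]; default
#'   the 13-item battery.
#' @param behaviors Behaviors to calibrate/compare.
#' @param min_positive Calibration prevalence guard (default 20).
#' @param weighting School aggregation rule (`"student"` or `"class_mean"`).
#' @param alpha Significance level for subgroup tests.
#' @param grid Percentile grid used when building norms.
#' @param age_range Age coverage used when building norms.
#' @param min_records Minimum records per age-month when building norms.
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return A `"run_config"` list.
#' @export
run_config <- function(survey, out_dir, norm_table = NULL, norm_pool = NULL,
                       weights = NULL, battery = NULL,
                       behaviors = c("alcohol", "drunkenness", "cigarette",
                                     "vaping"),
                       min_positive = 20, weighting = "student",
                       alpha = 0.05, grid = default_percentile_grid(),
                       age_range = c(120L, 240L), min_records = 20,
                       seed = NULL) {
  structure(list(survey = survey, out_dir = out_dir, norm_table = norm_table,
                 norm_pool = norm_pool, weights = weights, battery = battery,
                 behaviors = behaviors, min_positive = min_positive,
                 weighting = weighting, alpha = alpha, grid = grid,
                 age_range = age_range, min_records = min_records,
                 seed = seed),
            class = "run_config")
}

#' Read a pipeline configuration from JSON
#'
#' Path-valued fields are resolved relative to the JSON file's directory.
#'
#' @param path JSON config path.
#' @return A `"run_config"`.
#' @export
read_run_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p) || !is.character(p)) return(p)
    if (file.exists(p)) p else file.path(base, p)
  }
  run_config(survey = resolve(j$survey),
             out_dir = resolve(j$out_dir) %||% file.path(base, "out"),
             norm_table = resolve(j$norm_table),
             norm_pool = resolve(j$norm_pool),
             weights = resolve(j$weights),
             battery = resolve(j$battery),
             behaviors = j$behaviors %||% c("alcohol", "drunkenness",
                                            "cigarette", "vaping"),
             min_positive = j$min_positive %||% 20,
             weighting = j$weighting %||% "student",
             alpha = j$alpha %||% 0.05,
             seed = j$seed)
}

.load_or <- function(x, loader) {
  if (is.null(x)) return(NULL)
  if (is.character(x)) loader(x) else x
}

#' Run the virtual-controls pipeline end to end
#'
#' Stages: score the survey items into psych scores; obtain the normative
#' table (load, or build from a normative pool); calibrate behavior weights
#' from the treatment pretests (or load published weights); match every
#' eligible treatment case to its pegged virtual control; compare conditions
#' at the student, classroom and school level and across demographic
#' subgroups; emit the dichotomized increase table for external multi-level
#' modelling. All result tables, the exclusion log, fitted weights and a
#' manifest (input checksums, config hash, seed, package version) are
#' written to `config$out_dir`. Identical config + inputs give identical
#' outputs.
#'
#' @param config A [run_config()] (or path to a JSON config).
#' @return Invisibly, a list with the scored surveys, norm table,
#'   calibration reports, matched cohort, comparison tables and output
#'   paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- Filter(is.character, config[c("survey", "norm_table",
                                          "norm_pool", "weights", "battery")])

  # -- stage: score ---------------------------------------------------------
  surveys <- tryCatch({
    s <- .load_or(config$survey, read_surveys)
    if (is.null(s)) stop("no survey input")
    battery <- .load_or(config$battery, read_battery) %||% default_battery()
    score_surveys(s, battery)
  }, error = function(e) stop_stage("score", conditionMessage(e)))

  # -- stage: norms ---------------------------------------------------------
  table <- tryCatch({
    tab <- .load_or(config$norm_table, read_norm_table)
    if (is.null(tab)) {
      pool <- .load_or(config$norm_pool, read_surveys)
      if (is.null(pool))
        stop("neither a norm table nor a normative pool was supplied")
      tab <- build_norm_table(pool, grid = config$grid,
                              min_records = config$min_records,
                              age_range = config$age_range)
    }
    tab
  }, error = function(e) stop_stage("norms", conditionMessage(e)))

  # -- stage: calibrate -----------------------------------------------------
  calib <- tryCatch({
    loaded <- .load_or(config$weights, read_behavior_weights)
    if (!is.null(loaded)) {
      list(weights = loaded, reports = NULL)
    } else {
      pre <- surveys[surveys$wave == "pretest", , drop = FALSE]
      reports <- lapply(config$behaviors, function(b) {
        fit_behavior_weights(pre, b, min_positive = config$min_positive)
      })
      names(reports) <- config$behaviors
      w <- lapply(reports, `[[`, "weights")
      list(weights = Filter(Negate(is.null), w), reports = reports)
    }
  }, error = function(e) stop_stage("calibrate", conditionMessage(e)))
  if (!length(calib$weights))
    stop_stage("calibrate", "no behavior could be calibrated")

  # -- stage: match ---------------------------------------------------------
  matched <- tryCatch(
    match_cohort(table, calib$weights, surveys),
    error = function(e) stop_stage("match", conditionMessage(e)))

  # -- stage: compare -------------------------------------------------------
  results <- tryCatch({
    cells <- outcome_cells(surveys, matched$virtual)
    levels_tab <- compare_all(cells, weighting = config$weighting)
    sub_tab <- subgroup_table(surveys, matched$virtual, alpha = config$alpha)
    dich <- rbind(dichotomize_increase(cells, "posttest"),
                  dichotomize_increase(cells, "followup"))
    list(cells = cells, levels = levels_tab, subgroups = sub_tab,
         dichotomized = dich)
  }, error = function(e) stop_stage("compare", conditionMessage(e)))

  # -- stage: write ---------------------------------------------------------
  paths <- tryCatch({
    p <- list(
      levels = file.path(out_dir, "results_levels.csv"),
      subgroups = file.path(out_dir, "results_subgroups.csv"),
      dichotomized = file.path(out_dir, "dichotomized_increase.csv"),
      virtual = file.path(out_dir, "virtual_cases.csv"),
      exclusions = file.path(out_dir, "exclusions.log"),
      weights = file.path(out_dir, "weights.json"),
      manifest = file.path(out_dir, "manifest.json")
    )
    fmt <- results$levels
    fmt$pct_treatment <- round(fmt$pct_treatment, 2)
    fmt$pct_control <- round(fmt$pct_control, 2)
    utils::write.csv(fmt, p$levels, row.names = FALSE)
    fms <- results$subgroups
    fms$pct_treatment <- round(fms$pct_treatment, 2)
    fms$pct_control <- round(fms$pct_control, 2)
    utils::write.csv(fms, p$subgroups, row.names = FALSE)
    utils::write.csv(results$dichotomized, p$dichotomized, row.names = FALSE)
    write_virtual_cases(matched, p$virtual, p$exclusions)
    write_behavior_weights(calib$reports %||% calib$weights, p$weights)
    manifest <- list(
      package = "virtualcontrols",
      version = as.character(utils::packageVersion("virtualcontrols")),
      seed = config$seed,
      config_hash = unname(.hash_obj(config)),
      input_checksums = as.list(vapply(inputs, function(f)
        unname(tools::md5sum(f)), character(1))),
      n_treatment_cases = length(unique(matched$virtual$student_id)),
      n_exclusions = nrow(matched$exclusions),
      calibrated_behaviors = names(calib$weights)
    )
    jsonlite::write_json(manifest, p$manifest, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    p
  }, error = function(e) stop_stage("write", conditionMessage(e)))

  invisible(list(surveys = surveys, table = table, calibration = calib,
                 matched = matched, results = results, paths = paths))
}

.hash_obj <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  # drop non-serializable in-memory inputs from the hash; paths and scalar
  # options identify a rerun
  keep <- Filter(function(v) is.character(v) || is.numeric(v) || is.null(v),
                 unclass(x))
  keep$out_dir <- NULL  # where results land does not change what they are
  writeLines(jsonlite::toJSON(keep, auto_unbox = TRUE, null = "null"), f)
  unname(tools::md5sum(f))
}
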