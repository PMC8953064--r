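#' Build a pipeline run configuration
#'
#' Collects everything one scale-development run needs: the input tables (or
#' paths to their CSVs), stage toggles, rule overrides, output directory and
#' seed. A JSON or YAML file with the same field names can be loaded with
#' [read_run_config()]; in-memory objects take precedence over paths.
#'
#' @param responses A [response_matrix()] or path to a response CSV.
#' @param covariates Optional covariate data frame or CSV path (columns
#'   `person_id`, demographics, behavior columns, convergent score).
#' @param item_specs Optional [test_spec()] or item-spec CSV path (needed
#'   when `responses` is a path with partial-credit items).
#' @param stages Named logical vector toggling `calibrate`, `purify`,
#'   `person_round`, `dif`, `strata`, `validity`.
#' @param rules A [purification_rules()].
#' @param settings An [estimation_settings()].
#' @param dif_groupings Groupings passed to [dif_screen()].
#' @param behavior_cols Covariate columns holding binary criterion
#'   behaviors (default: all columns starting with `beh_`).
#' @param convergent_col Covariate column with the convergent screener
#'   summed score.
#' @param demographic_cols Covariate columns entered as controls in the
#'   criterion regressions.
#' @param output_dir Directory for the report bundle.
#' @param seed Integer seed recorded in the manifest (estimation itself is
#'   deterministic).
#' @return List of class `run_config`.
#' @export
run_config <- function(responses, covariates = NULL, item_specs = NULL,
                       stages = c(calibrate = TRUE, purify = TRUE,
                                  person_round = TRUE, dif = TRUE,
                                  strata = TRUE, validity = TRUE),
                       rules = purification_rules(),
                       settings = estimation_settings(),
                       dif_groupings = c("gender", "age_band", "ethnicity"),
                       behavior_cols = NULL,
                       convergent_col = "nvs_score",
                       demographic_cols = c("gender", "age", "ethnicity"),
                       output_dir = tempfile("raschval_run_"),
                       seed = 1L) {
  defaults <- c(calibrate = TRUE, purify = TRUE, person_round = TRUE,
                dif = TRUE, strata = TRUE, validity = TRUE)
  defaults[names(stages)] <- stages
  structure(list(responses = responses, covariates = covariates,
                 item_specs = item_specs, stages = defaults, rules = rules,
                 settings = settings, dif_groupings = dif_groupings,
                 behavior_cols = behavior_cols,
                 convergent_col = convergent_col,
                 demographic_cols = demographic_cols,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from JSON or YAML
#'
#' @param path Config file; the extension picks the parser.
#' @return A [run_config()] (input paths are left as paths; they are read
#'   when the pipeline runs).
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML configs", call. = FALSE)
    yaml::read_yaml(path)
  } else jsonlite::fromJSON(path, simplifyVector = TRUE)
  for (p in c("responses", "covariates", "item_specs"))
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]]))
      stop("config path does not exist: ", cfg[[p]], call. = FALSE)
  args <- list(responses = cfg$responses, covariates = cfg$covariates,
               item_specs = cfg$item_specs)
  if (!is.null(cfg$stages)) args$stages <- unlist(cfg$stages)
  if (!is.null(cfg$rules)) args$rules <- do.call(purification_rules, cfg$rules)
  if (!is.null(cfg$settings))
    args$settings <- do.call(estimation_settings, cfg$settings)
  for (p in c("dif_groupings", "behavior_cols", "convergent_col",
              "demographic_cols", "output_dir", "seed"))
    if (!is.null(cfg[[p]])) args[[p]] <- cfg[[p]]
  do.call(run_config, args)
}

#' Run the full scale-development pipeline
#'
#' Stage order mirrors a Rasch validation study: calibrate, check fit and
#' assumptions, purify items, run the one-round person-misfit procedure,
#' test invariance (DIF), derive strata-based reliability and cutoffs, and
#' run the validity battery. Writes a deterministic report bundle
#' (calibration JSON, item table CSV, purification trace, DIF CSVs, strata
#' report, validity CSV, and a manifest with version, seed and rules) into
#' `config$output_dir`. A stage failure aborts with the stage name after
#' writing the partial bundle manifest.
#'
#' @param config A [run_config()].
#' @param verbose Log stage progress via `message()`.
#' @return List of class `run_bundle` with every stage result, invisibly.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list(stages_run = character(0))
  manifest <- list(package = "raschval",
                   version = as.character(utils::packageVersion("raschval")),
                   seed = config$seed,
                   rules = unclass(config$rules),
                   settings = unclass(config$settings),
                   stages = as.list(config$stages),
                   status = "running")
  write_manifest <- function() jsonlite::write_json(
    manifest, file.path(config$output_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stage <- function(name, expr) {
    if (verbose) message("stage: ", name)
    tryCatch(expr, error = function(e) {
      manifest$status <<- paste0("failed at stage '", name, "': ",
                                 conditionMessage(e))
      write_manifest()
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  specs <- config$item_specs
  if (is.character(specs)) specs <- read_item_specs(specs)
  responses <- config$responses
  if (is.character(responses)) responses <- read_responses(responses, specs)
  covariates <- config$covariates
  if (is.character(covariates))
    covariates <- utils::read.csv(covariates, stringsAsFactors = FALSE)

  dat <- responses
  if (isTRUE(config$stages[["purify"]])) {
    out$purification <- stage("purify", purify_items(dat, config$rules,
                                                     config$settings))
    dat <- out$purification$final_responses
    write_trace_json(out$purification,
                     file.path(config$output_dir, "purification_trace.json"))
    out$stages_run <- c(out$stages_run, "purify")
  }
  if (isTRUE(config$stages[["person_round"]])) {
    out$person_round <- stage("person_round",
                              person_misfit_round(dat, config$rules,
                                                  config$settings))
    dat <- out$person_round$responses
    out$stages_run <- c(out$stages_run, "person_round")
  }

  out$calibration <- stage("calibrate", estimate_jmle(dat, config$settings))
  out$fit <- stage("calibrate", item_fit(out$calibration, dat))
  out$assumptions <- stage("calibrate", assumption_checks(out$calibration, dat))
  out$responses_final <- dat
  write_calibration_json(out$calibration,
                         file.path(config$output_dir, "calibration.json"))
  emit_item_table(out$calibration, out$fit,
                  path = file.path(config$output_dir, "item_table.csv"))
  out$stages_run <- c(out$stages_run, "calibrate")

  if (isTRUE(config$stages[["dif"]]) && !is.null(covariates)) {
    out$dif <- stage("dif", dif_screen(dat, covariates,
                                       groupings = config$dif_groupings))
    for (g in names(out$dif))
      utils::write.csv(out$dif[[g]],
                       file.path(config$output_dir, paste0("dif_", g, ".csv")),
                       row.names = FALSE)
    out$stages_run <- c(out$stages_run, "dif")
  }

  if (isTRUE(config$stages[["strata"]])) {
    out$score_table <- stage("strata", score_to_measure_table(out$calibration))
    out$strata <- stage("strata", wright_strata(out$score_table))
    out$reliability <- stage("strata", list(
      item_separation = item_separation_reliability(out$calibration),
      person_separation = person_separation_reliability(out$calibration),
      kr20 = kr20(dat),
      sample_independent = out$strata$sample_independent_reliability))
    write_strata(out$strata, file.path(config$output_dir, "strata.json"))
    write_strata(out$strata, file.path(config$output_dir, "score_table.csv"))
    out$stages_run <- c(out$stages_run, "strata")
  }

  if (isTRUE(config$stages[["validity"]]) && !is.null(covariates)) {
    out$validity <- stage("validity", validity_battery(
      dat, covariates, behavior_cols = config$behavior_cols,
      convergent_col = config$convergent_col,
      demographic_cols = config$demographic_cols))
    utils::write.csv(out$validity$summary,
                     file.path(config$output_dir, "validity.csv"),
                     row.names = FALSE)
    out$stages_run <- c(out$stages_run, "validity")
  }

  manifest$status <- "ok"
  manifest$stages_run <- out$stages_run
  write_manifest()
  out$output_dir <- config$output_dir
  class(out) <- "run_bundle"
  invisible(out)
}

#' @export
print.run_bundle <- function(x, ...) {
  cat("<run_bundle> stages:", paste(x$stages_run, collapse = ", "), "\n")
  cat("  bundle at:", x$output_dir, "\n")
  invisible(x)
}

#' Convergent and criterion validity battery
#'
#' Correlates the test's raw scores with the convergent screener and fits
#' one criterion logistic regression per behavior column (controlling for
#' the demographic columns), reporting odds ratios, Wald intervals, ROC
#' areas and Cohen's d.
#'
#' @param responses A [response_matrix()] (purified/final).
#' @param covariates Covariate data frame aligned by `person_id`.
#' @param behavior_cols Binary outcome columns; default: those starting
#'   `beh_`.
#' @param convergent_col Column with the screener summed score (skipped if
#'   absent).
#' @param demographic_cols Control covariates present in `covariates`.
#' @return List with `convergent` (r, p, n), `criterion` (list of
#'   [criterion_logistic()] results) and a flat `summary` data frame.
#' @export
validity_battery <- function(responses, covariates, behavior_cols = NULL,
                             convergent_col = "nvs_score",
                             demographic_cols = c("gender", "age", "ethnicity")) {
  cov <- covariates[match(responses$person_ids, covariates$person_id), ,
                    drop = FALSE]
  raw <- raw_totals(responses)
  if (is.null(behavior_cols))
    behavior_cols <- grep("^beh_", names(cov), value = TRUE)
  demographic_cols <- intersect(demographic_cols, names(cov))
  conv <- NULL
  if (!is.null(convergent_col) && convergent_col %in% names(cov))
    conv <- convergent_correlation(raw, cov[[convergent_col]])
  crit <- lapply(behavior_cols, function(bc) {
    covs <- if (length(demographic_cols))
      cov[, demographic_cols, drop = FALSE] else NULL
    criterion_logistic(cov[[bc]], raw, covariates = covs, outcome_name = bc)
  })
  names(crit) <- behavior_cols
  summary <- data.frame(
    measure = c(if (!is.null(conv)) "convergent_r", behavior_cols),
    estimate = c(if (!is.null(conv)) conv$r,
                 vapply(crit, `[[`, numeric(1), "odds_ratio")),
    ci_low = c(if (!is.null(conv)) NA_real_,
               vapply(crit, `[[`, numeric(1), "ci_low")),
    ci_high = c(if (!is.null(conv)) NA_real_,
                vapply(crit, `[[`, numeric(1), "ci_high")),
    auc = c(if (!is.null(conv)) NA_real_,
            vapply(crit, `[[`, numeric(1), "auc")),
    cohens_d = c(if (!is.null(conv)) NA_real_,
                 vapply(crit, `[[`, numeric(1), "cohens_d")),
    p_value = c(if (!is.null(conv)) conv$p_value,
                rep(NA_real_, length(crit))))
  list(convergent = conv, criterion = crit, summary = summary)
}
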