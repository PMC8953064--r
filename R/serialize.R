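#' Serialize a calibration to JSON
#'
#' Writes difficulties, thresholds, person measures, standard errors and the
#' convergence block in a stable JSON layout; `read_calibration_json()`
#' restores a `rasch_calibration` that reproduces every downstream number.
#'
#' @param calibration A `rasch_calibration`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_calibration_json <- function(calibration, path) {
  x <- calibration
  mm <- max_scores(x$specs)
  payload <- list(
    items = list(
      item_id = names(x$item_difficulty),
      family = vapply(x$specs, `[[`, character(1), "family"),
      max_score = unname(mm),
      difficulty = unname(x$item_difficulty),
      se = unname(x$item_se),
      thresholds = lapply(x$thresholds, function(t) if (is.null(t)) numeric(0) else t),
      threshold_se = lapply(x$threshold_se, function(t) if (is.null(t)) numeric(0) else t)
    ),
    persons = list(
      person_id = names(x$person_measure),
      measure = unname(x$person_measure),
      se = unname(x$person_se)
    ),
    excluded = list(persons = x$excluded_persons, items = x$excluded_items),
    convergence = list(converged = x$converged,
                       n_iterations = x$n_iterations,
                       max_residual_change = x$max_residual_change),
    settings = unclass(x$settings)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  it <- p$items
  specs <- test_spec(lapply(seq_along(it$item_id), function(j)
    item_spec(it$item_id[j], it$family[j], it$max_score[j])))
  thr <- lapply(it$thresholds, function(t) if (length(t)) t else NULL)
  thr_se <- lapply(it$threshold_se, function(t) if (length(t)) t else NULL)
  st <- p$settings
  structure(list(
    item_difficulty = stats::setNames(it$difficulty, it$item_id),
    item_se = stats::setNames(it$se, it$item_id),
    thresholds = stats::setNames(thr, it$item_id),
    threshold_se = stats::setNames(thr_se, it$item_id),
    person_measure = stats::setNames(p$persons$measure, p$persons$person_id),
    person_se = stats::setNames(p$persons$se, p$persons$person_id),
    excluded_persons = as.character(unlist(p$excluded$persons)),
    excluded_items = as.character(unlist(p$excluded$items)),
    converged = p$convergence$converged,
    n_iterations = p$convergence$n_iterations,
    max_residual_change = p$convergence$max_residual_change,
    specs = specs,
    settings = estimation_settings(st$convergence_tol, st$max_iterations,
                                   st$extreme_score_adjustment, st$damping,
                                   st$bias_correction)
  ), class = "rasch_calibration")
}

#' Item table in the published layout
#'
#' One row per retained item with the columns of a published Rasch item
#' table: Difficulty, SE, Outfit MNSQ, Outfit ZSTD, PMC. When a composite
#' calibration and fit are supplied, their columns appear alongside with a
#' `composite_` prefix (items absent from either calibration carry `NA`).
#'
#' @param calibration A `rasch_calibration`.
#' @param fit Its [item_fit()] report.
#' @param composite_calibration,composite_fit Optional second calibration
#'   (e.g. all sub-assessments in one model).
#' @param path Optional CSV output path.
#' @return Data frame (invisibly written to `path` if given).
#' @export
emit_item_table <- function(calibration, fit, composite_calibration = NULL,
                            composite_fit = NULL, path = NULL) {
  tab <- data.frame(item_id = names(calibration$item_difficulty),
                    difficulty = unname(calibration$item_difficulty),
                    se = unname(calibration$item_se))
  tab <- merge(tab, fit[, c("item_id", "outfit_mnsq", "outfit_zstd", "pmc")],
               by = "item_id", sort = FALSE)
  if (!is.null(composite_calibration)) {
    ct <- data.frame(item_id = names(composite_calibration$item_difficulty),
                     composite_difficulty = unname(composite_calibration$item_difficulty),
                     composite_se = unname(composite_calibration$item_se))
    ct <- merge(ct, stats::setNames(
      composite_fit[, c("item_id", "outfit_mnsq", "outfit_zstd", "pmc")],
      c("item_id", "composite_outfit_mnsq", "composite_outfit_zstd",
        "composite_pmc")), by = "item_id", sort = FALSE)
    tab <- merge(tab, ct, by = "item_id", all = TRUE, sort = FALSE)
  }
  if (!is.null(path)) utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}

#' Serialize a purification trace to JSON
#'
#' @param trace A `purification_trace`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trace_json <- function(trace, path) {
  rounds <- lapply(trace$rounds, function(r) list(
    n_items = r$n_items,
    removed_item = if (is.null(r$removed_item)) NULL else r$removed_item,
    trigger = if (is.null(r$trigger)) NULL else r$trigger,
    candidates = r$candidates,
    fit = r$fit,
    assumption_checks = unclass(r$assumption_checks)))
  jsonlite::write_json(list(rounds = rounds, removed = trace$removed),
                       path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Serialize a strata report
#'
#' @param report A `strata_report`.
#' @param path Output file (`.json` or `.csv` decides the format; CSV gets
#'   the score table only).
#' @return `path`, invisibly.
#' @export
write_strata <- function(report, path) {
  if (grepl("\\.csv$", path)) {
    utils::write.csv(report$score_table, path, row.names = FALSE)
  } else {
    jsonlite::write_json(list(
      score_table = report$score_table,
      n_levels = report$n_levels,
      level_cutoffs = report$level_cutoffs,
      sample_independent_reliability = report$sample_independent_reliability,
      se_inflation_factor = report$se_inflation_factor
    ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}
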