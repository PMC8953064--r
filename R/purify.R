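#' Item purification rules
#'
#' The removal policy: items whose outfit mean-square exceeds 1.5 *and*
#' whose standardized outfit exceeds 2 are removal candidates, worst first;
#' items with negative point-measure correlations are always removed
#' (negative polarity). Mean-squares in \[0.5, 1.5\] indicate good fit; low
#' mean-squares (< 0.5) are noted as overfitting but never trigger removal.
#'
#' @param outfit_mnsq_removal_floor Outfit mean-square gate (default 1.5).
#' @param zstd_removal_floor Standardized outfit gate (default 2.0).
#' @param low_mnsq_note_floor Overfit note floor (default 0.5).
#' @param drop_negative_pmc Remove negatively polarized items (default TRUE).
#' @param person_outfit_floor Person outfit above which a person counts as
#'   misfitting in the one-round person procedure (default 2.0).
#' @param keep_items Character vector of item ids never removed regardless
#'   of fit (the theory-based override hook).
#' @return A list of class `purification_rules`.
#' @export
purification_rules <- function(outfit_mnsq_removal_floor = 1.5,
                               zstd_removal_floor = 2.0,
                               low_mnsq_note_floor = 0.5,
                               drop_negative_pmc = TRUE,
                               person_outfit_floor = 2.0,
                               keep_items = character(0)) {
  stopifnot(outfit_mnsq_removal_floor > 0, zstd_removal_floor > 0,
            low_mnsq_note_floor > 0, person_outfit_floor > 0)
  structure(list(outfit_mnsq_removal_floor = outfit_mnsq_removal_floor,
                 zstd_removal_floor = zstd_removal_floor,
                 low_mnsq_note_floor = low_mnsq_note_floor,
                 drop_negative_pmc = drop_negative_pmc,
                 person_outfit_floor = person_outfit_floor,
                 keep_items = keep_items),
            class = "purification_rules")
}

#' Rank items for removal
#'
#' Applies the purification rules to an item fit report. Outfit-gated items
#' (outfit mean-square above the floor *and* standardized outfit above its
#' floor) come first, ordered by descending outfit mean-square with ties
#' broken by larger |zstd| then lexical item id. Items with negative
#' point-measure correlations are appended regardless of fit (classified by
#' trigger `negative_pmc`, which takes precedence for items breaching both
#' rules). Items on the keep-list are never listed.
#'
#' @param fit An item [item_fit()] report.
#' @param rules A [purification_rules()].
#' @return Data frame with `item_id`, `trigger` (`"outfit"` or
#'   `"negative_pmc"`), `outfit_mnsq`, `outfit_zstd`, `pmc`, in removal
#'   order; zero rows when nothing is flagged.
#' @export
flag_removal_candidates <- function(fit, rules = purification_rules()) {
  stopifnot(inherits(fit, "fit_report"))
  neg <- rules$drop_negative_pmc & !is.na(fit$pmc) & fit$pmc < 0
  out_gate <- !neg &
    fit$outfit_mnsq > rules$outfit_mnsq_removal_floor &
    fit$outfit_zstd > rules$zstd_removal_floor
  ord <- order(-fit$outfit_mnsq, -abs(fit$outfit_zstd), fit$item_id)
  rows <- c(ord[out_gate[ord]], ord[neg[ord]])
  cand <- data.frame(item_id = fit$item_id[rows],
                     trigger = rep(c("outfit", "negative_pmc"),
                                   c(sum(out_gate), sum(neg))),
                     outfit_mnsq = fit$outfit_mnsq[rows],
                     outfit_zstd = fit$outfit_zstd[rows],
                     pmc = fit$pmc[rows], row.names = NULL)
  cand[!cand$item_id %in% rules$keep_items, , drop = FALSE]
}

#' Iterative item purification
#'
#' The scale-purification loop: calibrate, compute fit and assumption
#' checks, remove the single worst removal candidate, recalibrate, and
#' repeat until no item is flagged. One item is removed per round (the
#' conservative reading of iterative removal), and unidimensionality, local
#' independence and monotonicity are re-examined every round. The loop
#' refuses to purify below `min_items` retained items.
#'
#' @param responses A [response_matrix()].
#' @param rules A [purification_rules()].
#' @param settings An [estimation_settings()].
#' @param min_items Hard floor on retained items (default 3).
#' @param verbose Emit a round-by-round log via `message()`.
#' @return An object of class `purification_trace`: list with `rounds` (each
#'   recording the fit snapshot, assumption checks, flagged candidates, and
#'   the removed item id + trigger, `NULL` in the final round), `removed`
#'   (data frame of item_id/trigger in removal order), `final_calibration`,
#'   and `final_responses`.
#' @export
purify_items <- function(responses, rules = purification_rules(),
                         settings = estimation_settings(), min_items = 3L,
                         verbose = FALSE) {
  stopifnot(inherits(responses, "response_matrix"))
  cur <- responses
  rounds <- list()
  removed <- data.frame(item_id = character(0), trigger = character(0),
                        outfit_mnsq = numeric(0), pmc = numeric(0))
  repeat {
    cal <- estimate_jmle(cur, settings)
    fit <- item_fit(cal, cur)
    checks <- assumption_checks(cal, cur)
    cand <- flag_removal_candidates(fit, rules)
    round_rec <- list(n_items = ncol(cur$scores), fit = fit,
                      assumption_checks = checks, candidates = cand,
                      removed_item = NULL, trigger = NULL)
    if (nrow(cand) == 0L) {
      rounds[[length(rounds) + 1L]] <- round_rec
      if (verbose) message("round ", length(rounds), ": no candidates; stop")
      break
    }
    if (ncol(cur$scores) - 1L < min_items)
      stop("purification would leave fewer than ", min_items, " items",
           call. = FALSE)
    drop_id <- cand$item_id[1L]
    round_rec$removed_item <- drop_id
    round_rec$trigger <- cand$trigger[1L]
    rounds[[length(rounds) + 1L]] <- round_rec
    removed <- rbind(removed, data.frame(
      item_id = drop_id, trigger = cand$trigger[1L],
      outfit_mnsq = cand$outfit_mnsq[1L], pmc = cand$pmc[1L]))
    if (verbose)
      message("round ", length(rounds), ": removed ", drop_id,
              " (", cand$trigger[1L], ", outfit ",
              sprintf("%.2f", cand$outfit_mnsq[1L]), ")")
    keep <- setdiff(colnames(cur$scores), drop_id)
    cur <- subset_responses(cur, items = keep)
  }
  structure(list(rounds = rounds, removed = removed,
                 final_calibration = estimate_jmle(cur, settings),
                 final_responses = cur, rules = rules),
            class = "purification_trace")
}

#' @export
print.purification_trace <- function(x, ...) {
  cat(sprintf("<purification_trace> %d round(s), %d item(s) removed\n",
              length(x$rounds), nrow(x$removed)))
  if (nrow(x$removed))
    cat(paste0("  - ", x$removed$item_id, " (", x$removed$trigger, ")\n"),
        sep = "")
  invisible(x)
}

#' One-round person misfit procedure
#'
#' Removes (once) all persons whose outfit mean-square exceeds the person
#' floor, recalibrates, and keeps the reduced dataset only if item fit
#' strictly improves: fewer items outside the \[0.5, 1.5\] outfit band, with
#' mean |item outfit zstd| breaking ties. Otherwise (or when removal would
#' leave fewer than `min_persons` persons) the original data are retained.
#'
#' @param responses A [response_matrix()] (typically the purified item set).
#' @param rules A [purification_rules()].
#' @param settings An [estimation_settings()].
#' @param min_persons Smallest acceptable sample after removal (default 30).
#' @return List of class `person_misfit_decision`: `verdict` (one of
#'   `"no_candidates"`, `"improved"`, `"not_improved"`, `"too_few_persons"`),
#'   `removed_persons`, `fit_before`, `fit_after` (`NULL` when no removal was
#'   evaluated), and `responses` (the dataset to carry forward).
#' @export
person_misfit_round <- function(responses, rules = purification_rules(),
                                settings = estimation_settings(),
                                min_persons = 30L) {
  cal <- estimate_jmle(responses, settings)
  pfit <- person_fit(cal, responses)
  fit_before <- item_fit(cal, responses)
  bad <- pfit$person_id[pfit$outfit_mnsq > rules$person_outfit_floor]
  if (length(bad) == 0L)
    return(structure(list(verdict = "no_candidates",
                          removed_persons = character(0),
                          fit_before = fit_before, fit_after = NULL,
                          responses = responses),
                     class = "person_misfit_decision"))
  keep <- setdiff(responses$person_ids, bad)
  if (length(keep) < min_persons) {
    warning("removing misfitting persons would leave fewer than ",
            min_persons, " persons; original dataset retained")
    return(structure(list(verdict = "too_few_persons",
                          removed_persons = character(0),
                          fit_before = fit_before, fit_after = NULL,
                          responses = responses),
                     class = "person_misfit_decision"))
  }
  reduced <- subset_responses(responses, persons = keep)
  cal2 <- estimate_jmle(reduced, settings)
  fit_after <- item_fit(cal2, reduced)
  band <- function(f) sum(f$outfit_mnsq < rules$low_mnsq_note_floor |
                            f$outfit_mnsq > rules$outfit_mnsq_removal_floor)
  improved <- band(fit_after) < band(fit_before) ||
    (band(fit_after) == band(fit_before) &&
       mean(abs(fit_after$outfit_zstd)) < mean(abs(fit_before$outfit_zstd)))
  structure(list(verdict = if (improved) "improved" else "not_improved",
                 removed_persons = if (improved) bad else character(0),
                 fit_before = fit_before, fit_after = fit_after,
                 responses = if (improved) reduced else responses),
            class = "person_misfit_decision")
}

#' @export
print.person_misfit_decision <- function(x, ...) {
  cat(sprintf("<person_misfit_decision> verdict: %s (%d person(s) removed)\n",
              x$verdict, length(x$removed_persons)))
  invisible(x)
}
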