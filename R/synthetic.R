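#' Item bank with known true parameters
#'
#' @param specs A [test_spec()].
#' @param difficulty Numeric vector of true difficulties, one per item
#'   (logits).
#' @param thresholds Optional named list of centered step thresholds for
#'   partial-credit items (`NULL` entries for dichotomous items).
#' @param scale Optional character vector tagging each item with the
#'   sub-assessment it belongs to.
#' @return List of class `item_bank`.
#' @export
item_bank <- function(specs, difficulty, thresholds = NULL, scale = NULL) {
  if (!inherits(specs, "test_spec")) specs <- test_spec(specs)
  ids <- item_ids(specs)
  stopifnot(length(difficulty) == length(specs))
  mm <- max_scores(specs)
  if (is.null(thresholds))
    thresholds <- lapply(mm, function(m) if (m > 1L) rep(0, m) else NULL)
  stopifnot(length(thresholds) == length(specs))
  for (j in seq_along(specs)) {
    if (mm[j] > 1L) {
      stopifnot(length(thresholds[[j]]) == mm[j])
      thresholds[[j]] <- thresholds[[j]] - mean(thresholds[[j]])
    } else thresholds[j] <- list(NULL)
  }
  if (is.null(scale)) scale <- rep("test", length(specs))
  structure(list(specs = specs,
                 difficulty = stats::setNames(as.numeric(difficulty), ids),
                 thresholds = stats::setNames(thresholds, ids),
                 scale = stats::setNames(scale, ids)),
            class = "item_bank")
}

#' @export
print.item_bank <- function(x, ...) {
  cat(sprintf("<item_bank> %d items (%s), difficulties %.2f to %.2f\n",
              length(x$specs), paste(unique(x$scale), collapse = "/"),
              min(x$difficulty), max(x$difficulty)))
  invisible(x)
}

#' Default 23-item mixed bank
#'
#' Emulates the published adolescent health literacy battery: 6 dichotomous
#' functional items, 10 dichotomous interactive items, and 7 critical items
#' (2 dichotomous + 5 partial-credit worth 12 score points, so the critical
#' scale spans 0-14). True difficulties are the published individual
#' calibrations, spanning about -2.05 to +2.91 logits; partial-credit step
#' thresholds are package defaults since per-item category structures were
#' not published.
#'
#' @return An [item_bank()] with `scale` tags `"fhl"`, `"ihl"`, `"chl"`.
#' @export
default_item_bank <- function() {
  fhl <- c(FHLD7 = 0.98, FHLD5 = 0.73, FHLD3 = 0.62, FHLD6 = -0.12,
           FHLD4 = -0.94, FHLD2 = -1.28)
  ihl <- c(ICHLD13 = 2.91, ICHLD18 = 2.02, ICHLD14 = 0.64, ICHLD17 = 0.35,
           ICHLD8 = -0.02, ICHLD16 = -0.26, ICHLD6 = -0.50, ICHLD9 = -1.21,
           ICHLD5 = -1.87, ICHLD15 = -2.05)
  chl <- c(CRHLD6 = 0.81, CRHLD2 = 0.47, CRHLPC11 = 0.36, CRHLP4 = -0.04,
           CRHLP5 = -0.05, CRHLP7 = -0.65, ICCHLP3R = -0.89)
  chl_max <- c(CRHLD6 = 1L, CRHLD2 = 1L, CRHLPC11 = 2L, CRHLP4 = 3L,
               CRHLP5 = 3L, CRHLP7 = 2L, ICCHLP3R = 2L)
  mk <- function(ids, mx) lapply(seq_along(ids), function(i)
    item_spec(ids[i],
              if (mx[i] == 1L) "dichotomous" else "partial_credit",
              mx[i]))
  specs <- test_spec(c(mk(names(fhl), rep(1L, 6)),
                       mk(names(ihl), rep(1L, 10)),
                       mk(names(chl), chl_max)))
  thr <- list(CRHLPC11 = c(-1, 1), CRHLP4 = c(-1.6, 0, 1.6),
              CRHLP5 = c(-1.6, 0, 1.6), CRHLP7 = c(-1, 1),
              ICCHLP3R = c(-1, 1))
  all_thr <- stats::setNames(vector("list", 23L), item_ids(specs))
  all_thr[names(thr)] <- thr
  item_bank(specs, c(fhl, ihl, chl), all_thr,
            scale = rep(c("fhl", "ihl", "chl"), c(6L, 10L, 7L)))
}

#' Cohort generation configuration
#'
#' Captures every condition of a simulated validation study: sample size,
#' true item bank, ability distribution (a two-component normal mixture by
#' default, giving the left-skewed shape of a high-school health-class
#' sample sitting about a logit above the item centers), optional injected
#' uniform DIF, person misfit, theta-independent noise items, reverse-keyed
#' items, criterion-behavior link, convergent-measure noise, and missingness.
#'
#' @param n_persons Cohort size (default 355).
#' @param bank An [item_bank()] (default [default_item_bank()]).
#' @param ability List describing the ability distribution: either
#'   `list(type = "normal", mean =, sd =)` or `list(type = "mixture",
#'   means =, sds =, weights =)`.
#' @param dif_effects Optional data frame `item_id`, `grouping` (one of
#'   `"gender"`, `"age_band"`, `"ethnicity"`), `shift` (logits added to the
#'   item's difficulty for the grouping's second level).
#' @param misfit_persons List `n` (count) and `mechanism`
#'   (`"random_responder"`: whole row answered uniformly at random;
#'   `"careless_tail"`: final third of the items answered uniformly).
#' @param noise_items Optional data frame `item_id`, `rate`: these items'
#'   responses are Bernoulli(`rate`) independent of ability (uniform over
#'   categories for partial-credit items).
#' @param reversed_items Ids of items whose generated scores are flipped to
#'   `max_score - x` (reverse-keyed).
#' @param criterion_link List `slope` (per raw-score-point log-odds) and
#'   named `intercepts` for the two behavior columns.
#' @param convergent_noise_sd SD of the ability noise behind the 6-item
#'   convergent screener (default 0.8, giving moderate hetero-trait
#'   correlations around 0.45).
#' @param missing_rate Independent per-cell missingness probability.
#' @param seed Mandatory integer seed.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_persons = 355L,
                          bank = default_item_bank(),
                          ability = list(type = "mixture",
                                         means = c(1.3, -0.3),
                                         sds = c(0.9, 1.1),
                                         weights = c(0.75, 0.25)),
                          dif_effects = NULL,
                          misfit_persons = list(n = 0L, mechanism = "random_responder"),
                          noise_items = NULL,
                          reversed_items = character(0),
                          criterion_link = list(
                            slope = log(1.15),
                            intercepts = c(questions_online = -2.73,
                                           reads_instructions = -2.26)),
                          convergent_noise_sd = 0.8,
                          missing_rate = 0,
                          seed) {
  if (missing(seed)) stop("seed is mandatory for reproducibility", call. = FALSE)
  stopifnot(inherits(bank, "item_bank"), n_persons >= 2L,
            missing_rate >= 0, missing_rate <= 1)
  if (!is.null(dif_effects))
    stopifnot(all(c("item_id", "grouping", "shift") %in% names(dif_effects)),
              all(is.finite(dif_effects$shift)))
  if (!is.null(noise_items))
    stopifnot(all(noise_items$item_id %in% item_ids(bank$specs)))
  structure(list(n_persons = as.integer(n_persons), bank = bank,
                 ability = ability, dif_effects = dif_effects,
                 misfit_persons = misfit_persons, noise_items = noise_items,
                 reversed_items = reversed_items,
                 criterion_link = criterion_link,
                 convergent_noise_sd = convergent_noise_sd,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "cohort_config")
}

draw_ability <- function(n, ability) {
  if (identical(ability$type, "normal"))
    return(stats::rnorm(n, ability$mean, ability$sd))
  comp <- sample.int(length(ability$weights), n, replace = TRUE,
                     prob = ability$weights)
  stats::rnorm(n, ability$means[comp], ability$sds[comp])
}

#' Draw Rasch/PCM responses at given abilities
#'
#' Cell-wise draws from the model category probabilities at the true
#' parameters; the generating law of every model-consistent cell of
#' [generate_cohort()].
#'
#' @param theta Ability vector.
#' @param bank An [item_bank()].
#' @param difficulty_matrix Optional persons x items matrix of effective
#'   difficulties (overrides the bank's, e.g. after DIF shifts).
#' @return Integer response matrix (persons x items).
#' @export
draw_responses <- function(theta, bank, difficulty_matrix = NULL) {
  n <- length(theta)
  ids <- item_ids(bank$specs)
  X <- matrix(NA_integer_, n, length(ids), dimnames = list(NULL, ids))
  for (j in seq_along(ids)) {
    bcol <- if (is.null(difficulty_matrix)) rep(bank$difficulty[j], n)
            else difficulty_matrix[, j]
    m <- max_scores(bank$specs)[j]
    tau <- bank$thresholds[[j]]
    u <- stats::runif(n)
    for (lvl in unique(bcol)) {      # vectorized within identical difficulty
      rows <- which(bcol == lvl)
      P <- pcm_prob_matrix(theta[rows], item_steps(lvl, tau))
      cum <- P %*% upper.tri(diag(m + 1L), diag = TRUE)
      X[rows, j] <- as.integer(rowSums(u[rows] > cum))
    }
  }
  X
}

#' Generate a synthetic validation cohort
#'
#' Draws a full study-like dataset with recoverable ground truth: abilities
#' from the configured distribution, responses cell-wise from the
#' dichotomous/partial-credit Rasch probabilities (with DIF shifts applied
#' to the affected group's effective difficulties), noise/reversed/misfit
#' injections overwriting the affected cells, missingness masking, plus a
#' demographic covariate table, two criterion behavior columns, and a 6-item
#' convergent screener score.
#'
#' @param config A [cohort_config()].
#' @return List of class `synthetic_cohort` with `responses` (a
#'   [response_matrix()]), `covariates` (person_id, gender, age, age_band,
#'   ethnicity, behavior columns, `nvs_score`), and `truth` (every
#'   generating parameter: theta, the bank, the effective difficulty matrix,
#'   injections, seed).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_persons
  bank <- config$bank
  ids <- item_ids(bank$specs)
  mm <- max_scores(bank$specs)

  theta <- draw_ability(n, config$ability)
  gender <- sample(c("male", "female"), n, replace = TRUE, prob = c(0.45, 0.55))
  age <- sample(12:18, n, replace = TRUE,
                prob = c(19, 19, 19, 50, 63, 101, 34))
  ethnicity <- sample(c("hispanic_latinx", "not_hispanic_latinx"), n,
                      replace = TRUE, prob = c(0.505, 0.495))
  groupings <- data.frame(gender = factor(gender, c("male", "female")),
                          age_band = age_band(age),
                          ethnicity = factor(ethnicity,
                                             c("hispanic_latinx",
                                               "not_hispanic_latinx")))

  # effective difficulties: DIF shifts apply to the second grouping level
  B <- matrix(bank$difficulty, n, length(ids), byrow = TRUE,
              dimnames = list(NULL, ids))
  if (!is.null(config$dif_effects)) {
    for (r in seq_len(nrow(config$dif_effects))) {
      grp <- as.character(config$dif_effects$grouping[r])
      id <- as.character(config$dif_effects$item_id[r])
      g <- groupings[[grp]]
      hit <- !is.na(g) & g == levels(g)[2L]
      B[hit, id] <- B[hit, id] + config$dif_effects$shift[r]
    }
  }

  X <- draw_responses(theta, bank, difficulty_matrix = B)

  noise_ids <- character(0)
  if (!is.null(config$noise_items)) {
    noise_ids <- config$noise_items$item_id
    for (r in seq_len(nrow(config$noise_items))) {
      id <- config$noise_items$item_id[r]
      m <- mm[id]
      X[, id] <- if (m == 1L)
        stats::rbinom(n, 1L, config$noise_items$rate[r])
      else sample(0:m, n, replace = TRUE)
    }
  }
  for (id in config$reversed_items) X[, id] <- mm[id] - X[, id]

  misfit_ids <- character(0)
  person_ids <- sprintf("P%03d", seq_len(n))
  if (config$misfit_persons$n > 0L) {
    rows <- sample.int(n, config$misfit_persons$n)
    misfit_ids <- person_ids[rows]
    for (i in rows) {
      cols <- if (identical(config$misfit_persons$mechanism, "careless_tail"))
        seq.int(ceiling(2 * length(ids) / 3) + 1L, length(ids))
      else seq_along(ids)
      X[i, cols] <- vapply(cols, function(j)
        sample(0:mm[j], 1L), integer(1))
    }
  }

  if (config$missing_rate > 0)
    X[matrix(stats::runif(length(X)) < config$missing_rate,
             nrow(X), ncol(X))] <- NA_integer_

  responses <- response_matrix(X, bank$specs, person_ids = person_ids)

  raw <- rowSums(X, na.rm = TRUE)
  beh <- generate_criterion_behaviors(raw, config$criterion_link$slope,
                                      config$criterion_link$intercepts)
  nvs <- generate_convergent_measure(theta, config$convergent_noise_sd)

  covariates <- data.frame(person_id = person_ids, gender = gender,
                           age = age, age_band = as.character(groupings$age_band),
                           ethnicity = ethnicity, beh,
                           nvs_score = nvs)
  truth <- list(theta = stats::setNames(theta, person_ids),
                difficulty = bank$difficulty,
                thresholds = bank$thresholds,
                effective_difficulty = B,
                scale = bank$scale,
                dif_effects = config$dif_effects,
                noise_items = config$noise_items,
                reversed_items = config$reversed_items,
                misfit_persons = misfit_ids,
                groupings = data.frame(person_id = person_ids, groupings),
                criterion_link = config$criterion_link,
                convergent_noise_sd = config$convergent_noise_sd,
                seed = config$seed)
  structure(list(responses = responses, covariates = covariates,
                 truth = truth, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d persons x %d items (seed %d)\n",
              nrow(x$responses$scores), ncol(x$responses$scores),
              x$truth$seed))
  invisible(x)
}

#' Generate criterion behavior columns
#'
#' Two binary health-literacy-related behaviors (questioning the
#' truthfulness of online health information; reading instructions before
#' taking medicine) drawn Bernoulli from a logistic link on a summed-score
#' proxy: `P = plogis(intercept + slope * score)`.
#'
#' @param score Numeric summed-score proxy per person.
#' @param slope Per-point log-odds slope.
#' @param intercepts Named numeric vector; one behavior column per entry.
#' @return Data frame of 0/1 columns named `beh_<name>`.
#' @export
generate_criterion_behaviors <- function(score, slope, intercepts) {
  out <- lapply(intercepts, function(b0)
    stats::rbinom(length(score), 1L, stats::plogis(b0 + slope * score)))
  stats::setNames(as.data.frame(out), paste0("beh_", names(intercepts)))
}

#' Generate a convergent screener score
#'
#' Six dichotomous pseudo-items answered under the same Rasch law at a
#' noise-perturbed ability (`theta + N(0, noise_sd)`), emulating an
#' established functional-literacy screener that is harder than the focal
#' test. Returns the summed 0-6 score.
#'
#' @param theta True abilities.
#' @param noise_sd SD of the independent ability noise.
#' @param difficulties The 6 pseudo-item difficulties (default
#'   `c(0.4, 0.8, 1.2, 1.6, 2.0, 2.4)`).
#' @return Integer vector of summed scores 0-6.
#' @export
generate_convergent_measure <- function(theta, noise_sd,
                                        difficulties = c(0.4, 0.8, 1.2,
                                                         1.6, 2.0, 2.4)) {
  stopifnot(length(difficulties) == 6L, noise_sd >= 0)
  th <- theta + stats::rnorm(length(theta), 0, noise_sd)
  P <- stats::plogis(outer(th, difficulties, `-`))
  s <- rowSums(matrix(stats::rbinom(length(P), 1L, P), nrow = length(th)))
  if (stats::sd(s) < 0.25)
    warning("convergent screener shows a floor/ceiling effect (near-zero variance)")
  as.integer(s)
}

#' Frozen injection-study designs for purification
#'
#' The two misfit-injection studies that mirror the published purification
#' narratives structurally: `"six_noise"` is a 12-item set whose 6 noise
#' items respond independently of ability (Bernoulli with extreme marginal
#' rates, the lucky-guess / careless-error pattern outfit targets);
#' `"reverse_keyed"` is a 15-item set with 4 such noise items plus one fully
#' reverse-keyed item. Both use a wide ability distribution (SD 2 logits) so
#' ability-independent responding is statistically separable from model
#' misfit at n = 355 (see the methods vignette).
#'
#' @param type `"six_noise"` or `"reverse_keyed"`.
#' @param seed Integer seed.
#' @param n_persons Cohort size (default 355).
#' @return A [cohort_config()].
#' @export
purification_design <- function(type = c("six_noise", "reverse_keyed"),
                                seed, n_persons = 355L) {
  type <- match.arg(type)
  mk_bank <- function(good_b, n_noise) {
    ids <- c(sprintf("G%02d", seq_along(good_b)),
             if (n_noise) sprintf("N%02d", seq_len(n_noise)),
             if (type == "reverse_keyed") "R01")
    b <- c(good_b, rep(0, length(ids) - length(good_b)))
    item_bank(test_spec(lapply(ids, item_spec)), b,
              scale = rep("test", length(ids)))
  }
  if (type == "six_noise") {
    bank <- mk_bank(seq(-1.2, 1.2, length.out = 6L), 6L)
    noise <- data.frame(item_id = sprintf("N%02d", 1:6),
                        rate = c(0.07, 0.10, 0.12, 0.88, 0.90, 0.93))
    rev <- character(0)
  } else {
    bank <- mk_bank(seq(-1.2, 1.2, length.out = 10L), 4L)
    noise <- data.frame(item_id = sprintf("N%02d", 1:4),
                        rate = c(0.07, 0.10, 0.90, 0.93))
    rev <- "R01"
  }
  cohort_config(n_persons = n_persons, bank = bank,
                ability = list(type = "normal", mean = 0, sd = 2),
                noise_items = noise, reversed_items = rev, seed = seed)
}
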