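#' Estimation settings for joint maximum likelihood
#'
#' @param convergence_tol Convergence tolerance on the maximum absolute
#'   parameter change per sweep, logits.
#' @param max_iterations Maximum number of alternating sweeps.
#' @param extreme_score_adjustment Fraction of a score point by which extreme
#'   raw scores are pulled inward when extrapolating measures for them in the
#'   score-to-measure table (the standard Rasch-software convention).
#' @param damping Largest permitted parameter move per Newton update, logits.
#' @param bias_correction If `TRUE`, shrink centered item difficulties by
#'   `(L - 1) / L` (`L` = number of items) to counter the known finite-test
#'   inflation of JMLE difficulty estimates. Off by default.
#' @return A list of class `estimation_settings`.
#' @export
estimation_settings <- function(convergence_tol = 1e-4, max_iterations = 200L,
                                extreme_score_adjustment = 0.3, damping = 1,
                                bias_correction = FALSE) {
  stopifnot(convergence_tol > 0, max_iterations >= 1,
            extreme_score_adjustment > 0, extreme_score_adjustment < 0.5,
            damping > 0)
  structure(list(convergence_tol = convergence_tol,
                 max_iterations = as.integer(max_iterations),
                 extreme_score_adjustment = extreme_score_adjustment,
                 damping = damping, bias_correction = bias_correction),
            class = "estimation_settings")
}

clamp <- function(x, lim) pmin(pmax(x, -lim), lim)

#' Joint maximum likelihood calibration
#'
#' Estimates person measures and item difficulties (with step thresholds for
#' partial-credit items) by joint maximum likelihood: alternating damped
#' one-parameter Newton-Raphson sweeps over persons and item steps until the
#' largest parameter change falls below tolerance. Identification is by
#' centering item difficulties at zero (thresholds are additionally centered
#' within each item). Persons with zero or perfect raw totals and items
#' without at least two distinct observed scores are removed before
#' estimation and reported in the calibration; missing responses are skipped,
#' not imputed.
#'
#' @param responses A [response_matrix()].
#' @param settings An [estimation_settings()].
#' @return An object of class `rasch_calibration` with elements
#'   `item_difficulty`, `item_se`, `thresholds`, `threshold_se` (per-item
#'   lists, `NULL` for dichotomous items), `person_measure`, `person_se`
#'   (named over all input persons, `NA` for excluded ones),
#'   `excluded_persons`, `excluded_items`, `converged`, `n_iterations`,
#'   `max_residual_change`, `specs` (retained items) and `settings`.
#' @export
estimate_jmle <- function(responses, settings = estimation_settings()) {
  stopifnot(inherits(responses, "response_matrix"),
            inherits(settings, "estimation_settings"))
  X <- responses$scores
  m_all <- max_scores(responses$specs)

  keep_p <- rep(TRUE, nrow(X))
  keep_i <- rep(TRUE, ncol(X))
  repeat {
    sub <- X[keep_p, keep_i, drop = FALSE]
    mm <- m_all[keep_i]
    ok_i <- vapply(seq_len(ncol(sub)), function(j) {
      v <- sub[, j][!is.na(sub[, j])]
      length(v) >= 2L && length(unique(v)) >= 2L
    }, logical(1))
    if (any(!ok_i)) { keep_i[which(keep_i)[!ok_i]] <- FALSE; next }
    tot <- rowSums(sub, na.rm = TRUE)
    admin_max <- rowSums(matrix(mm, nrow(sub), ncol(sub), byrow = TRUE) * !is.na(sub))
    ok_p <- rowSums(!is.na(sub)) >= 1L & tot > 0 & tot < admin_max
    if (any(!ok_p)) { keep_p[which(keep_p)[!ok_p]] <- FALSE; next }
    break
  }
  if (sum(keep_p) < 2L || sum(keep_i) < 2L)
    stop("matrix is not estimable after removing extreme persons/items",
         call. = FALSE)

  sub <- X[keep_p, keep_i, drop = FALSE]
  mm <- m_all[keep_i]
  n <- nrow(sub); k <- ncol(sub)
  tot <- rowSums(sub, na.rm = TRUE)
  admin_max <- rowSums(matrix(mm, n, k, byrow = TRUE) * !is.na(sub))

  # PROX-flavored starting values
  r_adj <- pmin(pmax(tot, 0.25), admin_max - 0.25)
  theta <- log(r_adj / (admin_max - r_adj))
  d <- lapply(seq_len(k), function(j) {
    x <- sub[, j][!is.na(sub[, j])]
    p <- pmin(pmax(mean(x) / mm[j], 0.02), 0.98)
    rep(log((1 - p) / p), mm[j])
  })

  dampen <- settings$damping
  delta <- Inf
  it <- 0L
  cat_idx <- lapply(mm, function(m) 0:m)
  obs_idx <- lapply(seq_len(k), function(j) which(!is.na(sub[, j])))
  ge_counts <- lapply(seq_len(k), function(j) {
    x <- sub[obs_idx[[j]], j]
    vapply(seq_len(mm[j]), function(s) sum(x >= s), numeric(1))
  })

  while (it < settings$max_iterations) {
    it <- it + 1L
    old <- c(theta, unlist(d))

    sumE <- numeric(n); sumW <- numeric(n)
    for (j in seq_len(k)) {
      P <- pcm_prob_matrix(theta, d[[j]])
      kk <- cat_idx[[j]]
      E <- drop(P %*% kk); W <- drop(P %*% (kk^2)) - E^2
      o <- obs_idx[[j]]
      sumE[o] <- sumE[o] + E[o]
      sumW[o] <- sumW[o] + W[o]
    }
    theta <- theta + clamp((tot - sumE) / pmax(sumW, 1e-10), dampen)

    for (j in seq_len(k)) {
      o <- obs_idx[[j]]
      P <- pcm_prob_matrix(theta[o], d[[j]])
      for (s in seq_len(mm[j])) {
        Pge <- rowSums(P[, (s + 1L):(mm[j] + 1L), drop = FALSE])
        U <- sum(Pge) - ge_counts[[j]][s]
        info <- sum(Pge * (1 - Pge))
        move <- clamp(U / max(info, 1e-10), dampen)
        d[[j]][s] <- d[[j]][s] + move
        if (s < mm[j]) {  # refresh probs so later steps see the move
          P <- pcm_prob_matrix(theta[o], d[[j]])
        }
      }
    }

    ctr <- mean(vapply(d, mean, numeric(1)))
    d <- lapply(d, function(v) v - ctr)
    theta <- theta - ctr

    delta <- max(abs(c(theta, unlist(d)) - old))
    if (delta < settings$convergence_tol) break
  }
  converged <- delta < settings$convergence_tol

  # standard errors from the relevant information sums at the solution
  sumW <- numeric(n)
  item_info <- numeric(k)
  step_se <- vector("list", k)
  for (j in seq_len(k)) {
    o <- obs_idx[[j]]
    P <- pcm_prob_matrix(theta, d[[j]])
    kk <- cat_idx[[j]]
    E <- drop(P %*% kk); W <- drop(P %*% (kk^2)) - E^2
    sumW[o] <- sumW[o] + W[o]
    item_info[j] <- sum(W[o])
    step_se[[j]] <- vapply(seq_len(mm[j]), function(s) {
      Pge <- rowSums(P[o, (s + 1L):(mm[j] + 1L), drop = FALSE])
      1 / sqrt(max(sum(Pge * (1 - Pge)), 1e-10))
    }, numeric(1))
  }

  b <- vapply(d, mean, numeric(1))
  if (settings$bias_correction && k > 1L) {
    shrink <- (k - 1) / k
    d <- lapply(seq_len(k), function(j) d[[j]] - b[j] + b[j] * shrink)
    b <- b * shrink
  }
  tau <- lapply(seq_len(k), function(j)
    if (mm[j] > 1L) unname(d[[j]] - b[j]) else NULL)

  specs_kept <- test_spec(unname(unclass(responses$specs)[keep_i]))
  ids_i <- item_ids(specs_kept)
  names(b) <- ids_i
  # difficulty is the mean of the estimated steps: propagate step SEs
  # (for dichotomous items this equals 1/sqrt(sum W))
  item_se <- stats::setNames(vapply(seq_len(k), function(j)
    sqrt(sum(step_se[[j]]^2)) / mm[j], numeric(1)), ids_i)
  names(tau) <- ids_i
  names(step_se) <- ids_i

  all_p <- responses$person_ids
  pm <- stats::setNames(rep(NA_real_, length(all_p)), all_p)
  ps <- pm
  pm[keep_p] <- theta
  ps[keep_p] <- 1 / sqrt(pmax(sumW, 1e-10))

  structure(list(
    item_difficulty = b, item_se = item_se,
    thresholds = tau,
    threshold_se = lapply(seq_len(k), function(j) if (mm[j] > 1L) step_se[[j]] else NULL),
    person_measure = pm, person_se = ps,
    excluded_persons = all_p[!keep_p],
    excluded_items = unname(item_ids(responses$specs)[!keep_i]),
    converged = converged, n_iterations = it,
    max_residual_change = delta,
    specs = specs_kept, settings = settings
  ), class = "rasch_calibration")
}

#' @export
print.rasch_calibration <- function(x, ...) {
  cat(sprintf(
    "<rasch_calibration> %d items, %d measured persons (%d excluded)\n",
    length(x$item_difficulty),
    sum(!is.na(x$person_measure)), length(x$excluded_persons)))
  cat(sprintf("  converged: %s after %d sweeps (max change %.2g logits)\n",
              x$converged, x$n_iterations, x$max_residual_change))
  cat("  difficulty range:",
      paste(sprintf("%.2f", range(x$item_difficulty)), collapse = " to "),
      "logits\n")
  invisible(x)
}

#' Assemble a calibration object from known parameters
#'
#' Low-level constructor used when item and person parameters are known a
#' priori (e.g. simulation truth) rather than estimated; the result can be
#' passed to every diagnostic that accepts an estimated calibration.
#'
#' @param specs A [test_spec()].
#' @param item_difficulty Named or positional numeric vector, one per item.
#' @param person_measure Numeric vector of person measures.
#' @param thresholds Optional list of centered step thresholds per item
#'   (`NULL` entries for dichotomous items).
#' @param person_ids Optional person ids.
#' @return A `rasch_calibration`.
#' @export
manual_calibration <- function(specs, item_difficulty, person_measure,
                               thresholds = NULL, person_ids = NULL) {
  if (!inherits(specs, "test_spec")) specs <- test_spec(specs)
  ids <- item_ids(specs)
  mm <- max_scores(specs)
  stopifnot(length(item_difficulty) == length(specs))
  if (is.null(thresholds))
    thresholds <- lapply(mm, function(m) if (m > 1L) rep(0, m) else NULL)
  if (is.null(person_ids)) person_ids <- paste0("P", seq_along(person_measure))
  structure(list(
    item_difficulty = stats::setNames(as.numeric(item_difficulty), ids),
    item_se = stats::setNames(rep(NA_real_, length(ids)), ids),
    thresholds = stats::setNames(thresholds, ids),
    threshold_se = stats::setNames(vector("list", length(ids)), ids),
    person_measure = stats::setNames(as.numeric(person_measure), person_ids),
    person_se = stats::setNames(rep(NA_real_, length(person_measure)), person_ids),
    excluded_persons = character(0), excluded_items = character(0),
    converged = TRUE, n_iterations = 0L, max_residual_change = 0,
    specs = specs, settings = estimation_settings()
  ), class = "rasch_calibration")
}

# expected scores / variances for every calibrated item at abilities theta:
# returns list(E = matrix, W = matrix), persons x items
calibration_moments <- function(calibration, theta) {
  ids <- names(calibration$item_difficulty)
  E <- W <- matrix(NA_real_, length(theta), length(ids),
                   dimnames = list(NULL, ids))
  for (j in seq_along(ids)) {
    d <- item_steps(calibration$item_difficulty[j],
                    calibration$thresholds[[j]])
    P <- pcm_prob_matrix(theta, d)
    kk <- 0:length(d)
    E[, j] <- drop(P %*% kk)
    W[, j] <- drop(P %*% (kk^2)) - E[, j]^2
  }
  list(E = E, W = W)
}

# test characteristic curve: expected raw total at each theta
tcc_value <- function(calibration, theta) {
  rowSums(calibration_moments(calibration, theta)$E)
}

#' Score-to-measure table
#'
#' Maps every attainable raw score of the calibrated test to a measure in
#' logits (the ability at which the test characteristic curve equals the raw
#' score) and its standard error (inverse square root of test information).
#' Extreme raw scores (zero and perfect) carry extrapolated measures obtained
#' by adjusting the extreme score inward by
#' `settings$extreme_score_adjustment` score points.
#'
#' @param calibration A converged [estimate_jmle()] calibration.
#' @return A data frame with columns `raw_score`, `measure`, `se`; measures
#'   are strictly increasing in raw score.
#' @export
score_to_measure_table <- function(calibration) {
  stopifnot(inherits(calibration, "rasch_calibration"))
  if (!calibration$converged)
    warning("calibration did not converge; score table may be unstable")
  mm <- max_scores(calibration$specs)
  r_max <- sum(mm)
  adj <- calibration$settings$extreme_score_adjustment
  raw <- 0:r_max
  target <- pmin(pmax(raw, adj), r_max - adj)
  measure <- vapply(target, function(r) {
    stats::uniroot(function(t) tcc_value(calibration, t) - r,
                   interval = c(-40, 40), tol = 1e-9)$root
  }, numeric(1))
  se <- vapply(measure, function(t) {
    1 / sqrt(sum(calibration_moments(calibration, t)$W))
  }, numeric(1))
  data.frame(raw_score = raw, measure = measure, se = se)
}

#' Stationarity residuals of a calibration
#'
#' At the joint maximum, every retained person's expected raw total equals
#' the observed total, and likewise for items (and each partial-credit step's
#' expected category-threshold count). Returns the observed-minus-expected
#' totals so convergence can be audited.
#'
#' @param calibration A `rasch_calibration`.
#' @param responses The `response_matrix` it was estimated from.
#' @return List with numeric vectors `person` and `item` of raw-total
#'   residuals (retained persons/items only).
#' @export
jmle_stationarity <- function(calibration, responses) {
  al <- align_calibration(calibration, responses)
  mom <- calibration_moments(calibration, al$theta)
  Ehat <- mom$E
  Ehat[is.na(al$X)] <- NA
  list(person = rowSums(al$X, na.rm = TRUE) - rowSums(Ehat, na.rm = TRUE),
       item = colSums(al$X, na.rm = TRUE) - colSums(Ehat, na.rm = TRUE))
}

# restrict a response matrix to the persons/items measured in a calibration
# and return aligned pieces
align_calibration <- function(calibration, responses) {
  stopifnot(inherits(calibration, "rasch_calibration"),
            inherits(responses, "response_matrix"))
  ids_i <- names(calibration$item_difficulty)
  if (!all(ids_i %in% colnames(responses$scores)))
    stop("calibration and response matrix do not share item ids", call. = FALSE)
  measured <- names(calibration$person_measure)[!is.na(calibration$person_measure)]
  keep <- intersect(responses$person_ids, measured)
  X <- responses$scores[keep, ids_i, drop = FALSE]
  list(X = X, theta = calibration$person_measure[keep],
       person_ids = keep, item_ids = ids_i)
}
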