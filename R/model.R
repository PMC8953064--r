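#' Rasch dichotomous response probability
#'
#' Probability of a correct/endorsed response under the dichotomous Rasch
#' model, `P = exp(theta - b) / (1 + exp(theta - b))`. Persons with higher
#' ability have higher endorsement probabilities; harder items have lower
#' ones. Vectorized over `theta` and `b`.
#'
#' @param theta Person ability in logits.
#' @param b Item difficulty in logits.
#' @return Probability in (0, 1).
#' @export
#' @examples
#' dichotomous_prob(0, 0)        # 0.5
#' dichotomous_prob(log(3), 0)   # 0.75
dichotomous_prob <- function(theta, b) {
  if (!all(is.finite(theta)) || !all(is.finite(b)))
    stop("theta and b must be finite", call. = FALSE)
  stats::plogis(theta - b)
}

#' Partial credit model category probabilities
#'
#' Masters' partial credit model: for an item with `m` score steps,
#' `P(X = k)` is proportional to `exp(sum_{j <= k} (theta - b - tau_j))`
#' with `tau_0 = 0`. With `m = 1` this reduces exactly to the dichotomous
#' Rasch model.
#'
#' @param theta Person ability (scalar), logits.
#' @param b Overall item difficulty, logits.
#' @param tau Step thresholds, length `m`; conventionally centered (sum 0).
#' @return Numeric vector of length `m + 1` of category probabilities
#'   (categories `0..m`), summing to 1.
#' @export
#' @examples
#' pcm_category_probs(0, 0, c(0, 0))  # 1/3 each
pcm_category_probs <- function(theta, b, tau) {
  if (length(tau) < 1L) stop("tau must have at least one step", call. = FALSE)
  if (!all(is.finite(c(theta, b, tau)))) stop("inputs must be finite", call. = FALSE)
  eta <- c(0, cumsum(theta - b - tau))
  eta <- eta - max(eta)
  p <- exp(eta)
  p / sum(p)
}

# Step difficulties d_j = b + tau_j fully parameterize an item; the matrix
# form below is the workhorse used by estimation and diagnostics.
# Returns length(theta) x (m+1) matrix of category probabilities.
pcm_prob_matrix <- function(theta, d) {
  m <- length(d)
  S <- c(0, cumsum(d))                       # cumulative step difficulty
  eta <- outer(theta, 0:m) - matrix(S, length(theta), m + 1L, byrow = TRUE)
  eta <- eta - eta[cbind(seq_along(theta), max.col(eta, ties.method = "first"))]
  P <- exp(eta)
  P / rowSums(P)
}

#' Model-expected item score
#'
#' Expected score `E = sum_k k P(X = k)` for a calibrated item at ability
#' `theta`; strictly increasing in `theta`, bounded by `[0, max_score]`.
#'
#' @param theta Ability vector, logits.
#' @param b Item difficulty, logits.
#' @param tau Step thresholds for partial-credit items; `NULL` or length 1
#'   zero for dichotomous.
#' @return Numeric vector of expected scores.
#' @export
expected_score <- function(theta, b, tau = NULL) {
  d <- item_steps(b, tau)
  P <- pcm_prob_matrix(theta, d)
  drop(P %*% (0:length(d)))
}

#' Model score variance
#'
#' `W = sum_k k^2 P(k) - E^2`, the binomial/multinomial variance of the item
#' score at ability `theta`; the denominator of standardized residuals.
#'
#' @inheritParams expected_score
#' @return Numeric vector of variances (strictly positive for finite theta).
#' @export
score_variance <- function(theta, b, tau = NULL) {
  d <- item_steps(b, tau)
  P <- pcm_prob_matrix(theta, d)
  k <- 0:length(d)
  drop(P %*% (k^2)) - drop(P %*% k)^2
}

# step difficulties from (b, tau); tau NULL => dichotomous
item_steps <- function(b, tau = NULL) {
  if (is.null(tau) || length(tau) == 0L) return(b)
  b + tau
}
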