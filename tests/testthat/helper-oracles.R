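# Independent oracles and small generators shared across the test files.
# The oracles never call the estimation code they are used to check.

log1pexp <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

# Profile joint log-likelihood of a complete dichotomous matrix over a grid
# of item-difficulty vectors. B is G x k (one candidate difficulty vector
# per row); person abilities are profiled out by bisection on the raw score.
profile_loglik_b <- function(B, X) {
  r <- rowSums(X)
  s <- colSums(X)
  G <- nrow(B)
  ll <- -drop(B %*% s)
  for (rv in unique(r)) {
    nr <- sum(r == rv)
    lo <- rep(-35, G); hi <- rep(35, G)
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      f <- rowSums(stats::plogis(mid - B)) - rv
      up <- f > 0
      hi[up] <- mid[up]
      lo[!up] <- mid[!up]
    }
    th <- (lo + hi) / 2
    ll <- ll + nr * (rv * th - rowSums(log1pexp(th - B)))
  }
  ll
}

# Single-pass grid search at a fixed step (used for the worked small-matrix
# example); centers difficulties by construction (last = -sum of others).
grid_search_jmle <- function(X, step = 0.01, lim = 4) {
  k <- ncol(X)
  g <- seq(-lim, lim, by = step)
  Gm <- as.matrix(expand.grid(rep(list(g), k - 1L)))
  B <- cbind(Gm, -rowSums(Gm))
  ll <- profile_loglik_b(B, X)
  unname(B[which.max(ll), ])
}

# Staged grid refinement to ~0.002 precision; flags likelihoods maximized at
# the search boundary (inestimable, e.g. Guttman-separable margins).
staged_grid_jmle <- function(X, lim = 6) {
  k <- ncol(X)
  centers <- rep(0, k - 1L)
  width <- lim
  step <- lim / 12
  for (stage in 1:4) {
    grids <- lapply(centers, function(c0) seq(c0 - width, c0 + width, by = step))
    Gm <- as.matrix(expand.grid(grids))
    B <- cbind(Gm, -rowSums(Gm))
    ll <- profile_loglik_b(B, X)
    centers <- unname(Gm[which.max(ll), , drop = TRUE])
    if (stage == 1L && any(abs(centers) >= lim - step))
      return(list(boundary = TRUE, b = NULL))
    width <- step
    step <- step / 6
  }
  list(boundary = FALSE, b = c(centers, -sum(centers)))
}

# All sorted margin classes of estimable dichotomous matrices with n persons
# and k items (person totals 1..k-1, item totals 1..n-1, equal sums), each
# realized by a canonical Gale-Ryser matrix. JMLE estimates depend on the
# data only through these margins, so one matrix per class suffices.
margin_class_matrices <- function(n, k) {
  sorted_tuples <- function(len, vals) {
    g <- do.call(expand.grid, rep(list(vals), len))
    g <- as.matrix(g[apply(g, 1L, function(x) all(diff(x) >= 0)), , drop = FALSE])
    unname(g)
  }
  rs <- sorted_tuples(n, seq_len(k - 1L))
  ss <- sorted_tuples(k, seq_len(n - 1L))
  out <- list()
  for (i in seq_len(nrow(rs))) for (j in seq_len(nrow(ss))) {
    if (sum(rs[i, ]) != sum(ss[j, ])) next
    X <- matrix_from_margins(rs[i, ], ss[j, ])
    if (!is.null(X)) out[[length(out) + 1L]] <- X
  }
  out
}

# Greedy Gale-Ryser realization of 0/1 margins; NULL when infeasible.
matrix_from_margins <- function(r, s) {
  n <- length(r); k <- length(s)
  X <- matrix(0L, n, k)
  cap <- as.integer(s)
  for (i in order(r, decreasing = TRUE)) {
    cols <- order(cap, decreasing = TRUE)[seq_len(r[i])]
    if (any(cap[cols] <= 0L)) return(NULL)
    X[i, cols] <- 1L
    cap[cols] <- cap[cols] - 1L
  }
  if (any(cap != 0L)) return(NULL)
  X
}

# ---- small generators -------------------------------------------------

dich_bank <- function(b, ids = sprintf("I%02d", seq_along(b))) {
  item_bank(test_spec(lapply(ids, item_spec)), b)
}

# model-consistent dichotomous responses at given abilities/difficulties
draw_dich <- function(theta, b) {
  P <- stats::plogis(outer(theta, b, `-`))
  X <- matrix(stats::rbinom(length(P), 1L, P), nrow = length(theta))
  colnames(X) <- sprintf("I%02d", seq_along(b))
  X
}

dich_responses <- function(theta, b) {
  X <- draw_dich(theta, b)
  response_matrix(X, test_spec(lapply(colnames(X), item_spec)))
}

# enumeration oracle for the ROC area: mean over all (positive, negative)
# pairs of win = 1, tie = 0.5
auc_enumeration <- function(outcome, score) {
  pos <- score[outcome == 1]
  neg <- score[outcome == 0]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}
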