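#' Dichotomous Rasch item response function
#'
#' Probability of a correct response given person ability `theta` and
#' item difficulty `delta`, both in logits:
#' `P = exp(D(theta - delta)) / (1 + exp(D(theta - delta)))`.
#' At `theta == delta` the probability is exactly 0.5 for any scaling
#' constant.  Computed via `plogis()` so it saturates cleanly to 0/1 for
#' extreme arguments.
#'
#' @param theta Person ability (logits); vectorized.
#' @param delta Item difficulty (logits); vectorized.
#' @param D Positive scaling constant; 1 for the logit metric, 1.702 to
#'   closely match the normal-ogive (probit) curve.
#' @return Success probabilities.
#' @examples
#' irf_dichotomous(0, 0)          # 0.5
#' irf_dichotomous(1, 0, D = 1)   # 0.731...
#' @export
irf_dichotomous <- function(theta, delta, D = 1) {
  stopifnot(D > 0)
  plogis(D * (theta - delta))
}

#' Partial credit category probabilities
#'
#' For an item with step difficulties `steps = (d_1, ..., d_m)` the
#' probability of scoring `x` in `0..m` is proportional to
#' `exp(x * theta - sum(d_1..d_x))` (empty sum 0).  The adjacent-category
#' conditional probability `P(X = j | X in {j-1, j})` is the dichotomous
#' logistic `plogis(theta - d_j)`, so with `m = 1` this reduces exactly
#' to [irf_dichotomous()] with `D = 1`.
#'
#' @param theta Ability values (vectorized).
#' @param steps Numeric vector of step difficulties (length `m`).
#' @return A `length(theta) x (m+1)` matrix of category probabilities;
#'   each row sums to 1.
#' @examples
#' pcm_category_probabilities(0, c(-1, 1))  # symmetric: P(0) == P(2)
#' @export
pcm_category_probabilities <- function(theta, steps) {
  stopifnot(is.numeric(steps), length(steps) >= 1L, all(is.finite(steps)))
  m <- length(steps)
  csum <- c(0, cumsum(steps))            # cumulative step difficulty per category
  lgt <- outer(theta, 0:m) - rep(csum, each = length(theta))
  lgt <- lgt - apply(lgt, 1L, max)       # stabilize
  p <- exp(lgt)
  p / rowSums(p)
}

# Expected score and score variance per ability under a PCM item.
pcm_moments <- function(theta, steps) {
  p <- pcm_category_probabilities(theta, steps)
  cats <- 0:length(steps)
  mu <- drop(p %*% cats)
  ex2 <- drop(p %*% cats^2)
  ex3 <- drop(p %*% cats^3)
  v <- ex2 - mu^2
  list(p = p, mean = mu, var = pmax(v, 0),
       mu3 = ex3 - 3 * mu * ex2 + 2 * mu^3)   # third central moment (dVar/dtheta)
}

# Cumulative probabilities P(X >= j | theta), j = 1..m, as a matrix
# length(theta) x m.
pcm_cumulative <- function(theta, steps) {
  p <- pcm_category_probabilities(theta, steps)
  m <- length(steps)
  out <- matrix(0, nrow = length(theta), ncol = m)
  for (j in seq_len(m)) out[, j] <- rowSums(p[, (j + 1L):(m + 1L), drop = FALSE])
  out
}
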