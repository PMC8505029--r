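#' Estimate person abilities given an item calibration
#'
#' Per-person ability on the logit scale, maximizing the conditional
#' likelihood over administered items given the fixed step difficulties.
#' `"MLE"` is plain maximum likelihood; extreme raw scores (0 or the
#' maximum), for which the MLE diverges, receive a half-point score
#' correction (raw score pulled in by 0.3 points) and an `EXTREME` flag
#' so a finite ability and standard error are always reported.  `"WLE"`
#' is Warm's weighted likelihood estimate, which is finite at extremes
#' without correction.
#'
#' The standard error is the inverse square root of the test
#' information at the estimate, `se = [sum_i Var(X_i | theta)]^(-1/2)`,
#' which for dichotomous items is the familiar `[sum p(1-p)]^(-1/2)`.
#'
#' On complete data the raw score is a sufficient statistic: equal raw
#' scores give equal ability estimates.
#'
#' @param data A [response_matrix()] (or coercible).
#' @param items An item calibration tibble (`item_id`, `step`, `delta`),
#'   e.g. `fit$items` from [fit_rasch()].
#' @param estimator `"MLE"` or `"WLE"`.
#' @return A tibble: `person_id`, `raw_score`, `max_score`, `theta`,
#'   `se_theta`, `estimator`, `extreme` (logical), `n_administered`.
#'   Persons with no administered calibrated items get `NA` ability.
#' @export
estimate_abilities <- function(data, items, estimator = c("MLE", "WLE")) {
  estimator <- match.arg(estimator)
  rm <- as_response_matrix(data)
  steps <- calib_steps(items)
  use <- intersect(rm$item_ids, names(steps))
  mmax <- vapply(steps[use], length, integer(1))
  Y <- recode_scores(rm, steps[use])

  solve_one <- function(adm, raw) {
    st <- steps[use[adm]]
    total_max <- sum(mmax[adm])
    extreme <- raw == 0 || raw == total_max
    esc <- function(th) sum(vapply(st, function(s) pcm_moments(th, s)$mean, numeric(1)))
    info <- function(th) sum(vapply(st, function(s) pcm_moments(th, s)$var, numeric(1)))
    if (estimator == "MLE") {
      target <- raw
      if (raw == 0) target <- 0.3
      if (raw == total_max) target <- total_max - 0.3
      f <- function(th) esc(th) - target
    } else {
      f <- function(th) {
        mo <- lapply(st, function(s) pcm_moments(th, s))
        I <- sum(vapply(mo, `[[`, numeric(1), "var"))
        J <- sum(vapply(mo, `[[`, numeric(1), "mu3"))
        (raw - sum(vapply(mo, `[[`, numeric(1), "mean"))) + J / (2 * max(I, 1e-12))
      }
    }
    th <- tryCatch(uniroot(f, c(-15, 15), extendInt = "yes", tol = 1e-9)$root,
                   error = function(e) NA_real_)
    se <- if (is.finite(th)) 1 / sqrt(max(info(th), 1e-12)) else NA_real_
    list(theta = th, se = se, extreme = extreme)
  }

  cache <- new.env(parent = emptyenv())
  n <- nrow(Y)
  out <- vector("list", n)
  for (p in seq_len(n)) {
    adm <- which(!is.na(Y[p, ]))
    if (length(adm) == 0L) {
      out[[p]] <- list(theta = NA_real_, se = NA_real_, extreme = FALSE, raw = NA_real_,
                       mx = 0, nadm = 0L)
      next
    }
    raw <- sum(Y[p, adm])
    key <- paste(c(raw, adm), collapse = ",")
    res <- cache[[key]]
    if (is.null(res)) {
      res <- solve_one(adm, raw)
      cache[[key]] <- res
    }
    out[[p]] <- c(res, list(raw = raw, mx = sum(mmax[adm]), nadm = length(adm)))
  }
  tibble::tibble(
    person_id = rm$person_ids,
    raw_score = vapply(out, function(o) as.numeric(o$raw), numeric(1)),
    max_score = vapply(out, function(o) as.numeric(o$mx), numeric(1)),
    theta = vapply(out, function(o) o$theta, numeric(1)),
    se_theta = vapply(out, function(o) o$se, numeric(1)),
    estimator = estimator,
    extreme = vapply(out, function(o) o$extreme, logical(1)),
    n_administered = vapply(out, function(o) as.integer(o$nadm), integer(1))
  )
}

# Put observed scores on the calibrated category scale: when the data
# carry more categories than the calibration has steps (a collapsed
# fit), scores are recoded to the rank of their observed value.
recode_scores <- function(rm, steps) {
  Y <- rm$scores[, names(steps), drop = FALSE]
  for (i in seq_along(steps)) {
    m_cal <- length(steps[[i]])
    col <- Y[, i]
    obs <- sort(unique(col[!is.na(col)]))
    if (length(obs) && (max(obs) > m_cal || length(obs) > m_cal + 1L)) {
      Y[, i] <- match(col, obs) - 1L
    }
  }
  Y
}

#' Item difficulty standard errors from person abilities
#'
#' Fisher-information standard errors per step difficulty evaluated at
#' the estimated person abilities:
#' `se[delta_ij] = [sum_n S_j(theta_n)(1 - S_j(theta_n))]^(-1/2)` where
#' `S_j(theta) = P(X >= j | theta)`.  For a dichotomous item this is the
#' classical `[sum_n P_n(1-P_n)]^(-1/2)`.
#'
#' @param data A [response_matrix()] (or coercible).
#' @param items Item calibration tibble.
#' @param abilities Output of [estimate_abilities()].
#' @return The calibration tibble with the `se` column (re)computed;
#'   items administered to fewer than 2 persons get `NA`.
#' @export
item_standard_errors <- function(data, items, abilities) {
  rm <- as_response_matrix(data)
  steps <- calib_steps(items)
  th <- abilities$theta[match(rm$person_ids, abilities$person_id)]
  out <- items
  out$se <- NA_real_
  for (id in names(steps)) {
    col <- rm$scores[, id]
    adm <- which(!is.na(col) & is.finite(th))
    rows <- which(items$item_id == id)
    if (length(adm) < 2L) next
    S <- pcm_cumulative(th[adm], steps[[id]])
    info <- colSums(S * (1 - S))
    out$se[rows] <- 1 / sqrt(pmax(info, 1e-12))
  }
  out
}

#' Test information and conditional standard error curve
#'
#' `information(theta) = sum_i Var(X_i | theta)` over the calibrated
#' items, with `se(theta) = information^(-1/2)`; the ability standard
#' error is smallest where the test is most informative.
#'
#' @param items Item calibration tibble.
#' @param theta_grid Ability grid (logits).
#' @return Tibble: `theta`, `information`, `se`.
#' @export
test_information_curve <- function(items, theta_grid = seq(-4, 4, by = 0.1)) {
  stopifnot(length(theta_grid) >= 1L)
  steps <- calib_steps(items)
  im <- vapply(steps, function(s) pcm_moments(theta_grid, s)$var,
               numeric(length(theta_grid)))
  info <- if (is.matrix(im)) rowSums(im) else sum(im)
  tibble::tibble(theta = theta_grid, information = info, se = 1 / sqrt(pmax(info, 1e-300)))
}
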