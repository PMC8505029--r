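#' Fit a Rasch / partial credit model by marginal maximum likelihood
#'
#' Estimates item step difficulties by MML-EM: person ability is
#' integrated out of the likelihood under a normal population
#' distribution represented on a fixed grid of quadrature nodes
#' (re-weighted by the current normal density each cycle).  The E-step
#' computes posterior node weights per person; the M-step applies
#' safeguarded Newton updates to each item's step difficulties and
#' re-fits the latent mean/SD, so the deviance (-2 log marginal
#' likelihood) is non-increasing across cycles.
#'
#' Identification follows `config$constraint`: `"cases"` fixes the
#' latent mean at 0 (ability SD estimated, difficulties free);
#' `"items"` fixes the grand mean of all step difficulties at 0 and
#' estimates both latent mean and SD.
#'
#' Items with no observed score variation are excluded from calibration
#' and reported in `notes`; interior categories never observed are
#' collapsed (scores relabelled to the observed ordered categories) with
#' a note.
#'
#' @param data A [response_matrix()], or a data frame coercible to one.
#' @param config A [fit_config()].
#' @return A `rasch_fit` object with elements `items` (tibble:
#'   `item_id`, `step`, `delta`, `se`), `latent` (`mean`, `sd`, `nodes`,
#'   `weights`), `deviance`, `n_iterations`, `converged`, `config`,
#'   `data`, and `notes`.  `se` is the Fisher step-information standard
#'   error evaluated at the estimated person abilities.
#' @examples
#' sim <- sim_responses(sim_design(n_items = 10, n_persons = 200, seed = 7))
#' fit <- fit_rasch(sim$responses, fit_config("items"))
#' glance(fit)
#' @export
fit_rasch <- function(data, config = fit_config()) {
  rm <- as_response_matrix(data)
  prep <- prep_items(rm)
  if (length(prep$active) < 2L) abort("fewer than 2 calibratable items")
  em <- mml_em(prep, config)
  items <- calibration_tibble(prep, em$delta, constraint = config$constraint)
  fit <- structure(
    list(items = items, latent = em$latent, deviance = em$deviance,
         deviance_trace = em$trace, n_iterations = em$iter, converged = em$converged,
         config = config, data = rm, notes = prep$notes),
    class = "rasch_fit"
  )
  # Eq-4-style step SEs at the estimated abilities
  ab <- estimate_abilities(rm, items, estimator = "MLE")
  fit$items$se <- item_standard_errors(rm, items, ab)$se
  fit$abilities <- ab
  if (!em$converged) {
    warning("MML estimation did not converge within ", config$max_iterations,
            " iterations (deviance ", format(em$deviance), ")", call. = FALSE)
  }
  fit
}

#' @export
print.rasch_fit <- function(x, ...) {
  cat("<rasch_fit> ", length(unique(x$items$item_id)), " items, ",
      nrow(x$data$scores), " persons\n", sep = "")
  cat("  constraint: ", x$config$constraint,
      "; deviance: ", format(round(x$deviance, 2)),
      "; iterations: ", x$n_iterations,
      if (!x$converged) " (NOT converged)", "\n", sep = "")
  cat("  latent ability: mean ", round(x$latent$mean, 3),
      ", sd ", round(x$latent$sd, 3), "\n", sep = "")
  invisible(x)
}

# ---- internal preparation -------------------------------------------------

# Recode each item to its observed ordered categories; drop zero-variance
# items from calibration; keep a note trail.
prep_items <- function(rm) {
  I <- length(rm$item_ids)
  notes <- character()
  y <- rm$scores
  items <- vector("list", I)
  for (i in seq_len(I)) {
    obs <- sort(unique(y[, i][!is.na(y[, i])]))
    full <- 0:(rm$max_score[i])
    if (length(obs) <= 1L) {
      items[[i]] <- list(excluded = TRUE, map = obs, m = 0L)
      notes <- c(notes, paste0("item ", rm$item_ids[i],
                               " has no score variation; excluded from calibration"))
      next
    }
    collapsed <- !identical(as.numeric(obs), as.numeric(full))
    if (collapsed) {
      notes <- c(notes, paste0("item ", rm$item_ids[i], ": categories {",
                               paste(setdiff(full, obs), collapse = ","),
                               "} unobserved; collapsed to ", length(obs), " ordered categories"))
    }
    items[[i]] <- list(excluded = FALSE, map = obs, m = length(obs) - 1L,
                       y = match(y[, i], obs) - 1L)   # recoded 0..m, NA preserved
  }
  active <- which(!vapply(items, `[[`, logical(1), "excluded"))
  list(rm = rm, items = items, active = active, notes = notes)
}

# Log category-probability matrices (Q x (m+1)) for a step vector.
log_pcm_probs <- function(nodes, steps) log(pcm_category_probabilities(nodes, steps))

# Expected complete-data log-likelihood for one item given expected
# category counts r (Q x (m+1)).
item_expected_ll <- function(steps, nodes, r) {
  sum(r * log_pcm_probs(nodes, steps), na.rm = TRUE)
}

# Safeguarded Newton update of one item's step difficulties from expected
# category counts r (Q x (m+1)); returns the updated steps (never worse
# in expected log-likelihood).
item_newton <- function(steps, nodes, r, n_inner = 3L) {
  m <- length(steps)
  for (it in seq_len(n_inner)) {
    S <- pcm_cumulative(nodes, steps)           # Q x m, P(X >= j)
    nq <- rowSums(r)
    Rge <- sapply(seq_len(m), function(j)
      rowSums(r[, (j + 1L):(m + 1L), drop = FALSE]))  # Q x m observed >= j
    if (m == 1L) Rge <- matrix(Rge, ncol = 1L)
    g <- colSums(nq * S - Rge)
    H <- matrix(0, m, m)
    for (j in seq_len(m)) for (k in seq_len(m)) {
      H[j, k] <- -sum(nq * (S[, max(j, k)] - S[, j] * S[, k]))
    }
    dir <- tryCatch(solve(H, g), error = function(e) g / diag(H))
    dir[!is.finite(dir)] <- 0
    ll0 <- item_expected_ll(steps, nodes, r)
    step_size <- 1
    repeat {
      cand <- steps - step_size * dir
      if (item_expected_ll(cand, nodes, r) >= ll0 - 1e-12) { steps <- cand; break }
      step_size <- step_size / 2
      if (step_size < 1e-6) break
    }
    if (max(abs(step_size * dir)) < 1e-10) break
  }
  steps
}

# Core EM loop for the uni-dimensional model.  `fixed_delta` (named list
# of step vectors) anchors those items at fixed values (fixed-anchor
# equating); `free_latent_mean` overrides the constraint-implied rule.
mml_em <- function(prep, config, fixed_delta = NULL, free_latent_mean = NULL) {
  rm <- prep$rm
  active <- prep$active
  N <- nrow(rm$scores)
  Q <- config$n_quadrature
  zgrid <- seq(-5, 5, length.out = Q)          # +/- 5 population SDs
  wz <- dnorm(zgrid); wz <- wz / sum(wz)       # fixed normalized weights
  mu <- 0; sigma <- 1
  estimate_mu <- if (is.null(free_latent_mean)) config$constraint == "items" else free_latent_mean

  delta <- lapply(prep$items, function(it) if (it$excluded) numeric() else rep(0, it$m))
  if (!is.null(fixed_delta)) {
    for (i in names(fixed_delta)) delta[[match(i, rm$item_ids)]] <- fixed_delta[[i]]
  }
  fixed_idx <- if (is.null(fixed_delta)) integer() else match(names(fixed_delta), rm$item_ids)

  # log-likelihood matrix (N x Q) at node positions mu + sigma * z
  loglik_matrix <- function(mu, sigma, delta) {
    nodes <- mu + sigma * zgrid
    logL <- matrix(0, N, Q)
    for (i in active) {
      lp <- log_pcm_probs(nodes, delta[[i]])
      yi <- prep$items[[i]]$y
      ok <- !is.na(yi)
      logL[ok, ] <- logL[ok, ] + t(lp)[yi[ok] + 1L, , drop = FALSE]
    }
    logL
  }

  dev_old <- Inf; converged <- FALSE; iter <- 0L; trace <- numeric()
  repeat {
    iter <- iter + 1L
    nodes <- mu + sigma * zgrid
    logL <- loglik_matrix(mu, sigma, delta)
    lj <- sweep(logL, 2L, log(wz), `+`)
    mx <- apply(lj, 1L, max)
    wts <- exp(lj - mx)
    marg <- rowSums(wts)
    post <- wts / marg
    deviance <- -2 * sum(mx + log(marg))
    trace <- c(trace, deviance)
    if (is.finite(dev_old) && abs(dev_old - deviance) < config$convergence_tol) {
      converged <- TRUE
    }

    # M-step: items (safeguarded Newton per item on expected counts)
    max_dpar <- 0
    for (i in setdiff(active, fixed_idx)) {
      yi <- prep$items[[i]]$y
      ok <- !is.na(yi)
      r <- matrix(0, Q, prep$items[[i]]$m + 1L)
      for (x in 0:prep$items[[i]]$m) {
        sel <- ok & yi == x
        if (any(sel)) r[, x + 1L] <- colSums(post[sel, , drop = FALSE])
      }
      new_steps <- item_newton(delta[[i]], nodes, r)
      max_dpar <- max(max_dpar, max(abs(new_steps - delta[[i]])))
      delta[[i]] <- new_steps
    }

    # M-step: latent moments, accepted only if the EM objective improves
    # (generalized EM: node positions move with mu and sigma)
    Qfun <- function(m, s) sum(post * loglik_matrix(m, s, delta))
    q_old <- Qfun(mu, sigma)
    pmean <- drop(post %*% nodes)
    mu_cand <- if (estimate_mu) mean(pmean) else 0
    sigma_cand <- sqrt(mean(drop(post %*% nodes^2) - 2 * mu_cand * pmean + mu_cand^2))
    sigma_cand <- max(sigma_cand, 0.05)
    lam <- 1
    new_mu <- mu; new_sigma <- sigma
    repeat {
      m_try <- (1 - lam) * mu + lam * mu_cand
      s_try <- (1 - lam) * sigma + lam * sigma_cand
      if (Qfun(m_try, s_try) >= q_old - 1e-10) { new_mu <- m_try; new_sigma <- s_try; break }
      lam <- lam / 2
      if (lam < 1e-4) break
    }
    max_dpar <- max(max_dpar, abs(new_mu - mu), abs(new_sigma - sigma))
    mu <- new_mu; sigma <- new_sigma

    # identification: items constraint recenters the step grand mean,
    # compensating through the latent mean (likelihood invariant)
    if (config$constraint == "items" && is.null(fixed_delta)) {
      allsteps <- unlist(delta[active])
      cshift <- mean(allsteps)
      for (i in active) delta[[i]] <- delta[[i]] - cshift
      mu <- mu - cshift
    }

    if (converged || max_dpar < config$convergence_tol) { converged <- TRUE; break }
    if (iter >= config$max_iterations) break
    dev_old <- deviance
  }

  nodes <- mu + sigma * zgrid
  list(delta = delta, latent = list(mean = mu, sd = sigma, nodes = nodes, weights = wz),
       deviance = deviance, iter = iter, converged = converged, post = post,
       trace = trace)
}

calibration_tibble <- function(prep, delta, constraint) {
  rows <- purrr::map_dfr(prep$active, function(i) {
    it <- prep$items[[i]]
    tibble::tibble(item_id = prep$rm$item_ids[i], step = seq_len(it$m),
                   delta = delta[[i]], se = NA_real_)
  })
  attr(rows, "constraint") <- constraint
  attr(rows, "excluded") <- prep$rm$item_ids[setdiff(seq_along(prep$items), prep$active)]
  class(rows) <- c("item_calibration", class(rows))
  rows
}

# named list of step vectors from a calibration tibble
calib_steps <- function(items) {
  split(items$delta, factor(items$item_id, levels = unique(items$item_id)))
}

#' Evaluate the marginal deviance of a fitted model by fine-grid integration
#'
#' Independent of the EM quadrature: integrates each person's likelihood
#' against the fitted normal ability density on a dense grid, for
#' validating the quadrature approximation.
#'
#' @param fit A `rasch_fit`.
#' @param n_grid Number of grid points (default 10000).
#' @param span Half-width of the grid in population SDs (default 6).
#' @return Deviance (-2 log marginal likelihood) as a scalar.
#' @export
deviance_by_grid <- function(fit, n_grid = 10000L, span = 6) {
  rm <- fit$data
  steps <- calib_steps(fit$items)
  mu <- fit$latent$mean; sigma <- fit$latent$sd
  grid <- seq(mu - span * sigma, mu + span * sigma, length.out = n_grid)
  w <- dnorm(grid, mu, sigma); w <- w / sum(w)
  logL <- matrix(0, nrow(rm$scores), n_grid)
  prep <- prep_items(rm)
  for (i in prep$active) {
    id <- rm$item_ids[i]
    if (!id %in% names(steps)) next
    lp <- log_pcm_probs(grid, steps[[id]])
    yi <- prep$items[[i]]$y
    ok <- !is.na(yi)
    logL[ok, ] <- logL[ok, ] + t(lp)[yi[ok] + 1L, , drop = FALSE]
  }
  lj <- sweep(logL, 2L, log(w), `+`)
  mx <- apply(lj, 1L, max)
  -2 * sum(mx + log(rowSums(exp(lj - mx))))
}
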