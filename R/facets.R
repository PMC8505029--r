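#' Many-facets Rasch fit: group effects and group-by-item interactions
#'
#' Extends the (partial credit) Rasch model so that the effective
#' difficulty of item `i` for a member of group `g` is
#' `delta_i + G_g + D_gi`: `G_g` is the overall group effect on
#' difficulty and `D_gi` the group-by-item interaction that measures
#' differential item functioning.  Estimated by the same MML-EM as
#' [fit_rasch()] under a common normal ability population, with
#' sum-to-zero identification: `sum_g G_g = 0`, `sum_g D_gi = 0` for
#' every item, and `sum_i D_gi = 0` for every group (so interactions are
#' separated from group impact).  A positive `D_gi` means the item is
#' *harder* for group `g` than its overall difficulty predicts.
#'
#' Group-item cells with no score variation leave that interaction
#' fixed at 0 with an `NA` standard error and a note.
#'
#' @param data A [grouped_responses()] object (or a data frame whose
#'   first column is the group label).
#' @param config A [fit_config()].
#' @return A `facets_fit` with `items` (base calibration tibble),
#'   `effects` (tibble: `item_id`, `group`, `D`, `se_D`, `G`, `se_G`),
#'   `latent`, `deviance`, `n_iterations`, `converged`, `config`,
#'   `data`, `notes`.
#' @export
fit_facets <- function(data, config = fit_config()) {
  gr <- if (inherits(data, "grouped_responses")) data else grouped_responses(data)
  rm <- gr$base
  glev <- sort(unique(gr$group))
  G <- length(glev)
  gidx <- match(gr$group, glev)
  if (any(table(gidx) < 2L)) abort("every group needs at least 2 persons")
  prep <- prep_items(rm)
  active <- prep$active
  N <- nrow(rm$scores); Q <- config$n_quadrature
  zgrid <- seq(-5, 5, length.out = Q)
  wz <- dnorm(zgrid); wz <- wz / sum(wz)
  mu <- 0; sigma <- 1
  I <- length(rm$item_ids)
  delta <- lapply(prep$items, function(it) if (it$excluded) numeric() else rep(0, it$m))
  s <- matrix(0, G, I)              # group-by-item shifts (later G_g + D_gi)
  # cells without variation cannot support an interaction
  cell_ok <- matrix(FALSE, G, I)
  for (i in active) for (g in seq_len(G)) {
    yv <- prep$items[[i]]$y[gidx == g]
    cell_ok[g, i] <- length(unique(yv[!is.na(yv)])) >= 2L
  }
  notes <- prep$notes
  if (any(!cell_ok[, active])) {
    bad <- which(!cell_ok[, active, drop = FALSE], arr.ind = TRUE)
    notes <- c(notes, paste0("no score variation for group ", glev[bad[, 1]],
                             " on item ", rm$item_ids[active][bad[, 2]],
                             "; interaction fixed at 0"))
  }
  estimate_mu <- config$constraint == "items"

  loglik_matrix <- function(mu, sigma, delta, s) {
    nodes <- mu + sigma * zgrid
    logL <- matrix(0, N, Q)
    for (i in active) {
      yi <- prep$items[[i]]$y
      for (g in seq_len(G)) {
        ok <- !is.na(yi) & gidx == g
        if (!any(ok)) next
        lp <- log_pcm_probs(nodes - s[g, i], delta[[i]])   # shift via ability metric
        logL[ok, ] <- logL[ok, ] + t(lp)[yi[ok] + 1L, , drop = FALSE]
      }
    }
    logL
  }

  dev_old <- Inf; converged <- FALSE; iter <- 0L
  repeat {
    iter <- iter + 1L
    nodes <- mu + sigma * zgrid
    logL <- loglik_matrix(mu, sigma, delta, s)
    lj <- sweep(logL, 2L, log(wz), `+`)
    mx <- apply(lj, 1L, max)
    wts <- exp(lj - mx)
    marg <- rowSums(wts)
    post <- wts / marg
    deviance <- -2 * sum(mx + log(marg))
    if (is.finite(dev_old) && abs(dev_old - deviance) < config$convergence_tol) converged <- TRUE

    max_dpar <- 0
    for (i in active) {
      yi <- prep$items[[i]]$y
      m <- prep$items[[i]]$m
      # stack per-group expected counts on group-shifted nodes
      nodes_st <- c(); r_st <- NULL
      r_by_g <- vector("list", G)
      for (g in seq_len(G)) {
        r <- matrix(0, Q, m + 1L)
        for (x in 0:m) {
          sel <- !is.na(yi) & yi == x & gidx == g
          if (any(sel)) r[, x + 1L] <- colSums(post[sel, , drop = FALSE])
        }
        r_by_g[[g]] <- r
        nodes_st <- c(nodes_st, nodes - s[g, i])
        r_st <- rbind(r_st, r)
      }
      new_steps <- item_newton(delta[[i]], nodes_st, r_st)
      max_dpar <- max(max_dpar, max(abs(new_steps - delta[[i]])))
      delta[[i]] <- new_steps
      # per-group shift: 1-D safeguarded Newton on the shift parameter
      for (g in seq_len(G)) {
        if (!cell_ok[g, i]) next
        new_s <- shift_newton(s[g, i], nodes, delta[[i]], r_by_g[[g]])
        max_dpar <- max(max_dpar, abs(new_s - s[g, i]))
        s[g, i] <- new_s
      }
    }
    # re-identify: absorb per-item mean shift into the item steps, then
    # recentre so all sum-to-zero invariants hold exactly
    for (i in active) {
      a_i <- mean(s[, i])
      delta[[i]] <- delta[[i]] + a_i
      s[, i] <- s[, i] - a_i
    }

    # latent update from posterior moments, safeguarded (generalized EM)
    Qfun <- function(m0, s0) sum(post * loglik_matrix(m0, s0, delta, s))
    q_old <- Qfun(mu, sigma)
    pmean <- drop(post %*% nodes)
    mu_cand <- if (estimate_mu) mean(pmean) else 0
    sigma_cand <- max(sqrt(mean(drop(post %*% nodes^2) - 2 * mu_cand * pmean + mu_cand^2)), 0.05)
    lam <- 1
    repeat {
      m_try <- (1 - lam) * mu + lam * mu_cand
      s_try <- (1 - lam) * sigma + lam * sigma_cand
      if (Qfun(m_try, s_try) >= q_old - 1e-10) {
        max_dpar <- max(max_dpar, abs(m_try - mu), abs(s_try - sigma))
        mu <- m_try; sigma <- s_try; break
      }
      lam <- lam / 2
      if (lam < 1e-4) break
    }

    if (config$constraint == "items") {
      allsteps <- unlist(delta[active])
      cshift <- mean(allsteps)
      for (i in active) delta[[i]] <- delta[[i]] - cshift
      mu <- mu - cshift
    }
    if (converged || max_dpar < config$convergence_tol) { converged <- TRUE; break }
    if (iter >= config$max_iterations) break
    dev_old <- deviance
  }

  Gg <- rowMeans(s[, active, drop = FALSE])
  Gg <- Gg - mean(Gg)
  D <- s
  for (g in seq_len(G)) D[g, ] <- s[g, ] - Gg[g]
  items <- calibration_tibble(prep, delta, constraint = config$constraint)

  # Eq-4-style SEs for the shifts at the estimated abilities
  eff_steps <- function(g) {
    st <- calib_steps(items)
    for (id in names(st)) st[[id]] <- st[[id]] + Gg[g] + D[g, match(id, rm$item_ids)]
    st
  }
  theta_eap <- drop(post %*% nodes)       # EAP abilities from the final E-step
  se_s <- matrix(NA_real_, G, I)
  for (g in seq_len(G)) {
    st <- eff_steps(g)
    for (id in names(st)) {
      i <- match(id, rm$item_ids)
      if (!cell_ok[g, i]) next
      sel <- gidx == g & !is.na(rm$scores[, i])
      if (sum(sel) < 2L) next
      S <- pcm_cumulative(theta_eap[sel], st[[id]])
      se_s[g, i] <- 1 / sqrt(max(sum(S * (1 - S)), 1e-12))
    }
  }
  # se of the centred interaction D_gi from the per-group shift ses
  se_D <- matrix(NA_real_, G, I)
  for (g in seq_len(G)) for (i in active) {
    if (!cell_ok[g, i]) next
    w <- ifelse(seq_len(G) == g, 1 - 1 / G, -1 / G)
    se_D[g, i] <- sqrt(sum((w^2) * se_s[, i]^2, na.rm = TRUE))
  }
  se_G <- vapply(seq_len(G), function(g)
    sqrt(mean(se_s[g, active]^2, na.rm = TRUE) / length(active)), numeric(1))

  effects <- purrr::map_dfr(active, function(i) {
    tibble::tibble(item_id = rm$item_ids[i], group = glev,
                   D = D[, i], se_D = se_D[, i],
                   G = Gg, se_G = se_G)
  })
  structure(
    list(items = items, effects = effects,
         latent = list(mean = mu, sd = sigma, nodes = mu + sigma * zgrid, weights = wz),
         deviance = deviance, n_iterations = iter, converged = converged,
         config = config, data = gr, notes = notes),
    class = "facets_fit"
  )
}

# 1-D safeguarded Newton for a group-by-item difficulty shift given
# expected category counts r (Q x (m+1)) on the unshifted nodes
shift_newton <- function(s0, nodes, steps, r, n_inner = 3L) {
  cats <- 0:length(steps)
  obj <- function(s) sum(r * log(pcm_category_probabilities(nodes - s, steps)), na.rm = TRUE)
  s <- s0
  for (it in seq_len(n_inner)) {
    mo <- pcm_moments(nodes - s, steps)
    nq <- rowSums(r)
    xbar <- drop(r %*% cats)
    g <- sum(nq * mo$mean - xbar)       # d/ds expected ll
    h <- -sum(nq * mo$var)
    if (abs(h) < 1e-12) break
    dir <- g / h
    ll0 <- obj(s)
    step_size <- 1
    repeat {
      cand <- s - step_size * dir
      if (abs(cand) <= 10 && obj(cand) >= ll0 - 1e-12) { s <- cand; break }
      step_size <- step_size / 2
      if (step_size < 1e-6) break
    }
    if (abs(step_size * dir) < 1e-10) break
  }
  s
}

#' @export
print.facets_fit <- function(x, ...) {
  cat("<facets_fit> ", length(unique(x$effects$item_id)), " items, ",
      length(unique(x$effects$group)), " groups\n", sep = "")
  cat("  deviance: ", format(round(x$deviance, 2)),
      "; iterations: ", x$n_iterations,
      if (!x$converged) " (NOT converged)", "\n", sep = "")
  invisible(x)
}

#' Flag items for statistical and practical differential functioning
#'
#' `STATISTICAL` (rendered red) when `|D_gi| / se(D_gi)` exceeds the
#' two-sided normal critical value at `dif_alpha`; `PRACTICAL`
#' (rendered blue) when the between-group difficulty gap — for two
#' groups, `2 |D_gi|` — reaches `practical_logits`.  The flags are
#' independent; an item may carry either or both.
#'
#' @param fit A `facets_fit`.
#' @param dif_alpha Two-sided test level (default 0.05).
#' @param practical_logits Practical-significance gap in logits
#'   (default 0.5).
#' @return The effects tibble with `z`, `gap`, `statistical`,
#'   `practical` columns.
#' @export
dif_flags <- function(fit, dif_alpha = 0.05, practical_logits = 0.5) {
  stopifnot(inherits(fit, "facets_fit"))
  zcrit <- qnorm(1 - dif_alpha / 2)
  G <- length(unique(fit$effects$group))
  fit$effects |>
    dplyr::group_by(.data$item_id) |>
    dplyr::mutate(gap = max(.data$D) - min(.data$D)) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      z = .data$D / .data$se_D,
      statistical = !is.na(.data$z) & abs(.data$z) > zcrit,
      practical = .data$gap >= practical_logits
    )
}

#' Tabular DIF results with flag colors
#'
#' One row per item-by-group with estimate, standard error, z, gap, and
#' the flag colors used in reporting: `"red"` for statistical
#' significance, `"blue"` for practical significance, `""` for neither
#' (a cell carrying both serializes as `"red,blue"`).
#' Rows are ordered by gap, largest first.
#'
#' @inheritParams dif_flags
#' @return Tibble: `item_id`, `group`, `D`, `se_D`, `z`, `gap`,
#'   `flag_color`.
#' @export
dif_table <- function(fit, dif_alpha = 0.05, practical_logits = 0.5) {
  dif_flags(fit, dif_alpha, practical_logits) |>
    dplyr::mutate(flag_color = dplyr::case_when(
      .data$statistical & .data$practical ~ "red,blue",
      .data$statistical ~ "red",
      .data$practical ~ "blue",
      TRUE ~ ""
    )) |>
    dplyr::arrange(dplyr::desc(.data$gap), .data$item_id, .data$group) |>
    dplyr::select("item_id", "group", "D", "se_D", "z", "gap", "flag_color")
}
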