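#' Thurstonian thresholds
#'
#' For each item-category `j >= 1`, the ability `gamma_ij` at which the
#' cumulative probability of scoring at least `j` equals 0.5, solved by
#' bisection to 1e-8.  Cumulative curves are strictly monotone in
#' ability, so these thresholds are always strictly ordered within an
#' item even when the underlying step difficulties are disordered.  For
#' a dichotomous item the single threshold equals the item difficulty.
#'
#' Labels follow the `I-<item>-<category>` convention used on Wright
#' maps and in the developmental (skill) report.
#'
#' @param items Item calibration tibble (`item_id`, `step`, `delta`).
#' @return Tibble sorted by threshold: `item_id`, `category`, `gamma`,
#'   `label`.
#' @export
thurstonian_thresholds <- function(items) {
  steps <- calib_steps(items)
  rows <- purrr::map_dfr(names(steps), function(id) {
    st <- steps[[id]]
    m <- length(st)
    g <- vapply(seq_len(m), function(j) {
      f <- function(th) pcm_cumulative(th, st)[, j] - 0.5
      lo <- min(st) - 30; hi <- max(st) + 30
      while (hi - lo > 1e-8) {        # bisection; f strictly increasing
        mid <- (lo + hi) / 2
        if (f(mid) < 0) lo <- mid else hi <- mid
      }
      (lo + hi) / 2
    }, numeric(1))
    tibble::tibble(item_id = id, category = seq_len(m), gamma = g,
                   label = paste0("I-", id, "-", seq_len(m)))
  })
  dplyr::arrange(rows, .data$gamma)
}

#' Wright map data: person histogram and threshold positions
#'
#' Bins the estimated person abilities at the requested bin width on the
#' same logit axis as the labelled Thurstonian thresholds, the two
#' ingredients of a Wright (person-item) map.  Histogram counts conserve
#' the number of persons with a defined ability.  A targeting summary
#' compares the person mean with the threshold mean.
#'
#' @param abilities Tibble from [estimate_abilities()].
#' @param thresholds Tibble from [thurstonian_thresholds()].
#' @param binwidth Histogram bin width in logits (> 0).
#' @return List with `persons` (tibble: `bin_mid`, `count`),
#'   `thresholds` (the input, with labels), and `targeting` (list:
#'   `person_mean`, `threshold_mean`, `offset`, `verdict`).
#' @export
wright_map_data <- function(abilities, thresholds, binwidth = 0.25) {
  stopifnot(binwidth > 0)
  th <- abilities$theta[is.finite(abilities$theta)]
  breaks <- seq(floor(min(c(th, thresholds$gamma)) / binwidth) * binwidth - binwidth,
                ceiling(max(c(th, thresholds$gamma)) / binwidth) * binwidth + binwidth,
                by = binwidth)
  cut_idx <- findInterval(th, breaks, rightmost.closed = TRUE)
  counts <- tabulate(cut_idx, nbins = length(breaks) - 1L)
  persons <- tibble::tibble(bin_mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
                            count = counts)
  pm <- mean(th); tm <- mean(thresholds$gamma)
  offset <- pm - tm
  verdict <- if (all(thresholds$gamma < min(th))) "test too easy for all persons"
  else if (all(thresholds$gamma > max(th))) "test too hard for all persons"
  else if (offset > 0.5) "test targeted easy relative to the persons"
  else if (offset < -0.5) "test targeted hard relative to the persons"
  else "persons and item thresholds are matched well"
  list(persons = persons, thresholds = thresholds,
       targeting = list(person_mean = pm, threshold_mean = tm,
                        offset = offset, verdict = verdict))
}

#' Category orderedness table
#'
#' For every item and score category, the point-biserial correlation
#' between category membership (0/1 indicator) and estimated ability,
#' and the mean ability of persons in the category.  For a
#' well-functioning polytomous item both sequences increase strictly
#' with the category; non-monotone sequences are flagged
#' (`flag_pb`, `flag_theta`), ties counting as disordered.  Categories
#' with no members are emitted with `NA` statistics and `flag_empty`.
#'
#' @param data A [response_matrix()] (or coercible).
#' @param abilities Tibble from [estimate_abilities()].
#' @return Tibble: `item_id`, `category`, `n`, `pb`, `mean_theta`,
#'   `flag_pb`, `flag_theta`, `flag_empty`.
#' @export
orderedness_table <- function(data, abilities) {
  rm <- as_response_matrix(data)
  th <- abilities$theta[match(rm$person_ids, abilities$person_id)]
  rows <- purrr::map_dfr(seq_along(rm$item_ids), function(i) {
    col <- rm$scores[, i]
    ok <- !is.na(col) & is.finite(th)
    cats <- 0:rm$max_score[i]
    purrr::map_dfr(cats, function(x) {
      ind <- as.numeric(col[ok] == x)
      n_x <- sum(ind)
      pb <- if (n_x > 0 && n_x < sum(ok) && stats::sd(ind) > 0) cor(ind, th[ok]) else NA_real_
      tibble::tibble(item_id = rm$item_ids[i], category = x, n = n_x,
                     pb = pb, mean_theta = if (n_x > 0) mean(th[ok][ind == 1]) else NA_real_)
    })
  })
  rows |>
    dplyr::group_by(.data$item_id) |>
    dplyr::mutate(
      flag_pb = !is_strictly_increasing(.data$pb),
      flag_theta = !is_strictly_increasing(.data$mean_theta),
      flag_empty = .data$n == 0L
    ) |>
    dplyr::ungroup()
}

# strict monotonicity over the non-missing part of a sequence; a
# sequence with fewer than 2 defined values is trivially ordered
is_strictly_increasing <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(TRUE)
  all(diff(x) > 0)
}

#' Flag persons for extreme scores and response misfit
#'
#' `EXTREME` marks zero and perfect raw scores.  Misfit uses the person
#' outfit mean square: the mean squared standardized residual
#' `(x - E[X|theta])^2 / Var(X|theta)` over administered items.  Values
#' below `person_fit_bounds[1]` (responses more deterministic than the
#' model expects, e.g. a Guttman pattern) flag `MISFIT_LOW`; values
#' above `person_fit_bounds[2]` (erratic responding) flag `MISFIT_HIGH`.
#'
#' @param abilities Tibble from [estimate_abilities()].
#' @param data A [response_matrix()] (or coercible).
#' @param items Item calibration tibble.
#' @param config A [flag_config()].
#' @return Tibble: `person_id`, `raw_score`, `theta`, `outfit`, `flags`
#'   (comma-separated string, `""` when clean).
#' @export
flag_persons <- function(abilities, data, items, config = flag_config()) {
  rm <- as_response_matrix(data)
  steps <- calib_steps(items)
  use <- intersect(rm$item_ids, names(steps))
  Yc <- recode_scores(rm, steps[use])
  th <- abilities$theta[match(rm$person_ids, abilities$person_id)]
  outfit <- rep(NA_real_, length(th))
  for (p in seq_along(th)) {
    if (!is.finite(th[p])) next
    z2 <- c()
    for (id in use) {
      yv <- Yc[p, id]
      if (is.na(yv)) next
      mo <- pcm_moments(th[p], steps[[id]])
      if (mo$var < 1e-10) next
      z2 <- c(z2, (yv - mo$mean)^2 / mo$var)
    }
    if (length(z2)) outfit[p] <- mean(z2)
  }
  flags <- purrr::map2_chr(seq_along(th), outfit, function(p, o) {
    f <- character()
    if (isTRUE(abilities$extreme[p])) f <- c(f, "EXTREME")
    if (is.finite(o) && o < config$person_fit_bounds[1]) f <- c(f, "MISFIT_LOW")
    if (is.finite(o) && o > config$person_fit_bounds[2]) f <- c(f, "MISFIT_HIGH")
    paste(f, collapse = ",")
  })
  tibble::tibble(person_id = abilities$person_id, raw_score = abilities$raw_score,
                 theta = abilities$theta, outfit = outfit, flags = flags)
}

#' Developmental (zone of proximal development) report
#'
#' For each person, lists the item-category thresholds lying within
#' `window` logits of the person's ability — the items on which the
#' person's odds of success are near 50:50 and which are therefore
#' candidates for instruction with support.  An optional descriptor
#' table (columns `label`, `skill`, and optionally more) is joined by
#' threshold label; absent descriptors yield blank skill columns.
#'
#' @param thresholds Tibble from [thurstonian_thresholds()].
#' @param abilities Tibble from [estimate_abilities()].
#' @param descriptors Optional data frame with a `label` column.
#' @param window Half-width of the ability window in logits (>= 0).
#' @return Tibble: `person_id`, `theta`, `label`, `gamma`, `distance`,
#'   plus descriptor columns.
#' @export
developmental_join <- function(thresholds, abilities, descriptors = NULL, window = 0.5) {
  stopifnot(window >= 0)
  out <- abilities |>
    dplyr::filter(is.finite(.data$theta)) |>
    dplyr::select("person_id", "theta") |>
    dplyr::cross_join(dplyr::select(thresholds, "label", "gamma")) |>
    dplyr::mutate(distance = abs(.data$gamma - .data$theta)) |>
    dplyr::filter(.data$distance <= window) |>
    dplyr::arrange(.data$person_id, .data$distance)
  if (!is.null(descriptors)) {
    stopifnot("label" %in% names(descriptors))
    out <- dplyr::left_join(out, tibble::as_tibble(descriptors), by = "label")
  } else {
    out$skill <- ""
  }
  out
}
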