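#' Item-rest correlation with Fisher-z confidence interval
#'
#' Pearson correlation between the item score and the rest score (test
#' total minus the focal item), computed over pairwise-complete
#' responses.  The confidence interval uses the Fisher z transform with
#' standard error `1/sqrt(n - 3)`.
#'
#' @param data A [response_matrix()] (or coercible).
#' @param item Item label.
#' @param ci_level Confidence level in (0, 1).
#' @return List: `r`, `ci_low`, `ci_high`, `n` (complete pairs).  A
#'   zero-variance item yields `NA` statistics (flagged downstream, not
#'   an error).
#' @export
item_rest_correlation <- function(data, item, ci_level = 0.95) {
  rm <- as_response_matrix(data)
  stopifnot(item %in% rm$item_ids)
  x <- rm$scores[, item]
  rest <- rowSums(rm$scores[, setdiff(rm$item_ids, item), drop = FALSE], na.rm = TRUE)
  rest[rowSums(!is.na(rm$scores[, setdiff(rm$item_ids, item), drop = FALSE])) == 0L] <- NA
  ok <- !is.na(x) & !is.na(rest)
  n <- sum(ok)
  if (n < 3L || stats::sd(x[ok]) == 0 || stats::sd(rest[ok]) == 0) {
    return(list(r = NA_real_, ci_low = NA_real_, ci_high = NA_real_, n = n))
  }
  r <- cor(x[ok], rest[ok])
  z <- atanh(r)
  zc <- qnorm(1 - (1 - ci_level) / 2) / sqrt(n - 3)
  list(r = r, ci_low = tanh(z - zc), ci_high = tanh(z + zc), n = n)
}

#' Attenuation-corrected (biserial / polyserial) correlation
#'
#' Corrects the item-rest correlation for the coarseness of the item's
#' response scale.  Dichotomous items use the biserial correction
#' `r_b = r_pb * sqrt(p(1-p)) / phi(z_p)`; polytomous items use the
#' two-step polyserial approximation
#' `r_ps = r * sd(x) / sum_k phi(tau_k)` with thresholds `tau_k` from
#' the cumulative category proportions (which reduces to the biserial
#' form when there are two categories).  Results are clamped to
#' `[-1, 1]`.
#'
#' @inheritParams item_rest_correlation
#' @return Corrected correlation (scalar; `NA` when undefined, e.g. all
#'   responses in one category).
#' @export
corrected_correlation <- function(data, item) {
  rm <- as_response_matrix(data)
  stopifnot(item %in% rm$item_ids)
  x <- rm$scores[, item]
  rest <- rowSums(rm$scores[, setdiff(rm$item_ids, item), drop = FALSE], na.rm = TRUE)
  ok <- !is.na(x)
  x <- x[ok]; rest <- rest[ok]
  if (length(unique(x)) < 2L || stats::sd(rest) == 0) return(NA_real_)
  r <- cor(x, rest)
  n <- length(x)
  props <- table(factor(x, levels = sort(unique(x)))) / n
  cum <- cumsum(props)
  tau <- qnorm(cum[-length(cum)])          # thresholds between categories
  denom <- sum(dnorm(tau))
  sx <- sqrt(mean((x - mean(x))^2))        # population SD (consistent with props)
  out <- r * sx / denom
  max(-1, min(1, out))
}

#' Cronbach's alpha with qualitative band
#'
#' Internal-consistency reliability
#' `alpha = k/(k-1) * (1 - sum(var_i) / var_total)` over complete cases,
#' banded as poor (< 0.6 from 0.5), questionable, acceptable, good, and
#' excellent at cutoffs 0.50 / 0.60 / 0.70 / 0.80 / 0.90.
#'
#' @param data A [response_matrix()] (or coercible).
#' @return List: `alpha`, `band`, `n_items`, `n_persons` (complete
#'   cases).  Zero total variance yields `NA` alpha.
#' @export
cronbach_alpha <- function(data) {
  rm <- as_response_matrix(data)
  Y <- rm$scores[complete.cases(rm$scores), , drop = FALSE]
  k <- ncol(Y)
  stopifnot(k >= 2L)
  tot <- rowSums(Y)
  vt <- var_pop_n1(tot)
  a <- if (is.na(vt) || vt == 0) NA_real_ else (k / (k - 1)) * (1 - sum(apply(Y, 2L, var)) / vt)
  list(alpha = a, band = alpha_band(a), n_items = k, n_persons = nrow(Y))
}

var_pop_n1 <- function(x) if (length(x) < 2L) NA_real_ else var(x)

alpha_band <- function(a) {
  if (is.na(a)) return(NA_character_)
  bands <- c("poor", "questionable", "acceptable", "good", "excellent")
  bands[max(1L, findInterval(a, c(0.6, 0.7, 0.8, 0.9)) + 1L)]
}

#' Alpha if item deleted
#'
#' For each item, Cronbach's alpha of the remaining items; items whose
#' deletion *raises* alpha above the full-scale value are flagged
#' `ALPHA_GAIN`.
#'
#' @param data A [response_matrix()] (or coercible; >= 3 items).
#' @return Tibble: `item_id`, `alpha_if_deleted`, `alpha_gain`.
#' @export
alpha_if_deleted <- function(data) {
  rm <- as_response_matrix(data)
  stopifnot(length(rm$item_ids) >= 3L)
  full <- cronbach_alpha(rm)$alpha
  rows <- purrr::map_dfr(rm$item_ids, function(id) {
    sub <- rm$scores[, setdiff(rm$item_ids, id), drop = FALSE]
    a <- cronbach_alpha(new_response_matrix(sub, rm$person_ids,
                                            setdiff(rm$item_ids, id)))$alpha
    tibble::tibble(item_id = id, alpha_if_deleted = a)
  })
  rows$alpha_gain <- !is.na(rows$alpha_if_deleted) & !is.na(full) &
    rows$alpha_if_deleted > full
  rows
}

#' Classical item statistics with flags
#'
#' One row per item: item-rest correlation with its Fisher-z CI, the
#' attenuation-corrected (bi-/polyserial) correlation, alpha if the item
#' is deleted, and the flag set.  Flags (unions, never exclusive):
#' `LOW_R` for `r` strictly below `min_item_rest_r`; `NEGATIVE_R` for
#' `r < 0`; `CI_BELOW_ZERO` when the lower CI bound is below 0 (if
#' enabled); `ALPHA_GAIN` when deletion raises alpha (if enabled);
#' `ZERO_VARIANCE` for degenerate items.
#'
#' @param data A [response_matrix()] (or coercible).
#' @param config A [flag_config()].
#' @return Tibble: `item_id`, `n`, `item_rest_r`, `ci_low`, `ci_high`,
#'   `corrected_r`, `alpha_if_deleted`, `flags` (comma-separated).
#' @examples
#' sim <- sim_responses(sim_design(n_items = 8, n_persons = 300, seed = 3))
#' ctt_item_stats(sim$responses)
#' @export
ctt_item_stats <- function(data, config = flag_config()) {
  rm <- as_response_matrix(data)
  aid <- if (length(rm$item_ids) >= 3L) alpha_if_deleted(rm) else
    tibble::tibble(item_id = rm$item_ids, alpha_if_deleted = NA_real_, alpha_gain = FALSE)
  rows <- purrr::map_dfr(rm$item_ids, function(id) {
    irc <- item_rest_correlation(rm, id, config$ci_level)
    tibble::tibble(item_id = id, n = irc$n, item_rest_r = irc$r,
                   ci_low = irc$ci_low, ci_high = irc$ci_high,
                   corrected_r = corrected_correlation(rm, id))
  })
  rows <- dplyr::left_join(rows, aid, by = "item_id")
  rows$flags <- purrr::pmap_chr(rows, function(item_id, n, item_rest_r, ci_low,
                                              ci_high, corrected_r,
                                              alpha_if_deleted, alpha_gain, ...) {
    f <- character()
    zv <- rm$zero_variance[[item_id]]
    if (isTRUE(zv)) f <- c(f, "ZERO_VARIANCE")
    if (!is.na(item_rest_r)) {
      if (item_rest_r < config$min_item_rest_r) f <- c(f, "LOW_R")
      if (item_rest_r < 0) f <- c(f, "NEGATIVE_R")
      if (config$flag_negative_ci && !is.na(ci_low) && ci_low < 0) f <- c(f, "CI_BELOW_ZERO")
    }
    if (config$alpha_gain_flag && isTRUE(alpha_gain)) f <- c(f, "ALPHA_GAIN")
    paste(f, collapse = ",")
  })
  dplyr::select(rows, -"alpha_gain")
}
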