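#' Align link-item difficulties across two calibrations
#'
#' Link items are matched by exact (case-sensitive) label between the
#' two calibrations; Form B difficulties are then shifted by the single
#' constant that equates the mean link difficulty with Form A, which
#' enforces the identity `sum(delta_A - delta_B_aligned) = 0`.  A pure
#' origin shift between forms is absorbed entirely by the alignment.
#' Item location is the mean of its step difficulties.
#'
#' @param calA,calB Item calibration tibbles (`item_id`, `step`,
#'   `delta`, `se`) from two independent fits.
#' @return Tibble, one row per link item: `item_id`, `delta_A`, `se_A`,
#'   `delta_B` (aligned), `se_B`, `difference`, and the alignment
#'   `shift` as an attribute.
#' @export
align_link_items <- function(calA, calB) {
  locA <- item_locations(calA)
  locB <- item_locations(calB)
  link <- intersect(locA$item_id, locB$item_id)
  if (length(link) < 2L) abort("fewer than 2 common item labels; equating undefined")
  a <- locA[match(link, locA$item_id), ]
  b <- locB[match(link, locB$item_id), ]
  shift <- mean(a$delta) - mean(b$delta)
  out <- tibble::tibble(item_id = link,
                        delta_A = a$delta, se_A = a$se,
                        delta_B = b$delta + shift, se_B = b$se)
  out$difference <- out$delta_A - out$delta_B
  attr(out, "shift") <- shift
  out
}

# item location = mean step difficulty; SE combined across steps
item_locations <- function(cal) {
  cal |>
    dplyr::group_by(.data$item_id) |>
    dplyr::summarise(delta = mean(.data$delta),
                     se = sqrt(sum(.data$se^2)) / dplyr::n(),
                     .groups = "drop")
}

#' Standardized link-item difficulty differences
#'
#' The invariance statistic
#' `z_i = (delta_A - delta_B) / sqrt(se_A^2 + se_B^2)` computed on the
#' aligned differences; positive `z` means the item was harder in Form A
#' after alignment.  Items with `|z|` beyond `bound` are flagged as
#' potentially non-invariant (reported, never auto-dropped).
#'
#' @param comparisons Tibble from [align_link_items()].
#' @param bound Flagging bound on `|z|` (default 1.96).
#' @return The input with `z` and `noninvariant` columns.
#' @export
invariance_z <- function(comparisons, bound = 1.96) {
  pooled <- sqrt(comparisons$se_A^2 + comparisons$se_B^2)
  z <- ifelse(pooled > 0, comparisons$difference / pooled, NA_real_)
  dplyr::mutate(comparisons, z = z, noninvariant = !is.na(z) & abs(z) > bound)
}

#' Equating error from link-item disagreement
#'
#' `epsilon = sqrt( sum(d_i^2) / (L - 1) ) / sqrt(L)` over the aligned
#' link differences `d_i`: the standard error of the equating constant.
#' Zero exactly when all aligned differences are zero.
#'
#' @param comparisons Tibble from [align_link_items()] (needs >= 2
#'   rows).
#' @return Equating error in logits (scalar, >= 0).
#' @export
equating_error <- function(comparisons) {
  d <- comparisons$difference
  L <- length(d)
  stopifnot(L >= 2L)
  sqrt(sum(d^2) / (L - 1)) / sqrt(L)
}

#' Fixed-anchor calibration of a second test form
#'
#' Re-fits Form B by MML with the link items' step difficulties *fixed*
#' at their Form A values, so Form B persons and its non-link items are
#' expressed directly on the Form A scale; the Form B latent mean and
#' SD are estimated freely (no centering constraint — identification
#' comes from the anchors).  Invariance diagnostics (aligned
#' differences, z statistics, equating error) come from the two
#' *independent* calibrations; the fixed-anchor refit provides the
#' reported scale.
#'
#' @param formB A [response_matrix()] for Form B (must contain every
#'   anchor label).
#' @param anchor Item calibration tibble from the Form A fit, subset to
#'   the link items (any non-link rows are ignored if absent from Form
#'   B).
#' @param config A [fit_config()].
#' @return An `equating_fit`: `items` (all Form B items on the Form A
#'   scale; anchor rows bit-equal to the input), `abilities` (Form B
#'   persons on the Form A scale), `latent`, `deviance`, `converged`,
#'   `anchor_items` (labels).
#' @export
fixed_anchor_calibrate <- function(formB, anchor, config = fit_config()) {
  rm <- as_response_matrix(formB)
  anchor_ids <- intersect(unique(anchor$item_id), rm$item_ids)
  missing <- setdiff(unique(anchor$item_id), rm$item_ids)
  if (length(anchor_ids) < 2L) {
    abort(paste0("anchor labels missing from Form B: ", paste(missing, collapse = ", ")))
  }
  prep <- prep_items(rm)
  fixed <- calib_steps(anchor[anchor$item_id %in% anchor_ids, ])
  em <- mml_em(prep, config, fixed_delta = fixed, free_latent_mean = TRUE)
  items <- calibration_tibble(prep, em$delta, constraint = "anchored")
  ab <- estimate_abilities(rm, items, estimator = "MLE")
  items2 <- item_standard_errors(rm, items, ab)
  # anchors stay bit-equal to their input values (SEs from Form A input)
  for (id in anchor_ids) {
    rows <- which(items2$item_id == id)
    arow <- which(anchor$item_id == id)
    items2$delta[rows] <- anchor$delta[arow]
    if ("se" %in% names(anchor)) items2$se[rows] <- anchor$se[arow]
  }
  structure(
    list(items = items2, abilities = ab, latent = em$latent,
         deviance = em$deviance, converged = em$converged,
         anchor_items = anchor_ids, config = config, data = rm),
    class = "equating_fit"
  )
}

#' Full two-form fixed-anchor equating
#'
#' Runs the complete procedure on two calibrated forms: label-matched
#' link alignment, invariance z statistics, the equating error, the
#' fixed-anchor refit of Form B, and a binned density comparison of the
#' Form A and equated Form B ability distributions.
#'
#' @param calA Form A item calibration tibble.
#' @param formB Form B [response_matrix()].
#' @param calB Form B independent calibration tibble (for invariance
#'   diagnostics).
#' @param abilitiesA Optional Form A abilities tibble for the density
#'   comparison.
#' @param config A [fit_config()].
#' @param binwidth Density bin width in logits.
#' @return An `equating_result`: `comparisons` (with `z`), `epsilon`,
#'   `L`, `fit` (the `equating_fit`), `density` (tibble `form`,
#'   `bin_mid`, `count`).
#' @export
equate_forms <- function(calA, formB, calB, abilitiesA = NULL,
                         config = fit_config(), binwidth = 0.25) {
  comp <- align_link_items(calA, calB)
  comp <- invariance_z(comp)
  eps <- equating_error(comp)
  anchor <- calA[calA$item_id %in% comp$item_id, ]
  fit <- fixed_anchor_calibrate(formB, anchor, config)
  dens <- NULL
  thB <- fit$abilities$theta[is.finite(fit$abilities$theta)]
  if (!is.null(abilitiesA)) {
    thA <- abilitiesA$theta[is.finite(abilitiesA$theta)]
    all_th <- c(thA, thB)
    breaks <- seq(floor(min(all_th) / binwidth) * binwidth,
                  ceiling(max(all_th) / binwidth) * binwidth + binwidth, by = binwidth)
    mk <- function(th, nm) tibble::tibble(
      form = nm,
      bin_mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
      count = tabulate(findInterval(th, breaks, rightmost.closed = TRUE),
                       nbins = length(breaks) - 1L))
    dens <- dplyr::bind_rows(mk(thA, "Form A"), mk(thB, "Form B (equated)"))
  }
  structure(
    list(comparisons = comp, epsilon = eps, L = nrow(comp),
         fit = fit, density = dens),
    class = "equating_result"
  )
}

#' @export
print.equating_result <- function(x, ...) {
  cat("<equating_result> ", x$L, " link items; equating error ",
      format(round(x$epsilon, 4)), " logits\n", sep = "")
  ni <- sum(x$comparisons$noninvariant)
  if (ni > 0) cat("  ", ni, " link item(s) flagged non-invariant (|z| > 1.96)\n", sep = "")
  invisible(x)
}
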