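#' Estimation controls for the marginal maximum likelihood fit
#'
#' Mirrors the user-facing model controls: the identification
#' constraint, convergence criteria, iteration cap, quadrature size, and
#' the logistic/probit scaling constant used for display.
#'
#' @param constraint `"cases"` fixes the latent ability mean at 0 and
#'   leaves item difficulties free; `"items"` fixes the grand mean of
#'   all step difficulties at 0 and estimates the ability mean.
#' @param convergence_tol Positive tolerance applied both to the change
#'   in deviance and to the largest parameter change between EM cycles.
#' @param max_iterations Iteration cap; hitting it returns a
#'   non-converged fit with a warning record rather than an error.
#' @param n_quadrature Number of quadrature nodes (>= 5) spanning +/- 5
#'   population SDs.
#' @param scaling_D Scaling constant for converting the logit metric to
#'   the probit-matched metric on display; estimation always runs at
#'   D = 1.  The classical probit-matching value is 1.702.
#' @param seed Integer seed recorded with the fit.
#' @return A `fit_config` list.
#' @export
fit_config <- function(constraint = c("cases", "items"),
                       convergence_tol = 1e-4,
                       max_iterations = 500L,
                       n_quadrature = 21L,
                       scaling_D = 1,
                       seed = 1L) {
  constraint <- match.arg(constraint)
  stopifnot(convergence_tol > 0, max_iterations >= 1, n_quadrature >= 5, scaling_D > 0)
  structure(list(constraint = constraint, convergence_tol = convergence_tol,
                 max_iterations = as.integer(max_iterations),
                 n_quadrature = as.integer(n_quadrature),
                 scaling_D = scaling_D, seed = as.integer(seed)),
            class = "fit_config")
}

#' Flagging thresholds for items and persons
#'
#' The customizable flagging system: items are flagged for small
#' item-rest correlations (`LOW_R`, strict `<`), lower confidence bounds
#' below zero (`CI_BELOW_ZERO`), negative correlations (`NEGATIVE_R`),
#' and reliability gains on deletion (`ALPHA_GAIN`); persons for extreme
#' raw scores and outfit mean squares outside `person_fit_bounds`.
#'
#' @param min_item_rest_r Item-rest correlations strictly below this are
#'   flagged `LOW_R` (default 0.10).
#' @param ci_level Confidence level for correlation intervals.
#' @param flag_negative_ci Flag items whose lower CI bound is below 0.
#' @param alpha_gain_flag Flag items whose deletion raises alpha.
#' @param person_fit_bounds Length-2 `(low, high)` outfit mean-square
#'   bounds for person misfit flags.
#' @param dif_alpha Two-sided significance level for DIF z-tests.
#' @param dif_practical_logits Between-group difficulty gap (logits)
#'   deemed practically significant.
#' @return A `flag_config` list.
#' @export
flag_config <- function(min_item_rest_r = 0.10, ci_level = 0.95,
                        flag_negative_ci = TRUE, alpha_gain_flag = TRUE,
                        person_fit_bounds = c(0.7, 1.3),
                        dif_alpha = 0.05, dif_practical_logits = 0.5) {
  stopifnot(ci_level > 0, ci_level < 1,
            length(person_fit_bounds) == 2L,
            person_fit_bounds[1] < person_fit_bounds[2],
            dif_alpha > 0, dif_alpha < 1, dif_practical_logits > 0)
  structure(list(min_item_rest_r = min_item_rest_r, ci_level = ci_level,
                 flag_negative_ci = flag_negative_ci, alpha_gain_flag = alpha_gain_flag,
                 person_fit_bounds = person_fit_bounds,
                 dif_alpha = dif_alpha, dif_practical_logits = dif_practical_logits),
            class = "flag_config")
}
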