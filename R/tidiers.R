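#' Tidy an MML Rasch fit into its item table
#'
#' @param x A `rasch_fit`.
#' @param ... Unused.
#' @return Tibble: `item_id`, `step`, `delta`, `se`.
#' @method tidy rasch_fit
#' @export
tidy.rasch_fit <- function(x, ...) tibble::as_tibble(x$items)

#' One-row fit summary
#'
#' @param x A `rasch_fit`.
#' @param ... Unused.
#' @return Tibble with deviance, iterations, convergence, latent
#'   moments, and problem size.
#' @method glance rasch_fit
#' @export
glance.rasch_fit <- function(x, ...) {
  tibble::tibble(deviance = x$deviance, n_iterations = x$n_iterations,
                 converged = x$converged, latent_mean = x$latent$mean,
                 latent_sd = x$latent$sd, n_persons = nrow(x$data$scores),
                 n_items = length(unique(x$items$item_id)),
                 constraint = x$config$constraint)
}

#' @rdname tidy.rasch_fit
#' @method tidy facets_fit
#' @export
tidy.facets_fit <- function(x, ...) tibble::as_tibble(x$effects)

#' @rdname glance.rasch_fit
#' @method glance facets_fit
#' @export
glance.facets_fit <- function(x, ...) {
  tibble::tibble(deviance = x$deviance, n_iterations = x$n_iterations,
                 converged = x$converged,
                 n_groups = length(unique(x$effects$group)),
                 n_items = length(unique(x$effects$item_id)))
}

#' Tidy an equating result into its link-item comparison table
#'
#' @param x An `equating_result`.
#' @param ... Unused.
#' @method tidy equating_result
#' @export
tidy.equating_result <- function(x, ...) tibble::as_tibble(x$comparisons)

#' @rdname tidy.equating_result
#' @method glance equating_result
#' @export
glance.equating_result <- function(x, ...) {
  tibble::tibble(epsilon = x$epsilon, L = x$L,
                 n_noninvariant = sum(x$comparisons$noninvariant),
                 converged = x$fit$converged)
}

#' Tidy a one-way ANOVA of ability
#'
#' @param x An `anova_result`.
#' @param ... Unused.
#' @return The Tukey pairwise table (one row per contrast).
#' @method tidy anova_result
#' @export
tidy.anova_result <- function(x, ...) tibble::as_tibble(x$tukey)

#' @rdname tidy.anova_result
#' @method glance anova_result
#' @export
glance.anova_result <- function(x, ...) {
  dplyr::bind_cols(x$table,
                   tibble::tibble(shapiro_W = x$shapiro$W, shapiro_p = x$shapiro$p,
                                  n = x$n, n_groups = length(x$groups)))
}

#' Tidy an intraclass correlation result
#'
#' @param x An `icc_result`.
#' @param ... Unused.
#' @method tidy icc_result
#' @export
tidy.icc_result <- function(x, ...) {
  tibble::tibble(model = x$model, type = x$type, unit = x$unit,
                 icc = x$icc, ci_low = x$ci[1], ci_high = x$ci[2],
                 ci_level = x$ci_level, F = x$F, df1 = x$df1, df2 = x$df2,
                 n_subjects = x$n_subjects, n_raters = x$n_raters)
}

#' Wright map: person histogram with item-category thresholds
#'
#' @param object A `rasch_fit` or `rasch_analysis`.
#' @param binwidth Histogram bin width in logits.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rasch_fit
#' @export
autoplot.rasch_fit <- function(object, binwidth = 0.25, ...) {
  ab <- object$abilities
  thr <- thurstonian_thresholds(object$items)
  wm <- wright_map_data(ab, thr, binwidth)
  ggplot2::ggplot() +
    ggplot2::geom_col(data = wm$persons,
                      ggplot2::aes(x = .data$bin_mid, y = .data$count),
                      width = binwidth, fill = "grey60") +
    ggplot2::geom_point(data = thr,
                        ggplot2::aes(x = .data$gamma, y = -max(wm$persons$count) / 20),
                        shape = 17) +
    ggplot2::geom_text(data = thr,
                       ggplot2::aes(x = .data$gamma, y = -max(wm$persons$count) / 8,
                                    label = .data$label),
                       angle = 90, size = 2.2, hjust = 1) +
    ggplot2::labs(x = "Ability / difficulty (logits)", y = "Persons",
                  title = "Wright map") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.rasch_fit
#' @method autoplot rasch_analysis
#' @export
autoplot.rasch_analysis <- function(object, binwidth = 0.25, ...) {
  autoplot(object$fit, binwidth = binwidth, ...)
}

#' Test information and standard error curve
#'
#' @param fit A `rasch_fit`.
#' @param theta_grid Ability grid.
#' @return A ggplot object with information and se panels.
#' @export
plot_test_information <- function(fit, theta_grid = seq(-4, 4, by = 0.1)) {
  ti <- test_information_curve(fit$items, theta_grid)
  long <- tidyr::pivot_longer(ti, c("information", "se"),
                              names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$theta, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "Ability (logits)", y = NULL,
                  title = "Test information and conditional standard error") +
    ggplot2::theme_minimal()
}

#' Equated ability density comparison
#'
#' @param object An `equating_result` built with Form A abilities.
#' @param ... Unused.
#' @method autoplot equating_result
#' @export
autoplot.equating_result <- function(object, ...) {
  if (is.null(object$density)) abort("density comparison needs Form A abilities (see equate_forms)")
  ggplot2::ggplot(object$density,
                  ggplot2::aes(x = .data$bin_mid, y = .data$count, fill = .data$form)) +
    ggplot2::geom_col(position = "identity", alpha = 0.5) +
    ggplot2::labs(x = "Ability on the Form A scale (logits)", y = "Persons",
                  title = "Equated ability distributions") +
    ggplot2::theme_minimal()
}

#' Ability by group boxplot
#'
#' @param object An `anova_result`.
#' @param ... Unused.
#' @method autoplot anova_result
#' @export
autoplot.anova_result <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$group, y = .data$theta)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "Group", y = "Ability (logits)", title = "Ability by group") +
    ggplot2::theme_minimal()
}
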