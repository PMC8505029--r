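#' One-way ANOVA of person ability on a grouping factor
#'
#' Classical fixed-effects one-way ANOVA of ability (theta) on group,
#' with a Shapiro-Wilk normality check on the residuals (reported,
#' never used to gate the test), estimated marginal means with
#' t-based confidence intervals, and Tukey HSD pairwise comparisons via
#' the studentized range distribution.  With exactly two groups the
#' Tukey-adjusted p equals the pooled two-sample t-test p
#' (`q = sqrt(2) t`).
#'
#' @param data Data frame with columns `theta` (numeric) and `group`
#'   (factor/character), e.g. the persons table of a fit joined
#'   positionally to a grouping table.
#' @param conf_level Confidence level for means and Tukey intervals.
#' @return An `anova_result`: `table` (F, dfs, p, eta_squared),
#'   `shapiro` (W, p), `means` (emmeans tibble), `tukey` (pairwise
#'   tibble: `contrast`, `diff`, `lwr`, `upr`, `p_adj`), `n`, `groups`.
#' @examples
#' df <- data.frame(theta = rnorm(60), group = rep(c("a", "b", "c"), 20))
#' oneway_anova(df)$table
#' @export
oneway_anova <- function(data, conf_level = 0.95) {
  stopifnot(all(c("theta", "group") %in% names(data)))
  df <- tibble::tibble(theta = as.numeric(data$theta),
                       group = factor(data$group))
  df <- df[is.finite(df$theta), ]
  sizes <- table(df$group)
  if (length(sizes) < 2L) abort("at least 2 groups required")
  if (any(sizes < 2L)) {
    abort(paste0("group(s) with fewer than 2 observations: ",
                 paste(names(sizes)[sizes < 2L], collapse = ", ")))
  }
  fit <- aov(theta ~ group, data = df)
  an <- summary(fit)[[1L]]
  ss <- an[["Sum Sq"]]
  table <- tibble::tibble(
    F = an[["F value"]][1L],
    df_between = an[["Df"]][1L], df_within = an[["Df"]][2L],
    p_value = an[["Pr(>F)"]][1L],
    eta_squared = ss[1L] / sum(ss)
  )
  res <- residuals(fit)
  sh <- if (length(res) >= 3 && length(res) <= 5000) shapiro.test(res) else
    list(statistic = NA_real_, p.value = NA_real_)
  em <- emmeans::emmeans(fit, "group", level = conf_level)
  means <- tibble::as_tibble(as.data.frame(em))
  tk <- TukeyHSD(fit, conf.level = conf_level)$group
  tukey <- tibble::tibble(contrast = rownames(tk),
                          diff = tk[, "diff"], lwr = tk[, "lwr"],
                          upr = tk[, "upr"], p_adj = tk[, "p adj"])
  structure(
    list(table = table,
         shapiro = list(W = unname(sh$statistic), p = sh$p.value),
         means = means, tukey = tukey,
         n = nrow(df), groups = names(sizes), data = df),
    class = "anova_result"
  )
}

#' @export
print.anova_result <- function(x, ...) {
  cat("<anova_result> F(", x$table$df_between, ", ", x$table$df_within, ") = ",
      round(x$table$F, 3), ", p = ", format.pval(x$table$p_value, digits = 3),
      ", eta^2 = ", round(x$table$eta_squared, 3), "\n", sep = "")
  invisible(x)
}

#' Join a persons table to a grouping table positionally
#'
#' The grouping file carries one row per participant in the same order
#' as the persons table; the join is positional with a strict length
#' check.
#'
#' @param persons Tibble with `theta` (e.g. from
#'   [estimate_abilities()]).
#' @param grouping Data frame of grouping variables, same row count.
#' @param variable Name of the grouping column to use (default: first).
#' @return Data frame ready for [oneway_anova()].
#' @export
join_grouping <- function(persons, grouping, variable = names(grouping)[1L]) {
  if (nrow(persons) != nrow(grouping)) {
    abort(paste0("persons (", nrow(persons), ") and grouping (", nrow(grouping),
                 ") tables differ in length; the join is positional"))
  }
  tibble::tibble(theta = persons$theta, group = grouping[[variable]])
}

#' Intraclass correlation for inter-rater reliability
#'
#' Shrout-Fleiss / McGraw-Wong estimators from the one- or two-way
#' ANOVA mean squares of a complete subject-by-rater table, with
#' F-based confidence limits.  `model` selects the design (raters as a
#' random sample crossed with subjects, a fixed panel, or nested
#' one-way), `type` whether rater mean differences count against
#' agreement, and `unit` whether the reliability of a single rater or
#' of the k-rater average is reported.  One-way models support
#' agreement only; average-unit ICCs never fall below their single-unit
#' counterparts.
#'
#' @param ratings Data frame or matrix, rows = subjects, columns =
#'   raters (a `subject` id column is dropped); complete cases
#'   required.
#' @param model `"oneway"`, `"twoway_random"`, or `"twoway_mixed"`.
#' @param type `"agreement"` or `"consistency"`.
#' @param unit `"single"` or `"average"`.
#' @param ci_level Confidence level.
#' @return An `icc_result`: `icc`, `ci` (low, high), `model`, `type`,
#'   `unit`, `F`, `df1`, `df2`, `n_subjects`, `n_raters`, `ms` (mean
#'   squares).
#' @examples
#' tab <- sim_rater_table(30, 3, true_icc = 0.7, seed = 2)
#' icc(tab, model = "oneway")$icc
#' @export
icc <- function(ratings, model = c("twoway_random", "twoway_mixed", "oneway"),
                type = c("agreement", "consistency"),
                unit = c("single", "average"), ci_level = 0.95) {
  model <- match.arg(model); type <- match.arg(type); unit <- match.arg(unit)
  x <- ratings
  if (is.data.frame(x) && "subject" %in% names(x)) x <- x[setdiff(names(x), "subject")]
  x <- as.matrix(x)
  if (anyNA(x)) abort("missing cells: the ICC requires a complete subject-by-rater table")
  n <- nrow(x); k <- ncol(x)
  stopifnot(n >= 5L, k >= 2L)
  if (model == "oneway" && type == "consistency") {
    abort("the one-way model supports agreement only")
  }

  # ANOVA mean squares of the subject x rater layout
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  SSR <- k * sum((row_m - grand)^2)            # subjects
  SSC <- n * sum((col_m - grand)^2)            # raters
  SST <- sum((x - grand)^2)
  SSE <- SST - SSR - SSC                       # residual (two-way)
  SSW <- SST - SSR                             # within subjects (one-way)
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  MSW <- SSW / (n * (k - 1))

  alpha <- 1 - ci_level
  if (model == "oneway") {
    est_s <- (MSR - MSW) / (MSR + (k - 1) * MSW)
    Fv <- MSR / MSW; df1 <- n - 1; df2 <- n * (k - 1)
    FL <- Fv / qf(1 - alpha / 2, df1, df2)
    FU <- Fv * qf(1 - alpha / 2, df2, df1)
    if (unit == "single") {
      est <- est_s
      ci <- c((FL - 1) / (FL + k - 1), (FU - 1) / (FU + k - 1))
    } else {
      est <- (MSR - MSW) / MSR
      ci <- c(1 - 1 / FL, 1 - 1 / FU)
    }
  } else if (type == "consistency") {
    Fv <- MSR / MSE; df1 <- n - 1; df2 <- (n - 1) * (k - 1)
    FL <- Fv / qf(1 - alpha / 2, df1, df2)
    FU <- Fv * qf(1 - alpha / 2, df2, df1)
    if (unit == "single") {
      est <- (MSR - MSE) / (MSR + (k - 1) * MSE)
      ci <- c((FL - 1) / (FL + k - 1), (FU - 1) / (FU + k - 1))
    } else {
      est <- (MSR - MSE) / MSR
      ci <- c(1 - 1 / FL, 1 - 1 / FU)
    }
  } else {
    # two-way agreement (absolute): rater variance counts against reliability
    if (unit == "single") {
      est <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
    } else {
      est <- (MSR - MSE) / (MSR + (MSC - MSE) / n)
    }
    # McGraw & Wong Satterthwaite CI
    a <- k * est / (n * (1 - est)); b <- 1 + k * est * (n - 1) / (n * (1 - est))
    v <- (a * MSC + b * MSE)^2 /
      ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
    FL <- qf(1 - alpha / 2, n - 1, v)
    FU <- qf(1 - alpha / 2, v, n - 1)
    lo <- n * (MSR - FL * MSE) / (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
    hi <- n * (FU * MSR - MSE) / (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
    if (unit == "average") {
      lo <- lo * k / (1 + (k - 1) * lo)
      hi <- hi * k / (1 + (k - 1) * hi)
    }
    ci <- c(lo, hi)
    Fv <- MSR / MSE; df1 <- n - 1; df2 <- (n - 1) * (k - 1)
  }
  structure(
    list(icc = est, ci = ci, model = model, type = type, unit = unit,
         ci_level = ci_level, F = Fv, df1 = df1, df2 = df2,
         n_subjects = n, n_raters = k,
         ms = list(MSR = MSR, MSC = MSC, MSE = MSE, MSW = MSW)),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  cat("<icc_result> ", x$model, "/", x$type, "/", x$unit, ": ICC = ",
      round(x$icc, 3), " [", round(x$ci[1], 3), ", ", round(x$ci[2], 3), "] (",
      x$ci_level * 100, "% CI)\n", sep = "")
  invisible(x)
}
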