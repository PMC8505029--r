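test_that("response-function anchors hold exactly", {
  expect_equal(irf_dichotomous(0.7, 0.7), 0.5)
  expect_equal(irf_dichotomous(-2, -2, D = 1.702), 0.5)
  expect_equal(irf_dichotomous(1, 0, D = 1), exp(1) / (1 + exp(1)), tolerance = 1e-12)
  expect_equal(irf_dichotomous(1, 0, D = 1), 0.7310586, tolerance = 1e-7)
  expect_equal(irf_dichotomous(1, 0, D = 1.702), exp(1.702) / (1 + exp(1.702)),
               tolerance = 1e-12)
  expect_equal(irf_dichotomous(1, 0, D = 1.702), 0.845796, tolerance = 1e-6)
  # numerically stable at extreme arguments
  expect_identical(irf_dichotomous(700, 0), 1)
  expect_lt(irf_dichotomous(-700, 0), 1e-300)
})

test_that("partial credit category system nests the dichotomous model", {
  th <- seq(-3, 3, by = 0.5)
  p <- pcm_category_probabilities(th, 0.4)
  expect_equal(p[, 2], irf_dichotomous(th, 0.4), tolerance = 1e-14)

  # symmetric steps at theta 0: normalize (1, e, 1)
  p2 <- drop(pcm_category_probabilities(0, c(-1, 1)))
  expect_equal(p2, c(1, exp(1), 1) / (2 + exp(1)), tolerance = 1e-12)
  expect_equal(p2[1], p2[3])
  expect_equal(p2, c(0.2119, 0.5761, 0.2119), tolerance = 1e-3)

  # adjacent-category conditional at theta = step is exactly 0.5
  steps <- c(-0.7, 0.2, 1.1)
  for (j in seq_along(steps)) {
    p3 <- drop(pcm_category_probabilities(steps[j], steps))
    expect_equal(p3[j + 1] / (p3[j] + p3[j + 1]), 0.5, tolerance = 1e-12)
  }
})

test_that("two mirrored items calibrate symmetrically under the items constraint", {
  set.seed(30)
  theta <- rnorm(800)
  y1 <- as.integer(plogis(theta - 0.8) > runif(800))
  y2 <- as.integer(plogis(theta + 0.8) > runif(800))
  fit <- fit_rasch(data.frame(a = y1, b = y2), fit_config("items", convergence_tol = 1e-7))
  expect_equal(fit$items$delta[1], -fit$items$delta[2], tolerance = 1e-6)
  expect_equal(mean(fit$items$delta), 0, tolerance = 1e-8)
})

test_that("quadrature deviance matches brute-force grid integration on toy data", {
  set.seed(9)
  Y <- matrix(rbinom(15, 1, 0.5), 5, 3)
  Y[1, ] <- c(0, 1, 0); Y[2, ] <- c(1, 0, 1)
  colnames(Y) <- c("a", "b", "c")
  fit <- suppressWarnings(fit_rasch(as_response_matrix(Y),
                                    fit_config("cases", convergence_tol = 1e-6)))
  expect_lt(abs(fit$deviance - deviance_by_grid(fit)), 1e-3)
})

test_that("EM deviance is non-increasing and the fit recovers the generating difficulties", {
  sim <- sim_responses(sim_design(n_items = 20, n_persons = 2000, seed = 1))
  fit <- fit_rasch(sim$responses, fit_config("items"))
  expect_true(fit$converged)
  expect_true(all(diff(fit$deviance_trace) <= 1e-6))

  est <- tapply(fit$items$delta, fit$items$item_id, mean)
  tr <- tapply(sim$true_delta$delta, sim$true_delta$item_id, mean)[names(est)]
  tr <- tr - mean(tr)
  expect_lt(sqrt(mean((est - tr)^2)), 0.12)
})

test_that("raw score is sufficient: equal scores give equal abilities, strictly ordered", {
  sim <- sim_responses(sim_design(n_items = 12, n_persons = 150, seed = 33))
  fit <- fit_rasch(sim$responses, fit_config("items"))
  for (estimator in c("MLE", "WLE")) {
    ab <- estimate_abilities(sim$responses, fit$items, estimator)
    agg <- tapply(ab$theta, ab$raw_score, function(v) diff(range(v)))
    expect_true(all(agg < 1e-8))
    by_score <- tapply(ab$theta, ab$raw_score, mean)
    expect_true(all(diff(by_score[order(as.numeric(names(by_score)))]) > 0))
  }
})

test_that("extreme raw scores get finite flagged abilities under MLE", {
  Y <- toy_matrix(n = 30, k = 6, seed = 44)
  Y[1, ] <- 0; Y[2, ] <- 1
  fit <- fit_rasch(as_response_matrix(Y), fit_config("items"))
  ab <- fit$abilities
  expect_true(all(is.finite(ab$theta)))
  expect_true(all(is.finite(ab$se_theta)))
  expect_true(ab$extreme[1] && ab$extreme[2])
  expect_false(any(ab$extreme[ab$raw_score %in% 1:5]))
})

test_that("ability standard errors follow the information identity", {
  # 20 on-target dichotomous items: se = 1/sqrt(20 * 0.25)
  cal <- make_calibration(stats::setNames(as.list(rep(0, 20)), paste0("i", 1:20)))
  Y <- matrix(rep(c(0, 1), each = 10, times = 2), nrow = 2, byrow = TRUE,
              dimnames = list(NULL, paste0("i", 1:20)))
  ab <- estimate_abilities(as_response_matrix(Y), cal)
  expect_equal(ab$theta, c(0, 0), tolerance = 1e-6)  # raw 10/20 at delta = 0
  expect_equal(ab$se_theta, rep(1 / sqrt(5), 2), tolerance = 1e-6)
})

test_that("item standard errors follow the Fisher sum and shrink with the sample", {
  # N persons exactly at theta = delta: se = 2/sqrt(N)
  for (N in c(64, 256)) {
    cal <- make_calibration(list(a = 0, b = 0))
    ab <- tibble::tibble(person_id = as.character(1:N), theta = rep(0, N))
    Y <- matrix(rep(c(0, 1), N), ncol = 2, dimnames = list(NULL, c("a", "b")))
    se <- item_standard_errors(as_response_matrix(Y), cal, ab)$se
    expect_equal(se, rep(2 / sqrt(N), 2), tolerance = 1e-10)
  }
  # single respondent -> undefined
  cal <- make_calibration(list(a = 0, b = 0))
  Y1 <- matrix(c(1, NA, 0, 1), 2, 2, dimnames = list(NULL, c("a", "b")))
  ab1 <- tibble::tibble(person_id = c("1", "2"), theta = c(0, 0))
  se1 <- item_standard_errors(as_response_matrix(Y1), cal, ab1)$se
  expect_true(is.na(se1[1]))
})

test_that("test information is positive, peaked inside the thresholds, translation invariant", {
  cal <- make_calibration(list(a = -1, b = 0, c = 1.5, d = c(-0.5, 0.5)))
  ti <- test_information_curve(cal, seq(-4, 4, by = 0.05))
  expect_true(all(ti$information > 0))
  peak <- ti$theta[which.max(ti$information)]
  expect_gt(peak, -1); expect_lt(peak, 1.5)
  expect_equal(ti$se, 1 / sqrt(ti$information))

  # single on-target dichotomous item: information 0.25, se 2
  one <- test_information_curve(make_calibration(list(a = 0.3)), 0.3)
  expect_equal(one$information, 0.25)
  expect_equal(one$se, 2)

  shifted <- make_calibration(list(a = -1 + 2, b = 0 + 2, c = 1.5 + 2,
                                   d = c(-0.5, 0.5) + 2))
  ti2 <- test_information_curve(shifted, seq(-4, 4, by = 0.05) + 2)
  expect_equal(ti2$information, ti$information, tolerance = 1e-12)
})

test_that("missing responses are treated as not administered", {
  Y <- toy_matrix(n = 60, k = 6, seed = 55)
  Ym <- Y; Ym[cbind(1:10, rep(1:3, length.out = 10))] <- NA
  fit <- fit_rasch(as_response_matrix(Ym), fit_config("items"))
  ab <- fit$abilities
  miss <- which(rowSums(is.na(Ym)) > 0)
  expect_true(all(ab$n_administered[miss] == 5))
  expect_true(all(ab$max_score[miss] == 5))
  expect_true(all(is.finite(ab$theta)))
})
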