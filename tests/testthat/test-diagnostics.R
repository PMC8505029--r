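test_that("Thurstonian thresholds are ordered and match known anchors", {
  # dichotomous: the single threshold is the item difficulty
  thr <- thurstonian_thresholds(make_calibration(list(a = 0.7)))
  expect_equal(thr$gamma, 0.7, tolerance = 1e-7)
  expect_identical(thr$label, "I-a-1")

  # symmetric steps: gamma_1 = -gamma_2
  thr2 <- thurstonian_thresholds(make_calibration(list(p = c(-1, 1))))
  expect_equal(thr2$gamma[1], -thr2$gamma[2], tolerance = 1e-7)

  # disordered steps still give strictly ordered thresholds; verify the
  # 0.5 crossing against a fine grid search oracle
  steps <- c(1, -1)
  thr3 <- thurstonian_thresholds(make_calibration(list(q = steps)))
  expect_true(all(diff(thr3$gamma) > 0))
  grid <- seq(-6, 6, by = 1e-4)
  for (j in 1:2) {
    cum <- pcm_cumulative(grid, steps)[, j]
    oracle <- grid[which.min(abs(cum - 0.5))]
    expect_equal(thr3$gamma[j], oracle, tolerance = 1e-3)
  }
})

test_that("Wright map conserves persons across bin widths and counts labels", {
  sim <- sim_responses(sim_design(n_items = 12, n_persons = 200, model = "pcm",
                                  categories_per_item = c(rep(1, 8), rep(2, 4)),
                                  seed = 61))
  fit <- fit_rasch(sim$responses, fit_config("items"))
  thr <- thurstonian_thresholds(fit$items)
  # 8 dichotomous + 4 two-step items -> 8 + 8 threshold labels
  expect_identical(nrow(thr), 16L)
  w1 <- wright_map_data(fit$abilities, thr, binwidth = 0.5)
  w2 <- wright_map_data(fit$abilities, thr, binwidth = 0.25)
  expect_identical(sum(w1$persons$count), sum(w2$persons$count))
  expect_identical(sum(w1$persons$count),
                   sum(is.finite(fit$abilities$theta)))
})

test_that("targeting narration detects an all-easy test", {
  ab <- tibble::tibble(person_id = as.character(1:50), theta = rnorm(50, 3, 0.3),
                       se_theta = 0.4, raw_score = 1, max_score = 2,
                       estimator = "MLE", extreme = FALSE, n_administered = 2L)
  thr <- thurstonian_thresholds(make_calibration(list(a = -2, b = -1.5)))
  w <- wright_map_data(ab, thr, 0.25)
  expect_match(w$targeting$verdict, "too easy")
})

test_that("orderedness flags disordered categories and leaves ordered ones alone", {
  set.seed(62)
  theta <- rnorm(600)
  # well-functioning 3-category item: higher ability -> higher category
  p <- pcm_category_probabilities(theta, c(-0.8, 0.8))
  u <- runif(600)
  good <- max.col(u < t(apply(p, 1, cumsum)), ties.method = "first") - 1L
  other <- as.integer(plogis(theta) > runif(600))
  Y <- cbind(good = good, rev = 2L - good, other = other)
  ab <- tibble::tibble(person_id = as.character(1:600), theta = theta)
  ot <- orderedness_table(as_response_matrix(Y), ab)

  g <- ot[ot$item_id == "good", ]
  expect_false(any(g$flag_pb))
  expect_true(all(diff(g$pb) > 0))
  expect_lt(g$pb[1], 0); expect_gt(g$pb[3], 0)  # negative, middle, positive
  expect_true(all(diff(g$mean_theta) > 0))

  r <- ot[ot$item_id == "rev", ]
  expect_true(all(r$flag_pb))
  expect_true(all(r$flag_theta))
})

test_that("empty categories are emitted flagged, not dropped", {
  Y <- cbind(a = c(0L, 2L, 0L, 2L, 2L, 0L), b = c(0L, 1L, 1L, 0L, 1L, 0L))
  rm <- response_matrix(as.data.frame(Y), declared_max = c(a = 2, b = 1))
  ab <- tibble::tibble(person_id = as.character(1:6), theta = seq(-1, 1, length.out = 6))
  ot <- orderedness_table(rm, ab)
  mid <- ot[ot$item_id == "a" & ot$category == 1, ]
  expect_true(mid$flag_empty)
  expect_true(is.na(mid$pb))
})

test_that("person flags catch extremes, Guttman patterns, and erratic responders", {
  delta <- seq(-2, 2, length.out = 12)
  cal <- make_calibration(stats::setNames(as.list(delta), paste0("i", 1:12)))
  # Guttman-perfect pattern: deterministic given the difficulty order
  gutt <- as.integer(delta < 0)
  # erratic: correct on the hard half, wrong on the easy half
  errat <- as.integer(delta > 0)
  filler <- rbind(as.integer(delta < 0.5), as.integer(delta < -0.5))
  Y <- rbind(gutt, errat, filler, rep(0L, 12), rep(1L, 12))
  colnames(Y) <- paste0("i", 1:12)
  rm <- as_response_matrix(Y)
  ab <- estimate_abilities(rm, cal)
  fl <- flag_persons(ab, rm, cal, flag_config(person_fit_bounds = c(0.7, 1.3)))
  expect_match(fl$flags[1], "MISFIT_LOW")
  expect_match(fl$flags[2], "MISFIT_HIGH")
  expect_match(fl$flags[5], "EXTREME")
  expect_match(fl$flags[6], "EXTREME")
  expect_lt(fl$outfit[1], 0.7)
  expect_gt(fl$outfit[2], 1.3)
})

test_that("orderedness flags are invariant to affine ability rescalings", {
  # the logit scale is defined up to origin and unit; flags must not
  # depend on either
  Y <- toy_matrix(n = 200, k = 5, seed = 63)
  set.seed(63)
  theta <- rnorm(200)
  ab1 <- tibble::tibble(person_id = as.character(1:200), theta = theta)
  ab2 <- tibble::tibble(person_id = as.character(1:200), theta = 2.5 * theta + 1)
  o1 <- orderedness_table(as_response_matrix(Y), ab1)
  o2 <- orderedness_table(as_response_matrix(Y), ab2)
  expect_identical(o1$flag_theta, o2$flag_theta)
  expect_identical(o1$flag_pb, o2$flag_pb)
})

test_that("the developmental window selects near-50:50 thresholds", {
  thr <- tibble::tibble(item_id = "I23", category = 2, gamma = 0.59,
                        label = "I-I23-2")
  ab <- tibble::tibble(person_id = "8", theta = 0.29)
  hit <- developmental_join(thr, ab, window = 0.5)
  expect_identical(nrow(hit), 1L)
  expect_equal(hit$distance, 0.3, tolerance = 1e-12)
  none <- developmental_join(thr, ab, window = 0.1)
  expect_identical(nrow(none), 0L)
  exact <- developmental_join(thr, dplyr::mutate(ab, theta = 0.59), window = 0)
  expect_identical(nrow(exact), 1L)

  desc <- data.frame(label = "I-I23-2", skill = "continuing decimal patterns")
  withd <- developmental_join(thr, ab, desc, window = 0.5)
  expect_identical(withd$skill, "continuing decimal patterns")
})
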