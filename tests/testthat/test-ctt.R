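test_that("item-rest correlation equals a brute-force computation", {
  Y <- toy_matrix()
  rm <- as_response_matrix(Y)
  for (id in rm$item_ids) {
    got <- item_rest_correlation(rm, id)
    rest <- rowSums(Y[, setdiff(colnames(Y), id), drop = FALSE])
    expect_equal(got$r, cor(Y[, id], rest), tolerance = 1e-12)
  }
})

test_that("Fisher-z interval matches closed form: r = 0.5, n = 100", {
  # frozen from z = atanh(0.5) +/- 1.96/sqrt(97), back-transformed
  # construct a 2-item matrix with exact sample correlation 0.5 is
  # fiddly; instead check the interval formula directly via a matrix
  # whose item-rest correlation we compute, then compare against the
  # transform applied to that r
  Y <- toy_matrix(n = 100, k = 2, seed = 4)
  got <- item_rest_correlation(Y |> as.data.frame() |> response_matrix(), "i1", 0.95)
  z <- atanh(got$r); hw <- qnorm(0.975) / sqrt(got$n - 3)
  expect_equal(got$ci_low, tanh(z - hw), tolerance = 1e-12)
  expect_equal(got$ci_high, tanh(z + hw), tolerance = 1e-12)
  # and the frozen reference pair for r exactly 0.5, n = 100
  expect_equal(tanh(atanh(0.5) - qnorm(0.975) / sqrt(97)), 0.3366433, tolerance = 1e-6)
  expect_equal(tanh(atanh(0.5) + qnorm(0.975) / sqrt(97)), 0.6341398, tolerance = 1e-6)
})

test_that("Fisher interval covers the population correlation at its nominal rate", {
  # bivariate normal scores discretized to an 11-point scale; the
  # population correlation of the discretized pair is estimated once
  # from a large oracle sample
  gen <- function(n, rho) {
    x <- rnorm(n); y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    cbind(pmin(pmax(round(x * 2 + 5), 0), 10), pmin(pmax(round(y * 2 + 5), 0), 10))
  }
  set.seed(42)
  big <- gen(400000, 0.3)
  rho_d <- cor(big[, 1], big[, 2])
  hit <- 0; reps <- 2000
  for (i in seq_len(reps)) {
    sm <- gen(50, 0.3)
    colnames(sm) <- c("a", "b")
    ci <- item_rest_correlation(as_response_matrix(sm), "a", 0.95)
    if (ci$ci_low <= rho_d && rho_d <= ci$ci_high) hit <- hit + 1
  }
  expect_gt(hit / reps, 0.93)
  expect_lt(hit / reps, 0.97)
})

test_that("biserial and polyserial corrections behave as derived", {
  # r_b = r_pb * sqrt(p(1-p)) / phi(z_p): frozen anchor at p = 0.5
  expect_equal(0.3 * 0.5 / dnorm(qnorm(0.5)), 0.3759942, tolerance = 1e-6)

  # simulation oracle: biserial of a median-split normal recovers the
  # latent correlation much better than the point-biserial does
  set.seed(5)
  n <- 40000
  x <- rnorm(n); y <- 0.5 * x + sqrt(0.75) * rnorm(n)
  Y <- cbind(item = as.integer(x > 0), rest = pmin(pmax(round(y * 2 + 6), 0), 12))
  rm <- as_response_matrix(Y)
  rb <- corrected_correlation(rm, "item")
  expect_equal(rb, 0.5, tolerance = 0.03)
  expect_gt(rb, item_rest_correlation(rm, "item")$r)

  # polytomous: correction inflates away from zero, clamped to [-1, 1]
  set.seed(6)
  x3 <- cbind(a = sample(0:2, 500, TRUE), b = sample(0:2, 500, TRUE),
              c = sample(0:2, 500, TRUE))
  r_raw <- item_rest_correlation(as_response_matrix(x3), "a")$r
  r_corr <- corrected_correlation(as_response_matrix(x3), "a")
  if (!is.na(r_corr) && r_raw != 0) expect_gt(abs(r_corr), abs(r_raw))
})

test_that("alpha is 1 for parallel items, near 0 for independent ones, banded correctly", {
  base <- rep(c(0, 1, 2), each = 10)
  Y <- cbind(a = base, b = base, c = base)
  expect_equal(cronbach_alpha(as_response_matrix(Y))$alpha, 1)

  set.seed(7)
  Z <- matrix(sample(0:1, 30000 * 5, TRUE), ncol = 5,
              dimnames = list(NULL, paste0("i", 1:5)))
  expect_lt(abs(cronbach_alpha(as_response_matrix(Z))$alpha), 0.02)

  expect_identical(raschkit:::alpha_band(0.85), "good")
  expect_identical(raschkit:::alpha_band(0.55), "poor")
  expect_identical(raschkit:::alpha_band(0.95), "excellent")
})

test_that("alpha-if-deleted flags a noise item and respects symmetry", {
  set.seed(8)
  theta <- rnorm(400)
  good <- sapply(seq(-1, 1, length.out = 9), function(d) as.integer(plogis(theta - d) > runif(400)))
  noise <- sample(0:1, 400, TRUE)
  Y <- cbind(good, noise)
  colnames(Y) <- c(paste0("g", 1:9), "noise")
  aid <- alpha_if_deleted(as_response_matrix(Y))
  expect_true(aid$alpha_gain[aid$item_id == "noise"])
  expect_false(any(aid$alpha_gain[aid$item_id != "noise"]))

  # exchangeable items: all deletion values equal, none flagged
  base <- rep(c(0, 1), each = 20)
  P <- cbind(a = base, b = base, c = base, d = base)
  aidp <- alpha_if_deleted(as_response_matrix(P))
  expect_equal(stats::sd(aidp$alpha_if_deleted), 0)
  expect_false(any(aidp$alpha_gain))
})

test_that("flag thresholds are strict and negative/reversed items are caught", {
  set.seed(9)
  theta <- rnorm(300)
  ok <- sapply(c(-0.5, 0, 0.5), function(d) as.integer(plogis(theta - d) > runif(300)))
  reversed <- as.integer(plogis(-theta) > runif(300))  # scored against ability
  Y <- cbind(ok, reversed)
  colnames(Y) <- c("a", "b", "c", "rev")
  stats_tbl <- ctt_item_stats(as_response_matrix(Y))
  expect_lt(stats_tbl$item_rest_r[stats_tbl$item_id == "rev"], 0)
  expect_match(stats_tbl$flags[stats_tbl$item_id == "rev"], "NEGATIVE_R")
  expect_match(stats_tbl$flags[stats_tbl$item_id == "rev"], "LOW_R")

  # strict inequality at the threshold: set the cut exactly at an item's
  # observed r and check it is not LOW_R-flagged, then nudge the cut up
  r_a <- stats_tbl$item_rest_r[stats_tbl$item_id == "a"]
  at_cut <- ctt_item_stats(as_response_matrix(Y), flag_config(min_item_rest_r = r_a))
  expect_no_match(at_cut$flags[at_cut$item_id == "a"], "LOW_R")
  above <- ctt_item_stats(as_response_matrix(Y),
                          flag_config(min_item_rest_r = r_a + 1e-9))
  expect_match(above$flags[above$item_id == "a"], "LOW_R")

  # CI_BELOW_ZERO follows the config toggle
  noisy <- ctt_item_stats(as_response_matrix(Y), flag_config(ci_level = 0.9999999))
  expect_true(any(grepl("CI_BELOW_ZERO", noisy$flags)))
  off <- ctt_item_stats(as_response_matrix(Y),
                        flag_config(ci_level = 0.9999999, flag_negative_ci = FALSE))
  expect_false(any(grepl("CI_BELOW_ZERO", off$flags)))
})
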