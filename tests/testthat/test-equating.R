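test_that("alignment enforces the zero-sum identity and absorbs origin shifts", {
  calA <- make_calibration(stats::setNames(as.list(seq(-1, 1, length.out = 10)),
                                           paste0("L", 1:10)))
  # identical calibrations: all differences 0
  comp <- align_link_items(calA, calA)
  expect_equal(comp$difference, rep(0, 10))
  expect_lt(abs(sum(comp$difference)), 1e-10)

  # a uniform +0.3 shift is a pure origin change, fully absorbed
  calB <- dplyr::mutate(calA, delta = delta + 0.3)
  comp2 <- align_link_items(calA, calB)
  expect_equal(comp2$difference, rep(0, 10), tolerance = 1e-12)

  # one outlier of +0.5 among 10 links: +0.45 for it, -0.05 elsewhere
  calC <- calA
  calC$delta[1] <- calC$delta[1] + 0.5
  comp3 <- align_link_items(calA, calC)
  expect_equal(comp3$difference[comp3$item_id == "L1"], -0.45, tolerance = 1e-12)
  expect_equal(comp3$difference[comp3$item_id != "L1"], rep(0.05, 9), tolerance = 1e-12)
  expect_lt(abs(sum(comp3$difference)), 1e-10)

  expect_error(align_link_items(calA, make_calibration(list(X = 0, Y = 1))),
               "fewer than 2")
})

test_that("invariance z follows its closed form", {
  comp <- tibble::tibble(item_id = c("a", "b"),
                         delta_A = c(1.0, 0.5), se_A = c(0.1, 0.1),
                         delta_B = c(0.7, 0.5), se_B = c(0.1, 0.1),
                         difference = c(0.3, 0))
  z <- invariance_z(comp)
  expect_equal(z$z[1], 0.3 / sqrt(0.02), tolerance = 1e-12)
  expect_equal(z$z[1], 2.1213, tolerance = 1e-4)
  expect_equal(z$z[2], 0)
  expect_true(z$noninvariant[1])
  expect_false(z$noninvariant[2])
})

test_that("the equating error matches its closed forms", {
  mk <- function(d) tibble::tibble(item_id = paste0("i", seq_along(d)),
                                   delta_A = d, se_A = 0.1,
                                   delta_B = 0, se_B = 0.1, difference = d)
  expect_equal(equating_error(mk(rep(0, 5))), 0)
  expect_equal(equating_error(mk(c(0.2, -0.2))), 0.2, tolerance = 1e-12)
  expect_equal(equating_error(mk(c(0.1, -0.1, 0.1, -0.1))),
               sqrt(0.04 / 3) / 2, tolerance = 1e-12)
  expect_equal(equating_error(mk(c(0.1, -0.1, 0.1, -0.1))), 0.057735, tolerance = 1e-5)
  # invariant to a constant added to Form B difficulties before alignment
  calA <- make_calibration(stats::setNames(as.list(rnorm(6)), paste0("L", 1:6)))
  calB <- dplyr::mutate(calA, delta = delta + rnorm(6, 0, 0.1))
  e1 <- equating_error(align_link_items(calA, calB))
  e2 <- equating_error(align_link_items(calA, dplyr::mutate(calB, delta = delta + 5)))
  expect_equal(e1, e2, tolerance = 1e-12)
})

test_that("self-equating is the identity and anchors stay bit-equal", {
  sim <- sim_responses(sim_design(n_items = 10, n_persons = 300, seed = 81))
  fit <- fit_rasch(sim$responses, fit_config("items"))
  eq <- fixed_anchor_calibrate(sim$responses, fit$items, fit_config("items"))
  # anchored items are reported at exactly the anchor values
  anch <- eq$items[eq$items$item_id %in% fit$items$item_id, ]
  expect_identical(anch$delta, fit$items$delta)
  expect_equal(eq$abilities$theta, fit$abilities$theta, tolerance = 1e-4)

  expect_error(fixed_anchor_calibrate(sim$responses,
                                      make_calibration(list(nope = 0, nah = 1))),
               "missing from Form B")
})

test_that("a linked-forms ability shift is recovered on the common scale", {
  lf <- sim_linked_forms(sim_design(n_items = 30, n_persons = 1200, seed = 82),
                         sim_design(n_items = 30, n_persons = 1200,
                                    theta_mean = 0.5, seed = 83),
                         n_link = 10)
  fa <- fit_rasch(lf$formA, fit_config("items"))
  fb <- fit_rasch(lf$formB, fit_config("items"))
  eq <- equate_forms(fa$items, lf$formB, fb$items, abilitiesA = fa$abilities)
  expect_identical(eq$L, 10L)
  shift <- eq$fit$latent$mean - fa$latent$mean
  expect_equal(shift, mean(lf$true_theta_B) - mean(lf$true_theta_A), tolerance = 0.12)
  # the equated Form B density sits to the right of Form A
  dens <- eq$density
  mA <- with(dens[dens$form == "Form A", ], sum(bin_mid * count) / sum(count))
  mB <- with(dens[dens$form != "Form A", ], sum(bin_mid * count) / sum(count))
  expect_gt(mB, mA)
})
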