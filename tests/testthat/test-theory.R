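test_that("growth suprema via interval arithmetic match dense sampling", {
  m <- schoener_model(
    a10 = 1, a20 = 1, m1 = 2, m2 = 2, a11 = 0.35, a22 = 0.35,
    a12 = 1e-4, a21 = 1e-4,
    c1 = qp_coef(0.30005, 5e-5, sqrt(2), waveform = "sin"),
    c2 = qp_coef(0.30005, 5e-5, sqrt(2), waveform = "cos"),
    delays = c(tau10 = 0, tau11 = 0, tau12 = 0, tau20 = 0, tau21 = 0,
               tau22 = 0),
    schedule = impulse_schedule(numeric(0), h = matrix(numeric(0), 0, 2)))
  r <- growth_suprema(m)
  expect_equal(unname(r[1]), 0.2)                  # sup |0.5 - c1|
  rs <- growth_suprema(m, mode = "sampled")
  expect_equal(unname(r), unname(rs), tolerance = 1e-5)

  expect_equal(unname(growth_suprema(const_model(a10 = 2, m1 = 1,
                                                 c1 = 0.5))[1]), 1.5)
  # ratio exactly 1, mortality exactly 1 -> 0
  m0 <- const_model(a10 = 2, m1 = 2, c1 = 1, a11 = 0.5)
  expect_equal(unname(growth_suprema(m0)), c(0, 0))
})

test_that("permanence bounds reduce to the continuous, undelayed constants", {
  m <- const_model(a10 = 1, a11 = 0.5, c1 = 0.2, a12 = 1e-3)
  bd <- permanence_bounds(m)
  ru <- 1 / 2 - 0.2
  expect_equal(bd$r1_u, ru)
  expect_equal(bd$xi1, 0); expect_equal(bd$eta1, 1)
  expect_equal(bd$B1, 0.5); expect_equal(bd$D1, 0.5)
  expect_equal(bd$M1, ru / 0.5)
  rl <- 1 / (bd$M1 + 2) - 1e-3 * bd$M2 - 0.2
  expect_equal(bd$r1_l, rl)
  expect_equal(bd$N1, rl / 0.5)
  expect_equal(bd$N1, bd$N1_printed)   # no impulses: xi = 0, variants agree
  # symmetry of the two species
  expect_equal(bd$M1, bd$M2); expect_equal(bd$N1, bd$N2)
})

test_that("check_H1 reports the printed condition and the strict margin", {
  m <- const_model(a10 = 1, a11 = 0.5, c1 = 0.2,
                   schedule = sched2(seq(0, 100, 5), 0.3, 0.3))
  bd <- permanence_bounds(m)
  h1 <- check_H1(bd)
  expect_equal(h1$margins,
               c(bd$r1_l - bd$xi1 * bd$A, bd$r2_l - bd$xi2 * bd$A))
  expect_true(h1$holds == all(h1$margins >= 0))
  # xi <= 0 and r^l = 0 satisfies the printed condition
  fake <- bd; fake$r1_l <- 0; fake$r2_l <- 0
  expect_true(check_H1(fake)$holds)
  expect_false(check_H1(fake)$strict)
  # r^l = -0.1 with xi A = 0 fails with margin -0.1
  m2 <- const_model(a10 = 1, a11 = 0.5, c1 = 0.2)
  bd2 <- permanence_bounds(m2)
  bd2$r1_l <- -0.1
  h12 <- check_H1(bd2)
  expect_false(h12$holds)
  expect_equal(h12$margins[1], -0.1)
})

test_that("stability constants match an independent re-implementation", {
  # zero delays annihilate every delay product
  m0 <- const_model(a10 = 1, a11 = 0.5, c1 = 0.2, a12 = 1e-3)
  bd0 <- permanence_bounds(m0)
  ab0 <- stability_constants(m0, bd0)
  expect_equal(unname(ab0["alpha1"]),
               1 * bd0$N1 / (bd0$M1 + 2)^2 + 0.5 * bd0$N1)
  expect_equal(unname(ab0["beta1"]), 1e-3 * bd0$M1)
  expect_equal(unname(ab0["beta2"]), 1e-3 * bd0$M2)

  # worked-example coefficients with the externally supplied window
  m <- example1_model(c(0, 100))
  w <- list(M1 = 0.7256, M2 = 0.5421, N1 = 0.01, N2 = 0.01)
  ab <- stability_constants(m, w)
  expect_true(ab["alpha1"] > 0 && ab["alpha2"] > 0)
  expect_lt(max(ab["beta1"], ab["beta2"]), min(ab["alpha1"], ab["alpha2"]))
  # independent recomputation of alpha_1 and beta_2 from the printed forms
  cb <- function(x) coef_bounds(x)
  a10 <- cb(m$a10); a11 <- cb(m$a11); a12 <- cb(m$a12); m1 <- cb(m$m1)
  t10 <- 1e-4; t11 <- 1e-4
  alpha1_ref <- a10[1] * w$N1 / (w$M1 + m1[2])^2 + a11[1] * w$N1 -
    (sqrt(t10) * a10[2] * w$M1 / (w$N1 + m1[1])^2)^2 -
    (t10 + t11) * a10[2] * a11[2] * w$M1^2 / (w$N1 + m1[1])^2 -
    t11 * a11[2]^2 * w$M1^2
  beta2_ref <- t10 * a10[2] * a12[2] * w$M1 * w$M2 / (w$N1 + m1[1])^2 +
    t11 * a11[2] * a12[2] * w$M1 * w$M2 + a12[2] * w$M2
  expect_equal(unname(ab["alpha1"]), alpha1_ref)
  expect_equal(unname(ab["beta2"]), beta2_ref)
  expect_error(stability_constants(m, list(M1 = 1, M2 = 1, N1 = -1, N2 = 1)),
               "positive")
})

test_that("check_H2 matches its closed-form characterization and examples", {
  # worked-instance constants: feasible, and lambda = (1, 1) works too
  r <- check_H2(0.03, 0.02, 7e-5, 7e-5)
  expect_true(r$feasible)
  expect_true(1 * 0.03 > 1 * 7e-5 && 1 * 0.02 > 1 * 7e-5)
  expect_true(r$lambda1 * r$alpha1 > r$lambda2 * r$beta1)
  expect_true(r$lambda2 * r$alpha2 > r$lambda1 * r$beta2)
  expect_gt(r$Theta, 0)

  expect_false(check_H2(1, 1, 2, 2)$feasible)
  r2 <- check_H2(2, 1, 1, 1.9)
  expect_true(r2$feasible)
  expect_equal(r2$ratio_interval, c(0.5, 1 / 1.9))
})

test_that("check_H2 agrees with a brute-force lambda-grid oracle", {
  set.seed(5)
  grid <- 10^seq(-8, 8, length.out = 3201)
  for (rep in 1:300) {
    a1 <- runif(1, -0.5, 2); a2 <- runif(1, -0.5, 2)
    b1 <- runif(1, 0, 1.5); b2 <- runif(1, 0, 1.5)
    oracle <- any(grid * a1 > b1 & a2 > grid * b2)
    expect_identical(check_H2(a1, a2, b1, b2)$feasible, oracle)
  }
})

test_that("the no-impulse zero-delay pipeline is its own continuous limit", {
  m <- const_model(a10 = 1.2, a11 = 0.8, c1 = 0.15, a12 = 2e-4)
  bd <- permanence_bounds(m)
  ru <- 1.2 / 2 - 0.15
  expect_equal(bd$M1, ru / 0.8)
  expect_equal(bd$N1, bd$r1_l / 0.8)
  expect_true(check_H1(bd)$holds && check_H1(bd)$strict)
  # and the bound is honored by simulation
  h <- initial_history(0.3, 0.3, range = c(-1, 0))
  tr <- integrate_schoener(m, h, c(0, 120), step = 0.05)
  te <- tail_extrema(tr, 0.25)
  expect_true(all(te$high <= c(bd$M1, bd$M2) + 1e-3))
  expect_true(all(te$low >= c(bd$N1, bd$N2) - 1e-3))
})
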