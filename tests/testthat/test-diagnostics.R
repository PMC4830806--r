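# hand-built trajectory on a plain grid (no jumps), for estimator tests
fake_traj <- function(times, states, derivs = NULL) {
  states <- as.matrix(states)
  if (is.null(derivs)) derivs <- matrix(0, nrow(states), ncol(states))
  structure(list(times = times, states = states, derivs = derivs,
                 seg = rep(1L, length(times)),
                 jumps = data.frame(time = numeric(0)),
                 step = times[2] - times[1], space = "linear",
                 species = ncol(states), t0 = times[1],
                 t1 = times[length(times)],
                 history = initial_history(
                   max(states[1, 1], 1e-6),
                   if (ncol(states) > 1) max(states[1, 2], 1e-6) else NULL,
                   range = c(-1, 0))),
            class = "imp_trajectory")
}

test_that("tail_extrema scans the stated window including jumps", {
  tr <- integrate_logistic(1, 1, NULL, 0, x0 = 1, c(0, 10), step = 0.1)
  te <- tail_extrema(tr, 0.25)
  expect_equal(te$low, 1); expect_equal(te$high, 1)

  tt <- seq(0, 40, by = 0.01)
  ts <- fake_traj(tt, cbind(sin(tt), cos(tt)),
                  cbind(cos(tt), -sin(tt)))
  te2 <- tail_extrema(ts, 0.5)
  expect_equal(te2$low, c(-1, -1), tolerance = 1e-4)
  expect_equal(te2$high, c(1, 1), tolerance = 1e-4)
  expect_error(tail_extrema(ts, 0), "fraction")

  # post-jump values are part of the scan
  trj <- integrate_logistic(1, 1, sched1(c(9.5), 1.0), 0, x0 = 1,
                            c(0, 10), step = 0.05)
  te3 <- tail_extrema(trj, 0.25)
  expect_gte(te3$high, 2 - 1e-6)
})

test_that("invariant set membership holds under certification", {
  m <- random_weak_model(11)
  bd <- permanence_bounds(m)
  expect_true(check_H1(bd)$strict)
  hS <- initial_history((bd$N1 + bd$M1) / 2, (bd$N2 + bd$M2) / 2,
                        range = c(-1, 0))
  tr <- integrate_schoener(m, hS, c(0, 80), step = 0.05)
  expect_true(invariant_set_check(tr, bd))
  # history outside S is a misuse, not a FALSE
  hOut <- initial_history(bd$M1 * 2, (bd$N2 + bd$M2) / 2, range = c(-1, 0))
  trOut <- integrate_schoener(m, hOut, c(0, 5), step = 0.05)
  expect_error(invariant_set_check(trOut, bd), "outside")

  # degenerate window at the exact equilibrium of the constant model
  mc <- const_model()
  eq <- uniroot(function(x) 1 / (x + 2) - 0.35 * x - 0.3, c(0.01, 2),
                tol = 1e-13)$root
  trE <- integrate_schoener(mc, initial_history(eq, eq, range = c(-1, 0)),
                            c(0, 20), step = 0.05)
  expect_true(invariant_set_check(trE, list(N1 = eq, N2 = eq,
                                            M1 = eq, M2 = eq)))
})

test_that("pair_distance measures sup and terminal gaps", {
  m <- example1_model(c(0, 20))
  h <- initial_history(0.12, 0.02, range = c(-1, 0))
  tr <- integrate_schoener(m, h, c(0, 20), step = 0.05)
  expect_identical(pair_distance(tr, tr, "sup"), 0)
  expect_identical(pair_distance(tr, tr, "terminal"), 0)
  tr2 <- integrate_schoener(m, h, c(0, 20), step = 0.1)
  expect_error(pair_distance(tr, tr2), "grid")
})

test_that("lyapunov_V: coincidence, zero delays, constant log-offsets", {
  m <- const_model(a12 = 1e-3)          # all delays zero
  bd <- permanence_bounds(m)
  h <- initial_history(0.3, 0.3, range = c(-1, 0))
  tr <- integrate_schoener(m, h, c(0, 20), step = 0.05)
  v <- lyapunov_V(tr, tr, m, bd, 1, 1, 10)
  expect_identical(v$V, 0)
  expect_identical(c(v$V2, v$V3, v$V4), c(0, 0, 0))

  tt <- seq(0, 10, by = 0.05)
  trA <- fake_traj(tt, cbind(rep(1, length(tt)), rep(1, length(tt))))
  trB <- fake_traj(tt, cbind(rep(exp(0.1), length(tt)),
                             rep(exp(-0.2), length(tt))))
  v2 <- lyapunov_V(trA, trB, m, bd, 1, 1, 5)
  expect_equal(v2$V, 0.3)
  expect_equal(v2$V, v2$V1)
})

test_that("V is conserved across jumps and decays under H2", {
  m <- random_weak_model(11)
  bd <- permanence_bounds(m)
  ab <- stability_constants(m, bd)
  h2 <- check_H2(ab[["alpha1"]], ab[["alpha2"]], ab[["beta1"]],
                 ab[["beta2"]])
  expect_true(h2$feasible)
  trA <- integrate_schoener(m, initial_history(0.32, 0.31, range = c(-1, 0)),
                            c(0, 60), step = 0.05)
  trB <- integrate_schoener(m, initial_history(0.45, 0.22, range = c(-1, 0)),
                            c(0, 60), step = 0.05)
  lc <- lyapunov_checks(trA, trB, m, bd, h2$lambda1, h2$lambda2,
                        checkpoints = seq(5, 60, by = 5))
  expect_lt(lc$jump_max_violation, 1e-8)
  expect_true(lc$monotone)
  # the lower bracket of the functional: V >= min(lambda) * |z - z*|
  v <- lyapunov_V(trA, trB, m, bd, h2$lambda1, h2$lambda2, 30)
  z30 <- abs(log(history_eval(trA, 30)) - log(history_eval(trB, 30)))
  expect_gte(v$V, min(h2$lambda1, h2$lambda2) * sum(z30) - 1e-12)
})
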