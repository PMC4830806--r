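test_that("cauchy_W matches a segment-by-segment linear solve", {
  sch <- sched1(1:4, 0.5)
  expect_equal(cauchy_W(1, impulse_schedule(numeric(0)), 1, 0), exp(-1))
  # independent oracle: march du/dt = -a u across the impulses
  a <- 0.2
  u <- 1; tcur <- 0
  for (tk in c(1, 2, 3, 4)) {
    u <- u * exp(-a * (tk - tcur)); u <- u / 1.5; tcur <- tk
  }
  u <- u * exp(-a * (5 - tcur))
  expect_equal(cauchy_W(a, sch, 5, 0), u)
  expect_equal(u, (1 / 1.5)^4 * exp(-1))
  expect_equal(u, 0.0726676, tolerance = 1e-6)
  expect_equal(cauchy_W(1, sch, 3, 3), 1)     # W(t, t) = 1
  expect_error(cauchy_W(1, sch, 0, 1), "s <= t")
})

test_that("cauchy_W has the cocycle property", {
  set.seed(7)
  sch <- sched1(sort(runif(12, 0, 30)), 0.4)
  for (rep in 1:50) {
    s <- runif(1, 0, 10); t <- s + runif(1, 0.5, 15)
    r <- runif(1, s + 1e-3, t - 1e-3)
    if (r %in% sch$points) next
    w1 <- cauchy_W(0.7, sch, t, s)
    w2 <- cauchy_W(0.7, sch, t, r) * cauchy_W(0.7, sch, r, s)
    expect_lt(abs(w1 - w2) / w1, 1e-12)
  }
})

test_that("almost periodic orbit: no-impulse closed form and jump relation", {
  expect_equal(logistic_ap_solution(impulsive_logistic(1, 1), 3,
                                    tol = 1e-13), 1, tolerance = 1e-10)
  expect_equal(logistic_ap_solution(impulsive_logistic(2, 0.5), -1.7,
                                    tol = 1e-13), 4, tolerance = 1e-10)
  p <- impulsive_logistic(1, 1, sched1(seq(0, 100, by = 5), 0.5))
  tol <- 1e-9
  # jump relation x*(tau_k^+) = 1.5 x*(tau_k)
  xl <- logistic_ap_solution(p, 55, tol = tol, side = "left")
  xr <- logistic_ap_solution(p, 55, tol = tol, side = "right")
  expect_lt(abs(xr / xl - 1.5), 10 * tol)
  # satisfies dx = x(1-x) between impulses (5-point stencil derivative)
  hh <- 0.01
  xs <- logistic_ap_solution(p, 52.5 + (-2:2) * hh, tol = tol)
  deriv <- (xs[1] - 8 * xs[2] + 8 * xs[4] - xs[5]) / (12 * hh)
  expect_lt(abs(deriv - xs[3] * (1 - xs[3])), 10 * tol)
  # long-time limit of the simulated equation from any start
  tr <- integrate_logistic(1, 1, sched1(seq(0, 100, by = 5), 0.5), 0,
                           x0 = 0.37, c(0, 100), step = 0.01)
  expect_equal(tr$states[length(tr$times), 1],
               logistic_ap_solution(p, 100, tol = 1e-12), tolerance = 1e-6)
  expect_error(logistic_ap_solution(impulsive_logistic(1, 1, delay = 1), 0),
               "undelayed")
})

test_that("orbit lies in the (validity-corrected) closed-form bracket", {
  set.seed(3)
  for (rep in 1:10) {
    a <- runif(1, 0.4, 2); b <- runif(1, 0.3, 2)
    per <- runif(1, 2, 8); h <- runif(1, 0, 0.8)
    p <- impulsive_logistic(a, b, sched1(seq(0, 120, by = per), h))
    sb <- logistic_scalar_bounds(p)
    xs <- logistic_ap_solution(p, seq(60, 60 + 2 * per, length.out = 31),
                               tol = 1e-10)
    expect_true(all(xs >= sb$ap_lower - 1e-8))
    expect_true(all(xs <= sb$ap_upper + 1e-8))
  }
})

test_that("global stability: distinct starts contract onto one orbit", {
  sch <- sched1(seq(0, 80, by = 5), 0.5)
  trA <- integrate_logistic(1, 1, sch, 0, x0 = 0.05, c(0, 80), step = 0.02)
  trB <- integrate_logistic(1, 1, sch, 0, x0 = 3.2, c(0, 80), step = 0.02)
  d <- abs(trA$states - trB$states)
  checkpoints <- vapply(seq(10, 80, by = 10), function(tc)
    abs(history_eval(trA, tc)[1, 1] - history_eval(trB, tc)[1, 1]),
    numeric(1))
  expect_true(all(diff(checkpoints) <= 1e-12))
  expect_lt(d[length(trA$times)], 1e-6)
})

test_that("scalar bounds reduce correctly and certify simulations", {
  # no impulses, no delay: the classical logistic constants
  sb <- logistic_scalar_bounds(impulsive_logistic(1.3, 0.6))
  expect_equal(sb$xi, 0); expect_equal(sb$eta, 1)
  expect_equal(sb$theta, Inf)
  expect_equal(sb$B, 0.6); expect_equal(sb$D, 0.6)
  expect_equal(sb$M, 1.3 / 0.6); expect_equal(sb$N, 1.3 / 0.6)
  # no impulses, delay tau: M = (a/b) e^{a tau}
  a <- 0.9; b <- 0.5; tau <- 0.4
  sb2 <- logistic_scalar_bounds(impulsive_logistic(a, b, delay = tau))
  expect_equal(sb2$B, b * exp(-a * tau))
  expect_equal(sb2$M, (a / b) * exp(a * tau))

  # randomized sweep: simulated tails respect M and the corrected N
  set.seed(11)
  for (rep in 1:8) {
    a <- runif(1, 0.5, 1.5); b <- runif(1, 0.5, 1.5)
    h <- runif(1, 0, 0.5); per <- runif(1, 3, 8)
    tau <- runif(1, 0, 0.3)
    sch <- sched1(seq(0, 120, by = per), h)
    p <- impulsive_logistic(a, b, sch, delay = tau)
    sb <- logistic_scalar_bounds(p)
    tr <- integrate_logistic(a, b, sch, tau, x0 = runif(1, 0.3, 1.5),
                             c(0, 120), step = 0.02)
    tail_x <- tr$states[tr$times >= 90, 1]
    expect_lte(max(tail_x), sb$M + 1e-3)
    if (sb$N > 0) expect_gte(min(tail_x), sb$N - 1e-3)
  }
})

test_that("the as-printed lower bound overstates the infimum when h > 0", {
  # the exponent chain behind N is only valid for xi >= 0; with h = 0.5 the
  # printed value exceeds the true orbit minimum by a wide margin, while the
  # corrected bound (a/D for h >= 0) holds
  sch <- sched1(seq(0, 100, by = 5), 0.5)
  sb <- logistic_scalar_bounds(impulsive_logistic(1, 1, sch))
  tr <- integrate_logistic(1, 1, sch, 0, x0 = 1, c(0, 100), step = 0.02)
  tail_min <- min(tr$states[tr$times >= 75, 1])
  expect_gt(sb$N_printed, tail_min + 0.5)   # printed bound is violated
  expect_lte(sb$N, tail_min + 1e-9)         # corrected bound is honored
  expect_lte(tail_min, sb$M + 1e-9)
})
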