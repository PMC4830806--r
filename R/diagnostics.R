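#' Tail extrema of a trajectory
#'
#' Empirical estimators of \eqn{\liminf} / \eqn{\limsup}: the per-species
#' minimum and maximum of the stored grid values (pre- and post-jump rows
#' included) over the final `fraction` of the integration horizon.
#'
#' @param traj An `imp_trajectory`.
#' @param fraction Fraction of the horizon to scan, in `(0, 1]`.
#' @return List with numeric vectors `low` and `high` (one entry per
#'   species).
#' @export
tail_extrema <- function(traj, fraction = 0.25) {
  stopifnot(inherits(traj, "imp_trajectory"), fraction > 0, fraction <= 1)
  cutoff <- traj$t1 - fraction * (traj$t1 - traj$t0)
  keep <- traj$times >= cutoff
  if (!any(keep)) stop("empty tail window")
  s <- traj$states[keep, , drop = FALSE]
  list(low = apply(s, 2, min), high = apply(s, 2, max))
}

#' Invariant-set membership check
#'
#' Verifies that a trajectory whose initial history lies in the permanence
#' window \eqn{S = \{N_i \le x_i \le M_i\}} never leaves it: under the
#' certified permanence condition, \eqn{S} is an invariant set of the system.
#' The precondition (history inside \eqn{S}) is enforced and its violation is
#' an error, not a `FALSE`.
#'
#' @param traj A two-species `imp_trajectory`.
#' @param bounds A [permanence_bounds()] (the corrected `N_i` are used).
#' @param tol Numerical slack on the window boundaries.
#' @return `TRUE` iff every stored state (pre- and post-jump) stays within
#'   `[N_i - tol, M_i + tol]`.
#' @export
invariant_set_check <- function(traj, bounds, tol = 1e-6) {
  stopifnot(inherits(traj, "imp_trajectory"), traj$species == 2L)
  lo <- c(bounds$N1, bounds$N2); hi <- c(bounds$M1, bounds$M2)
  hgrid <- seq(traj$history$range[1], 0, length.out = 21L)
  for (i in 1:2) {
    hv <- traj$history$funs[[i]](hgrid)
    if (any(hv < lo[i] - tol) || any(hv > hi[i] + tol))
      stop("initial history lies outside the invariant set S; ",
           "the membership check presupposes it starts inside")
  }
  all(sweep(traj$states, 2, lo - tol, ">=") &
        sweep(traj$states, 2, hi + tol, "<="))
}

#' Distance between two trajectories on a common grid
#'
#' \eqn{\sum_i |x_i^A - x_i^B|} either as a supremum over the final quarter
#' of the horizon (`norm = "sup"`) or at the terminal time
#' (`norm = "terminal"`). A convergence diagnostic for the uniform asymptotic
#' stability of the almost periodic orbit.
#'
#' @param trajA,trajB Trajectories on identical time grids.
#' @param norm `"sup"` or `"terminal"`.
#' @return A single nonnegative number.
#' @export
pair_distance <- function(trajA, trajB, norm = c("sup", "terminal")) {
  norm <- match.arg(norm)
  stopifnot(inherits(trajA, "imp_trajectory"),
            inherits(trajB, "imp_trajectory"))
  if (length(trajA$times) != length(trajB$times) ||
      any(abs(trajA$times - trajB$times) > 1e-12))
    stop("trajectories must share an identical time grid")
  d <- rowSums(abs(trajA$states - trajB$states))
  if (norm == "terminal") return(d[length(d)])
  cutoff <- trajA$t1 - 0.25 * (trajA$t1 - trajA$t0)
  max(d[trajA$times >= cutoff])
}

# term table of the Lyapunov functional's delay-memory integrals:
# each double integral  coef * int_{-ta-tb}^{-tb} int_{t+s}^{t} |dz_sp(r)| dr ds
# reduces by Fubini to  coef * int_{t-ta-tb}^{t} w(r) |dz_sp(r)| dr  with
# weight w(r) = min(ta, max(0, r - t + ta + tb)).
.lyap_terms <- function(model, bounds, lambda1, lambda2) {
  b <- lapply(model[c("a10", "a20", "a11", "a12", "a21", "a22", "m1", "m2")],
              coef_bounds)
  d <- model$delays
  M1 <- bounds$M1; M2 <- bounds$M2; N1 <- bounds$N1; N2 <- bounds$N2
  q1 <- (N1 + b$m1[1])^2; q2 <- (N2 + b$m2[1])^2
  t10 <- d[["tau10"]]; t11 <- d[["tau11"]]; t12 <- d[["tau12"]]
  t20 <- d[["tau20"]]; t21 <- d[["tau21"]]; t22 <- d[["tau22"]]
  rbindlist <- function(...) do.call(rbind, lapply(list(...), function(r)
    data.frame(group = r[[1]], sp = r[[2]], coef = r[[3]],
               ta = r[[4]], tb = r[[5]])))
  rbindlist(
    list("V2", 1L, lambda1 * (b$a10[2] * M1 / q1)^2,            t10, t10),
    list("V2", 1L, lambda1 * b$a10[2] * b$a11[2] * M1^2 / q1,   t10, t11),
    list("V2", 1L, lambda1 * b$a10[2] * b$a11[2] * M1^2 / q1,   t11, t10),
    list("V2", 1L, lambda1 * b$a11[2]^2 * M1^2,                 t11, t11),
    list("V2", 1L, lambda2 * b$a20[2] * b$a21[2] * M1 * M2 / q2, t20, t21),
    list("V2", 1L, lambda2 * b$a21[2] * b$a22[2] * M1 * M2,     t22, t21),
    list("V3", 2L, lambda1 * b$a10[2] * b$a12[2] * M1 * M2 / q1, t10, t12),
    list("V3", 2L, lambda1 * b$a11[2] * b$a12[2] * M1 * M2,     t11, t12),
    list("V3", 2L, lambda2 * (b$a20[2] * M2 / q2)^2,            t20, t20),
    list("V3", 2L, lambda2 * b$a20[2] * b$a22[2] * M2^2 / q2,   t20, t22),
    list("V3", 2L, lambda2 * b$a20[2] * b$a22[2] * M2^2 / q2,   t22, t20),
    list("V3", 2L, lambda2 * b$a22[2]^2 * M2^2,                 t22, t22))
}

# |z_sp(r) - z*_sp(r)| sampled by interpolating both trajectories
.dz_fun <- function(trajA, trajB, side = "left") {
  function(r, sp) {
    za <- log(history_eval(trajA, r, side = side)[, sp])
    zb <- log(history_eval(trajB, r, side = side)[, sp])
    abs(za - zb)
  }
}

.trapz <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (y[-1] + y[-length(y)])) / 2
}

#' Evaluate the Lyapunov functional of the product system
#'
#' The stability proof's functional
#' \eqn{V = V_1 + V_2 + V_3 + V_4} of two solutions, on the log scale
#' \eqn{z_i = \ln x_i}: \eqn{V_1 = \lambda_1 |z_1 - z_1^*| +
#' \lambda_2 |z_2 - z_2^*|} at `t`; \eqn{V_2, V_3} are the double-integral
#' memory terms (reduced analytically to single weighted integrals over the
#' delay windows before quadrature) and \eqn{V_4} the two single-integral
#' terms. Composite trapezoidal quadrature on the interpolated grid.
#'
#' @param trajA,trajB Two-species trajectories of the same model on a common
#'   grid, both defined on `[t - tau_max, t]`.
#' @param model The [schoener_model()].
#' @param bounds A [permanence_bounds()] with positive (corrected) `N_i`.
#' @param lambda1,lambda2 Positive multipliers (from [check_H2()]).
#' @param t Evaluation time.
#' @param side `"left"` (default) or `"right"` value of \eqn{V_1} at an
#'   impulse time.
#' @param n_quad Minimum number of quadrature nodes per delay window.
#' @return An object of class `lyapunov_evaluation` with `V, V1, V2, V3, V4`.
#' @export
lyapunov_V <- function(trajA, trajB, model, bounds, lambda1, lambda2, t,
                       side = c("left", "right"), n_quad = 17L) {
  side <- match.arg(side)
  stopifnot(inherits(trajA, "imp_trajectory"), trajA$species == 2L,
            inherits(trajB, "imp_trajectory"), trajB$species == 2L,
            lambda1 > 0, lambda2 > 0)
  if (t - model$tau_max < trajA$t0 - 1e-9 || t > trajA$t1 + 1e-9)
    stop("insufficient stored history around t for the delay windows")
  dz <- .dz_fun(trajA, trajB, side = "left")
  dz_t <- .dz_fun(trajA, trajB, side = side)
  V1 <- lambda1 * dz_t(t, 1L) + lambda2 * dz_t(t, 2L)

  terms <- .lyap_terms(model, bounds, lambda1, lambda2)
  V2 <- V3 <- 0
  for (k in seq_len(nrow(terms))) {
    ta <- terms$ta[k]; tb <- terms$tb[k]
    if (ta == 0 || terms$coef[k] == 0) next
    lo <- t - ta - tb
    nodes <- max(n_quad, 2L * ceiling((ta + tb) / trajA$step) + 1L)
    r <- seq(lo, t, length.out = nodes)
    w <- pmin(ta, pmax(0, r - t + ta + tb))
    val <- terms$coef[k] * .trapz(r, w * dz(r, terms$sp[k]))
    if (terms$group[k] == "V2") V2 <- V2 + val else V3 <- V3 + val
  }
  d <- model$delays
  au <- coef_bounds(model$a21)[2]; av <- coef_bounds(model$a12)[2]
  V4 <- 0
  if (d[["tau21"]] > 0) {
    r <- seq(t - d[["tau21"]], t,
             length.out = max(n_quad, 2L * ceiling(d[["tau21"]] / trajA$step) + 1L))
    V4 <- V4 + lambda2 * au * bounds$M1 * .trapz(r, dz(r, 1L))
  }
  if (d[["tau12"]] > 0) {
    r <- seq(t - d[["tau12"]], t,
             length.out = max(n_quad, 2L * ceiling(d[["tau12"]] / trajA$step) + 1L))
    V4 <- V4 + lambda1 * av * bounds$M2 * .trapz(r, dz(r, 2L))
  }
  structure(list(V = V1 + V2 + V3 + V4, V1 = V1, V2 = V2, V3 = V3, V4 = V4,
                 lambda1 = lambda1, lambda2 = lambda2, t = t),
            class = "lyapunov_evaluation")
}

#' @export
print.lyapunov_evaluation <- function(x, ...) {
  cat(sprintf("<lyapunov_evaluation> t = %g: V = %.6g (V1 %.3g, V2 %.3g, V3 %.3g, V4 %.3g)\n",
              x$t, x$V, x$V1, x$V2, x$V3, x$V4))
  invisible(x)
}

#' Numerical checks of the Lyapunov functional's certificate properties
#'
#' Verifies on a stored trajectory pair that (i) `V` is continuous across
#' every impulse (the common jump factor cancels in the log differences, so
#' \eqn{V(\tau_k^+) = V(\tau_k)} exactly; reported as the maximal relative
#' violation) and (ii) `V` is non-increasing across the supplied checkpoints
#' between impulses (reported, with the maximal observed increase).
#'
#' @inheritParams lyapunov_V
#' @param checkpoints Times at which `V` is evaluated for the monotonicity
#'   check (values closer than `tau_max` to the start are dropped).
#' @return List with `jump_max_violation` (relative, floored at the
#'   measurable scale 1e-7), `jump_max_abs` (raw discrepancy),
#'   `checkpoints`, `V`, `monotone`, `max_increase`.
#' @export
lyapunov_checks <- function(trajA, trajB, model, bounds, lambda1, lambda2,
                            checkpoints) {
  t_min <- trajA$t0 + model$tau_max + 1e-9
  jmp <- trajA$jumps$time
  jmp <- jmp[jmp > t_min & jmp < trajA$t1]
  jump_viol <- jump_abs <- 0
  for (tk in jmp) {
    vl <- lyapunov_V(trajA, trajB, model, bounds, lambda1, lambda2, tk,
                     side = "left")
    vr <- lyapunov_V(trajA, trajB, model, bounds, lambda1, lambda2, tk,
                     side = "right")
    # V1 is built from log differences of O(1) states, so its absolute
    # rounding floor is ~1e-15; once V has decayed below ~1e-7 a relative
    # band tighter than that floor is not measurable, hence the floor in the
    # denominator. The raw absolute discrepancy is reported alongside.
    jump_abs <- max(jump_abs, abs(vr$V - vl$V))
    jump_viol <- max(jump_viol, abs(vr$V - vl$V) / max(vl$V, 1e-7))
  }
  checkpoints <- checkpoints[checkpoints >= t_min & checkpoints <= trajA$t1]
  vv <- vapply(checkpoints, function(tc)
    lyapunov_V(trajA, trajB, model, bounds, lambda1, lambda2, tc)$V,
    numeric(1))
  incr <- if (length(vv) > 1L) max(diff(vv)) else -Inf
  list(jump_max_violation = jump_viol, jump_max_abs = jump_abs,
       checkpoints = checkpoints, V = vv,
       monotone = incr <= 0, max_increase = max(incr, 0))
}
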