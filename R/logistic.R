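#' Parameters of the scalar impulsive delayed logistic equation
#'
#' Bundles \eqn{\dot x = x\,[a - b\,x(t-\tau)]} with jumps
#' \eqn{x(\tau_k^+) = (1 + h_k) x(\tau_k)}.
#'
#' @param a Growth rate (`> 0` for the theory operations).
#' @param b Density dependence (`> 0`).
#' @param schedule An [impulse_schedule()] (first species column used);
#'   `NULL` for no impulses.
#' @param delay Delay `tau >= 0`.
#' @return An object of class `impulsive_logistic`.
#' @export
impulsive_logistic <- function(a, b, schedule = NULL, delay = 0) {
  if (is.null(schedule)) schedule <- impulse_schedule(numeric(0))
  stopifnot(inherits(schedule, "impulse_schedule"), delay >= 0)
  structure(list(a = a, b = b, schedule = schedule, delay = delay),
            class = "impulsive_logistic")
}

#' Cauchy matrix of the linear impulsive decay equation
#'
#' The state-transition factor of \eqn{\dot u = -a u} with jumps
#' \eqn{u(\tau_k^+) = u(\tau_k)/(1 + h_k)}:
#' \deqn{W(t, s) = e^{-a (t - s)} \prod_{\tau_k \in (s,\, t]} \frac{1}{1 + h_k},}
#' with \eqn{W(t, t) = 1}. Satisfies the cocycle property
#' \eqn{W(t, s) = W(t, r) W(r, s)} for non-impulse \eqn{r \in (s, t)}.
#'
#' @param a Decay rate.
#' @param schedule An [impulse_schedule()] (first species column).
#' @param t,s Times with `s <= t` (vectorized over pairs).
#' @return Numeric vector of transition factors.
#' @export
cauchy_W <- function(a, schedule, t, s) {
  stopifnot(inherits(schedule, "impulse_schedule"))
  if (any(s > t)) stop("cauchy_W requires s <= t")
  pts <- schedule$points; hv <- if (length(pts)) schedule$h[, 1] else numeric(0)
  n <- max(length(t), length(s))
  t <- rep_len(t, n); s <- rep_len(s, n)
  vapply(seq_len(n), function(q) {
    inside <- pts > s[q] & pts <= t[q]
    exp(-a * (t[q] - s[q])) *
      (if (any(inside)) prod(1 / (1 + hv[inside])) else 1)
  }, numeric(1))
}

#' Almost periodic solution of the undelayed impulsive logistic equation
#'
#' Evaluates the closed form
#' \deqn{x^*(t) = \Big[\, b \int_{-\infty}^{t} W(t, s)\, \mathrm{d}s \Big]^{-1}.}
#' Between impulse times the integrand is exactly \eqn{P\, e^{-a(t-s)}} with a
#' piecewise-constant jump product \eqn{P}, so each segment is integrated in
#' closed form; the infinite lower limit is truncated at \eqn{t - L} where
#' \eqn{L} is chosen so the neglected tail envelope falls below `tol`.
#'
#' @param params An [impulsive_logistic()] with `delay = 0`.
#' @param t Evaluation time(s).
#' @param tol Truncation tolerance for the tail of the integral.
#' @param side `"right"` (default: the jump at `t`, if any, is applied) or
#'   `"left"` (pre-jump value).
#' @return Numeric vector `x*(t)`.
#' @export
logistic_ap_solution <- function(params, t, tol = 1e-10,
                                 side = c("right", "left")) {
  side <- match.arg(side)
  stopifnot(inherits(params, "impulsive_logistic"))
  a <- params$a; b <- params$b
  if (params$delay != 0)
    stop("the closed-form orbit is defined for the undelayed equation")
  stopifnot(a > 0, b > 0, tol > 0)
  pts <- params$schedule$points
  hv <- if (length(pts)) params$schedule$h[, 1] else numeric(0)
  grow <- if (length(hv)) max(1 / (1 + hv)) else 1
  A <- schedule_A(params$schedule)
  rate <- a - A * max(0, log(grow))
  if (rate <= 0)
    stop("integral truncation does not converge (a too small for the ",
         "impulse growth envelope)")
  L <- max((log(max(b, 1) / (min(a, 1) * tol)) + A * abs(log(grow))) / rate, 1)
  vapply(t, function(tt) {
    inside <- if (side == "right") pts > tt - L & pts <= tt
              else pts > tt - L & pts < tt
    p <- pts[inside]; hp <- hv[inside]
    sb <- c(tt - L, p, tt)
    # product of jump factors for s in segment i: impulses strictly above sb[i]
    prods <- rev(cumprod(rev(c(1 / (1 + hp), 1))))
    segint <- (exp(-a * (tt - sb[-1])) - exp(-a * (tt - sb[-length(sb)]))) / a
    1 / (b * sum(prods * segint))
  }, numeric(1))
}

#' Certified constants and bounds for the scalar impulsive delayed logistic
#'
#' Computes the full constant set of the scalar comparison theory: the jump
#' statistics \eqn{\xi = \ln \sup_k 1/(1+h_k)}, \eqn{\eta} (two-consecutive
#' factor product, capped at 1), \eqn{\theta} (minimal gap), the window
#' constants
#' \deqn{B = \inf_t\, b \prod_{\tau_k \in [t-\tau,\, t)} (1+h_k)^{-1} e^{-a\tau},
#' \qquad D = \sup_t\, b \prod_{\tau_k \in [t-\tau,\, t)} (1+h_k)^{-1} e^{-(a - bM)\tau},}
#' the eventual upper bound \eqn{M = a / (\eta B (1 - e^{-a\theta}))} and the
#' eventual lower bound \eqn{N}.
#'
#' For the lower bound two variants are reported. `N_printed` uses the
#' exponent \eqn{\xi A} exactly as in the source formulas,
#' \eqn{(a - \xi A) / (e^{\xi A} D)}; that chain is only valid for
#' \eqn{\xi \ge 0}, while \eqn{h_k \ge 0} gives \eqn{\xi \le 0}, so
#' `N_printed` can exceed the true infimum. `N` uses the validity-corrected
#' exponent \eqn{\xi^+ = \max(\xi, 0)} (for \eqn{h \ge 0} this is
#' \eqn{N = a / D}), which is a true eventual lower bound; all
#' trajectory-containment diagnostics use `N`. The same correction is applied
#' to the closed-form orbit bracket (`ap_lower` vs `ap_lower_printed`).
#'
#' @param params An [impulsive_logistic()].
#' @param A Counting constant of the schedule; computed by [schedule_A()]
#'   when `NULL`.
#' @return An object of class `scalar_bounds` with elements
#'   `xi, alpha, theta, eta, A, B, D, M, N` (and the `_printed` /
#'   `ap_*` extras described above).
#' @export
logistic_scalar_bounds <- function(params, A = NULL) {
  stopifnot(inherits(params, "impulsive_logistic"))
  a <- params$a; b <- params$b; tau <- params$delay
  stopifnot(a > 0, b > 0)
  pts <- params$schedule$points
  hv <- if (length(pts)) params$schedule$h[, 1] else numeric(0)
  if (is.null(A)) A <- schedule_A(params$schedule)
  xi <- .schedule_xi(hv)
  xip <- max(xi, 0)
  eta <- .schedule_eta(hv)
  theta <- schedule_theta(params$schedule)
  wex <- .window_prod_extrema(pts, hv, tau)
  B <- b * wex[1] * exp(-a * tau)
  M <- a / (eta * B * (1 - exp(-a * theta)))
  if (!is.finite(M) || M <= 0) stop("upper bound M is undefined or nonpositive")
  D <- b * wex[2] * exp(-(a - b * M) * tau)
  structure(list(
    a = a, b = b, delay = tau,
    xi = xi, xi_plus = xip, alpha = a - xi * A, alpha_plus = a - xip * A,
    theta = theta, eta = eta, A = A, B = B, D = D, M = M,
    N = (a - xip * A) / (exp(xip * A) * D),
    N_printed = (a - xi * A) / (exp(xi * A) * D),
    ap_lower = (a - xip * A) / (exp(xip * A) * b),
    ap_lower_printed = (a - xi * A) / (exp(xi * A) * b),
    ap_upper = a / (eta * b * (1 - exp(-a * theta)))),
    class = "scalar_bounds")
}

#' @export
print.scalar_bounds <- function(x, ...) {
  cat(sprintf("<scalar_bounds> M = %g, N = %g (printed %g), xi = %g, eta = %g, theta = %g, A = %d\n",
              x$M, x$N, x$N_printed, x$xi, x$eta, x$theta, x$A))
  invisible(x)
}
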