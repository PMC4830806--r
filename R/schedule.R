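#' Impulse schedule with per-species jump coefficients
#'
#' A finite, strictly increasing sequence of impulse times \eqn{\tau_k} over a
#' stated horizon, together with the multiplicative jump coefficients
#' \eqn{h_{ik} \ge 0} per species: at \eqn{t = \tau_k} the state jumps as
#' \eqn{x_i(\tau_k^+) = (1 + h_{ik}) x_i(\tau_k)}.
#'
#' All schedules in this package are finite (horizon-limited); infima and
#' suprema over the impulse index are taken over the generated window. The
#' empty schedule is the no-impulse limit: every impulse product is 1,
#' \eqn{\theta = +\infty}, \eqn{\xi = 0}, \eqn{\eta = 1}, \eqn{A = 0}.
#'
#' @param points Strictly increasing numeric vector of impulse times (may be
#'   empty).
#' @param h Jump coefficients: a numeric vector (one species, or recycled per
#'   point) or a matrix with `length(points)` rows and one column per
#'   species. All entries must satisfy `1 + h > 0` (the model setting has
#'   `h >= 0`).
#' @param horizon Length-2 numeric, the time interval the schedule covers.
#'   Defaults to the range of `points` (or `c(0, 0)` when empty).
#' @param base_period,jitter_amplitude,jitter_frequency Generator metadata
#'   (see [schedule_generate()]); `NA` for hand-built schedules.
#' @return An object of class `impulse_schedule`.
#' @export
impulse_schedule <- function(points, h = numeric(0),
                             horizon = NULL,
                             base_period = NA_real_,
                             jitter_amplitude = NA_real_,
                             jitter_frequency = NA_real_) {
  points <- as.numeric(points)
  if (is.unsorted(points, strictly = TRUE))
    stop("impulse points must be strictly increasing")
  if (length(points) > 1L && min(diff(points)) <= 0)
    stop("impulse gaps must be positive")
  if (is.matrix(h)) {
    if (length(points) && nrow(h) != length(points))
      stop("h must have one row per impulse point")
  } else {
    h <- matrix(rep_len(as.numeric(h), max(length(points), 0L) *
                          max(1L, NCOL(h))),
                nrow = length(points))
    if (length(points) == 0L) h <- matrix(numeric(0), nrow = 0, ncol = 1)
  }
  if (length(h) && any(1 + h <= 0)) stop("all jump coefficients need 1 + h > 0")
  if (is.null(horizon))
    horizon <- if (length(points)) range(points) else c(0, 0)
  structure(list(points = points, h = h, horizon = as.numeric(horizon),
                 base_period = base_period,
                 jitter_amplitude = jitter_amplitude,
                 jitter_frequency = jitter_frequency),
            class = "impulse_schedule")
}

#' @export
print.impulse_schedule <- function(x, ...) {
  cat(sprintf("<impulse_schedule> %d point(s) on [%g, %g], %d species, theta = %g\n",
              length(x$points), x$horizon[1], x$horizon[2], ncol(x$h),
              schedule_theta(x)))
  invisible(x)
}

#' Generate an almost periodic impulse schedule
#'
#' Builds \eqn{\tau_k = k P + J \sin(\nu k)} for integer \eqn{k \ge 0} within
#' the horizon: a base period \eqn{P} with a deterministic sinusoidal jitter
#' in the index \eqn{k}, which guarantees by construction that the family of
#' difference sequences \eqn{\tau_{k+j} - \tau_k} is uniformly almost
#' periodic. Jump coefficients are constant per species.
#'
#' @param base_period Base spacing \eqn{P > 0}; must exceed
#'   `2 * jitter_amplitude` so gaps stay positive.
#' @param jitter_amplitude Jitter amplitude \eqn{J \ge 0} (time units).
#' @param jitter_frequency Jitter angular frequency \eqn{\nu} (per index).
#' @param h1,h2 Constant jump coefficients for species 1 and 2 (`h2 = NULL`
#'   for a single-species schedule); both `>= 0`.
#' @param horizon Length-2 numeric interval to cover.
#' @param seed Reserved for future stochastic jitter; the generator is fully
#'   deterministic in its arguments.
#' @return An [impulse_schedule()].
#' @examples
#' s <- schedule_generate(5, 0, 0, h1 = 0.5, h2 = 0.4, horizon = c(0, 100))
#' schedule_theta(s)  # 5
#' @export
schedule_generate <- function(base_period, jitter_amplitude = 0,
                              jitter_frequency = 0, h1 = 0, h2 = NULL,
                              horizon = c(0, 100), seed = NULL) {
  stopifnot(base_period > 2 * jitter_amplitude, jitter_amplitude >= 0,
            h1 >= 0, is.null(h2) || h2 >= 0)
  kmax <- floor((horizon[2] + jitter_amplitude) / base_period) + 1L
  k <- 0:kmax
  pts <- k * base_period + jitter_amplitude * sin(jitter_frequency * k)
  keep <- pts >= horizon[1] & pts <= horizon[2]
  pts <- pts[keep]
  if (length(pts) > 1L && min(diff(pts)) <= 0)
    stop("generated schedule has nonpositive gaps")
  h <- if (is.null(h2)) matrix(h1, length(pts), 1)
       else cbind(rep(h1, length(pts)), rep(h2, length(pts)))
  impulse_schedule(pts, h, horizon = horizon, base_period = base_period,
                   jitter_amplitude = jitter_amplitude,
                   jitter_frequency = jitter_frequency)
}

#' Minimal consecutive gap of a schedule
#'
#' \eqn{\theta = \inf_k (\tau_{k+1} - \tau_k)} over the generated window;
#' `Inf` for an empty or single-point schedule (the no-impulse convention, so
#' that \eqn{1 - e^{-a\theta} \to 1} in the bound formulas).
#'
#' @param schedule An [impulse_schedule()].
#' @return A single number, possibly `Inf`.
#' @export
schedule_theta <- function(schedule) {
  stopifnot(inherits(schedule, "impulse_schedule"))
  if (length(schedule$points) < 2L) return(Inf)
  min(diff(schedule$points))
}

#' Counting constant A of an impulse schedule
#'
#' The minimal nonnegative integer \eqn{A} such that the number of impulse
#' points in every open interval \eqn{(s, t)} inside the horizon satisfies
#' \eqn{i(s,t) \le A (t - s) + A}. Computed by exhaustive scanning over all
#' point-index pairs: an open window containing points
#' \eqn{\tau_i, \dots, \tau_j} has length greater than \eqn{\tau_j - \tau_i},
#' so the binding constraint per pair is
#' \eqn{(j - i + 1) \le A (\tau_j - \tau_i + 1)}.
#'
#' @param schedule An [impulse_schedule()].
#' @param horizon Optional length-2 interval restricting which points are
#'   scanned (defaults to the schedule horizon).
#' @return Integer `A >= 0` (0 for an empty schedule).
#' @export
schedule_A <- function(schedule, horizon = NULL) {
  stopifnot(inherits(schedule, "impulse_schedule"))
  pts <- schedule$points
  if (!is.null(horizon)) pts <- pts[pts >= horizon[1] & pts <= horizon[2]]
  n <- length(pts)
  if (n == 0L) return(0L)
  ratio <- 1  # singleton windows: 1 point, infimal length 0
  for (i in seq_len(n)) {
    j <- i:n
    ratio <- max(ratio, max((j - i + 1) / (pts[j] - pts[i] + 1)))
  }
  as.integer(ceiling(ratio - 1e-12))
}

## ---- internal impulse-window machinery -------------------------------------

# Count impulse points in the half-open window [t - tau, t) for each t.
.window_count <- function(points, t, tau) {
  vapply(t, function(ti) sum(points >= ti - tau & points < ti), numeric(1))
}

# Extrema over t of the product  prod_{tau_k in [t - tau, t)} (1 + h_k)^(-1).
# The product is piecewise constant in t with breakpoints at tau_k and
# tau_k + tau (point k is inside the window for t in (tau_k, tau_k + tau]);
# breakpoints are enumerated exactly and each elementary interval is
# evaluated at its right endpoint. Window positions with no impulse (before
# the first point, after the last + tau) contribute the empty product 1.
.window_prod_extrema <- function(points, hvec, tau) {
  if (length(points) == 0L || tau <= 0) return(c(1, 1))
  cand <- sort(unique(c(points, points + tau)))
  vals <- vapply(cand, function(t) {
    inside <- points < t & points >= t - tau
    if (!any(inside)) 1 else prod(1 / (1 + hvec[inside]))
  }, numeric(1))
  vals <- c(vals, 1)  # empty-window positions always exist on a finite horizon
  c(min(vals), max(vals))
}

# xi = ln sup_k 1/(1 + h_k)  (<= 0 when h >= 0); 0 for the empty schedule.
.schedule_xi <- function(hvec) {
  if (length(hvec) == 0L) return(0)
  -log1p(min(hvec))
}

# eta = inf_k min{ prod_{j=0}^{1} 1/(1 + h_{k+j}), 1 }: the two-consecutive-
# factor product, capped at 1; 1 for the empty schedule. The source notation
# block starts the product at j = 0 and a later restatement at j = 1; both
# are two-term products and coincide for stationary h (the package uses the
# j = 0 form, with a single-factor fallback for one-point schedules).
.schedule_eta <- function(hvec) {
  n <- length(hvec)
  if (n == 0L) return(1)
  if (n == 1L) return(min(1 / (1 + hvec), 1))
  pair <- 1 / ((1 + hvec[-n]) * (1 + hvec[-1]))
  min(c(pair, 1))
}
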