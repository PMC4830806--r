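#' Two-species impulsive delayed Schoener competition model
#'
#' The full parameterization of the hybrid system
#' \deqn{\dot x_1 = x_1\Big[\frac{a_{10}(t)}{x_1(t-\tau_{10}) + m_1(t)}
#'   - a_{11}(t)\,x_1(t-\tau_{11}) - a_{12}(t)\,x_2(t-\tau_{12}) - c_1(t)\Big],}
#' \deqn{\dot x_2 = x_2\Big[\frac{a_{20}(t)}{x_2(t-\tau_{20}) + m_2(t)}
#'   - a_{21}(t)\,x_1(t-\tau_{21}) - a_{22}(t)\,x_2(t-\tau_{22}) - c_2(t)\Big],}
#' for \eqn{t \ne \tau_k}, with multiplicative jumps
#' \eqn{x_i(\tau_k^+) = (1 + h_{ik})\, x_i(\tau_k)}. All ten coefficient
#' functions are positive quasi-periodic coefficients; \eqn{a_{i0}} is the
#' saturating resource supply, \eqn{m_i} the half-saturation density,
#' \eqn{a_{ii}} / \eqn{a_{ij}} the intra-/inter-specific competition rates and
#' \eqn{c_i} the net death rate. Delays \eqn{\tau_{ij} \ge 0} retard every
#' state on the right-hand side ("pure delays").
#'
#' @param a10,a20,a11,a12,a21,a22,m1,m2,c1,c2 [qp_coef()] objects (plain
#'   positive numbers are promoted to constant coefficients).
#' @param delays Named numeric vector with entries
#'   `tau10, tau11, tau12, tau20, tau21, tau22`, all `>= 0`.
#' @param schedule An [impulse_schedule()] with two species columns.
#' @return An object of class `schoener_model`; its element `tau_max` is the
#'   history depth \eqn{\tau = \max 2\tau_{ij}}.
#' @export
schoener_model <- function(a10, a20, a11, a12, a21, a22, m1, m2, c1, c2,
                           delays, schedule) {
  as_coef <- function(x, pos = TRUE)
    if (inherits(x, "qp_coef")) x else qp_coef(x, positive = pos)
  coefs <- list(a10 = as_coef(a10), a20 = as_coef(a20),
                a11 = as_coef(a11),
                # cross-competition may be absent (zero)
                a12 = as_coef(a12, pos = FALSE),
                a21 = as_coef(a21, pos = FALSE),
                a22 = as_coef(a22), m1 = as_coef(m1), m2 = as_coef(m2),
                c1 = as_coef(c1), c2 = as_coef(c2))
  for (nm in setdiff(names(coefs), c("a12", "a21")))
    if (coef_bounds(coefs[[nm]])[1] <= 0)
      stop("coefficient ", nm, " must have strictly positive infimum")
  for (nm in c("a12", "a21")) {
    coefs[[nm]]$positive <- FALSE
    if (coef_bounds(coefs[[nm]])[1] < 0)
      stop("coefficient ", nm, " must be nonnegative")
  }
  need <- c("tau10", "tau11", "tau12", "tau20", "tau21", "tau22")
  if (!all(need %in% names(delays))) stop("delays must name ", toString(need))
  delays <- vapply(need, function(nm) as.numeric(delays[[nm]]), numeric(1))
  if (any(delays < 0)) stop("delays must be nonnegative")
  stopifnot(inherits(schedule, "impulse_schedule"))
  if (length(schedule$points) && ncol(schedule$h) != 2L)
    stop("schedule must carry jump coefficients for two species")
  structure(c(coefs, list(delays = delays, schedule = schedule,
                          tau_max = max(2 * delays))),
            class = "schoener_model")
}

#' @export
print.schoener_model <- function(x, ...) {
  cat(sprintf("<schoener_model> tau_max = %g, %d impulse point(s)\n",
              x$tau_max, length(x$schedule$points)))
  invisible(x)
}

#' The packaged worked-example model
#'
#' The two-species scenario with \eqn{a_{10} = a_{20} \equiv 1},
#' \eqn{m_1 = m_2 \equiv 2}, \eqn{a_{11}(t) = a_{22}(t) = 0.35 + 0.05\cos(\sqrt 3 t)},
#' \eqn{a_{12} = a_{21} \equiv 10^{-4}},
#' \eqn{c_1(t) = 0.30005 + 5\cdot 10^{-5}\sin(\sqrt 2 t)},
#' \eqn{c_2(t) = 0.30005 + 5\cdot 10^{-5}\cos(\sqrt 2 t)}, delays of
#' \eqn{10^{-4}} (own-species terms) and \eqn{2 \cdot 10^{-4}} (cross terms),
#' jumps \eqn{h_{1k} = 0.5}, \eqn{h_{2k} = 0.4} at \eqn{\tau_k = 5k}.
#'
#' @param horizon Length-2 interval the impulse schedule should cover.
#' @return A [schoener_model()].
#' @export
example1_model <- function(horizon = c(0, 200)) {
  schoener_model(
    a10 = 1, a20 = 1, m1 = 2, m2 = 2,
    a11 = qp_coef(0.35, 0.05, sqrt(3), waveform = "cos"),
    a22 = qp_coef(0.35, 0.05, sqrt(3), waveform = "cos"),
    a12 = 1e-4, a21 = 1e-4,
    c1 = qp_coef(0.30005, 5e-5, sqrt(2), waveform = "sin"),
    c2 = qp_coef(0.30005, 5e-5, sqrt(2), waveform = "cos"),
    delays = c(tau10 = 1e-4, tau11 = 1e-4, tau12 = 2e-4,
               tau20 = 1e-4, tau21 = 2e-4, tau22 = 1e-4),
    schedule = schedule_generate(5, 0, 0, h1 = 0.5, h2 = 0.4,
                                 horizon = horizon))
}

#' Seeded generator of random weak-competition scenarios
#'
#' Draws a two-species model in the weak-competition, mild-impulse regime:
#' interspecific rates two to four orders of magnitude below intraspecific
#' ones, impulse magnitudes `h <= h_max` (default 0.1), period-`base_period`
#' schedules with optional deterministic jitter, and short delays. In this
#' regime the permanence condition H1 holds with a strictly positive growth
#' infimum, so the certified bounds are informative; see the methods vignette
#' for the rationale behind each default range.
#'
#' @param seed Integer seed; the model is a deterministic function of it.
#' @param horizon Interval the schedule should cover.
#' @param h_max Upper end of the uniform range for the jump coefficients.
#' @param base_period Impulse base period.
#' @param delay_max Upper end of the uniform range for each delay.
#' @return A [schoener_model()].
#' @export
random_weak_model <- function(seed, horizon = c(0, 200), h_max = 0.1,
                              base_period = 5, delay_max = 1e-3) {
  set.seed(seed)
  rc <- function(lo, hi, amp_max) {
    const <- stats::runif(1, lo, hi)
    qp_coef(const, stats::runif(1, 0, amp_max), stats::runif(1, 0.5, 2),
            stats::runif(1, 0, 2 * pi),
            waveform = sample(c("sin", "cos"), 1))
  }
  m <- list(
    a10 = rc(0.9, 1.1, 0.02), a20 = rc(0.9, 1.1, 0.02),
    m1 = rc(1.8, 2.2, 0.05), m2 = rc(1.8, 2.2, 0.05),
    a11 = rc(0.8, 1.2, 0.05), a22 = rc(0.8, 1.2, 0.05),
    a12 = rc(2e-4, 5e-4, 5e-5), a21 = rc(2e-4, 5e-4, 5e-5),
    c1 = rc(0.08, 0.12, 0.005), c2 = rc(0.08, 0.12, 0.005))
  delays <- stats::runif(6, 0, delay_max)
  names(delays) <- c("tau10", "tau11", "tau12", "tau20", "tau21", "tau22")
  sched <- schedule_generate(base_period,
                             jitter_amplitude = stats::runif(1, 0, 0.5),
                             jitter_frequency = sqrt(2),
                             h1 = stats::runif(1, 0, h_max),
                             h2 = stats::runif(1, 0, h_max),
                             horizon = horizon)
  schoener_model(a10 = m$a10, a20 = m$a20, a11 = m$a11, a12 = m$a12,
                 a21 = m$a21, a22 = m$a22, m1 = m$m1, m2 = m$m2,
                 c1 = m$c1, c2 = m$c2, delays = delays, schedule = sched)
}
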