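#' Quasi-periodic coefficient: constant plus trigonometric harmonics
#'
#' Represents a bounded time-varying model coefficient of the form
#' \deqn{f(t) = c + \sum_m A_m \, w_m(\omega_m t + \varphi_m),}
#' where each waveform \eqn{w_m} is `sin` or `cos`. With incommensurate
#' angular frequencies this is the standard constructive family of almost
#' periodic functions, and its exact range is certified by the amplitude
#' bounds \eqn{[c - \sum |A_m|,\; c + \sum |A_m|]}.
#'
#' @param constant Constant term \eqn{c}.
#' @param amplitude,frequency,phase Numeric vectors (recycled to a common
#'   length) giving each harmonic's amplitude, angular frequency (radians per
#'   unit time) and phase (radians). May be empty for a constant coefficient.
#' @param waveform Character vector, `"sin"` or `"cos"` per harmonic.
#' @param positive If `TRUE` (default), require the certified infimum
#'   \eqn{c - \sum |A_m|} to be strictly positive and error otherwise.
#'
#' @return An object of class `qp_coef`.
#' @examples
#' a11 <- qp_coef(0.35, 0.05, sqrt(3), waveform = "cos")
#' coef_eval(a11, 0)        # 0.4
#' coef_bounds(a11)         # c(0.3, 0.4)
#' @export
qp_coef <- function(constant, amplitude = numeric(0), frequency = numeric(0),
                    phase = 0, waveform = "cos", positive = TRUE) {
  stopifnot(is.numeric(constant), length(constant) == 1L, is.finite(constant))
  nh <- max(length(amplitude), length(frequency),
            if (length(amplitude) || length(frequency)) length(phase) else 0L)
  if (nh > 0L) {
    amplitude <- rep_len(amplitude, nh)
    frequency <- rep_len(frequency, nh)
    phase <- rep_len(phase, nh)
    waveform <- rep_len(waveform, nh)
    if (!all(waveform %in% c("sin", "cos")))
      stop("waveform must be 'sin' or 'cos'")
  } else {
    amplitude <- frequency <- phase <- numeric(0)
    waveform <- character(0)
  }
  obj <- structure(
    list(constant = constant, amplitude = amplitude, frequency = frequency,
         phase = phase, waveform = waveform, positive = isTRUE(positive)),
    class = "qp_coef")
  if (isTRUE(positive) && constant - sum(abs(amplitude)) <= 0)
    stop("coefficient flagged positive has nonpositive analytic infimum ",
         constant - sum(abs(amplitude)))
  obj
}

#' @export
print.qp_coef <- function(x, ...) {
  b <- coef_bounds(x)
  cat(sprintf("<qp_coef> constant %g, %d harmonic(s), range [%g, %g]\n",
              x$constant, length(x$amplitude), b[1], b[2]))
  invisible(x)
}

#' Evaluate a quasi-periodic coefficient
#'
#' @param coef A [qp_coef()] object (plain numbers are accepted and treated
#'   as constants).
#' @param t Numeric vector of times.
#' @return Numeric vector of the same length as `t`.
#' @export
coef_eval <- function(coef, t) {
  if (is.numeric(coef)) return(rep_len(coef, length(t)))
  stopifnot(inherits(coef, "qp_coef"))
  out <- rep_len(coef$constant, length(t))
  for (m in seq_along(coef$amplitude)) {
    arg <- coef$frequency[m] * t + coef$phase[m]
    w <- if (coef$waveform[m] == "sin") sin(arg) else cos(arg)
    out <- out + coef$amplitude[m] * w
  }
  out
}

#' Certified infimum and supremum of a coefficient
#'
#' Analytic mode returns the amplitude bounds
#' \eqn{(c - \sum|A_m|,\; c + \sum|A_m|)}, which equal the exact range for a
#' constant or single-harmonic coefficient and contain it otherwise; this is
#' the certified interval used by all theory computations. Sampled mode
#' returns empirical extrema over a dense time grid (a diagnostic; always a
#' sub-interval of the analytic one).
#'
#' @inheritParams coef_eval
#' @param mode `"analytic"` (default) or `"sampled"`.
#' @param horizon Length-2 numeric, sampling window for `mode = "sampled"`.
#' @param n Number of grid points for `mode = "sampled"`.
#' @return Numeric vector `c(inf, sup)`.
#' @export
coef_bounds <- function(coef, mode = c("analytic", "sampled"),
                        horizon = c(0, 1000), n = 100001L) {
  mode <- match.arg(mode)
  if (is.numeric(coef)) return(c(coef, coef))
  stopifnot(inherits(coef, "qp_coef"))
  amp <- sum(abs(coef$amplitude))
  lo <- coef$constant - amp
  if (coef$positive && lo <= 0)
    stop("coefficient required positive has nonpositive analytic infimum")
  if (mode == "analytic") return(c(lo, coef$constant + amp))
  v <- coef_eval(coef, seq(horizon[1], horizon[2], length.out = n))
  c(min(v), max(v))
}
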