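#' Supremum of the per-capita growth magnitude
#'
#' \eqn{r_i^u = \sup_t |a_{i0}(t)/m_i(t) - c_i(t)|}, the growth-rate constant
#' driving the eventual upper bounds. Computed conservatively by interval
#' arithmetic on the certified coefficient bounds
#' (\eqn{\sup |f| \le \max(|\mathrm{lo}|, |\mathrm{hi}|)} of the enclosing
#' interval), with a dense-sampling refinement mode for diagnostics.
#'
#' @param model A [schoener_model()].
#' @param mode `"analytic"` (default, certified) or `"sampled"`.
#' @param horizon,n Sampling window and density for `mode = "sampled"`.
#' @return Named numeric vector `c(r1_u, r2_u)`.
#' @export
growth_suprema <- function(model, mode = c("analytic", "sampled"),
                           horizon = c(0, 1000), n = 100001L) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "schoener_model"))
  one <- function(a0, m, cc) {
    if (mode == "analytic") {
      ab <- coef_bounds(a0); mb <- coef_bounds(m); cb <- coef_bounds(cc)
      lo <- ab[1] / mb[2] - cb[2]
      hi <- ab[2] / mb[1] - cb[1]
      max(abs(lo), abs(hi))
    } else {
      tt <- seq(horizon[1], horizon[2], length.out = n)
      max(abs(coef_eval(a0, tt) / coef_eval(m, tt) - coef_eval(cc, tt)))
    }
  }
  c(r1_u = one(model$a10, model$m1, model$c1),
    r2_u = one(model$a20, model$m2, model$c2))
}

#' Permanence bounds for the impulsive delayed Schoener system
#'
#' Computes, per species, the constants of the two-sided comparison argument:
#' \deqn{M_i = \frac{r_i^u}{\eta_i B_i (1 - e^{-r_i^u \theta})}, \qquad
#'       B_i = \inf_t\, a_{ii}^l \prod_{\tau_k \in [t - \tau_{ii},\, t)}
#'             (1 + h_{ik})^{-1} e^{-r_i^u \tau_{ii}},}
#' \deqn{r_i^l = \inf_t \Big[\frac{a_{i0}(t)}{M_i + m_i(t)}
#'       - a_{ij}(t) M_j - c_i(t)\Big], \qquad
#'       D_i = \sup_t\, a_{ii}^u \prod (1 + h_{ik})^{-1}
#'             e^{-(r_i^l - a_{ii}^u M_i) \tau_{ii}},}
#' and the eventual lower bounds \eqn{N_i}. All suprema/infima over `t` use
#' interval arithmetic on the certified coefficient bounds.
#'
#' As in [logistic_scalar_bounds()], `N1`/`N2` use the validity-corrected
#' exponent \eqn{\xi_i^+ = \max(\xi_i, 0)} and are true eventual lower bounds
#' under H1 with \eqn{r_i^l > 0}; `N1_printed`/`N2_printed` evaluate the
#' source formula verbatim (exponent \eqn{\xi_i A} with \eqn{\xi_i \le 0}
#' when \eqn{h \ge 0}), which can exceed the true infimum.
#'
#' @param model A [schoener_model()].
#' @param A Counting constant; computed from the schedule when `NULL`.
#' @return An object of class `permanence_bounds`.
#' @export
permanence_bounds <- function(model, A = NULL) {
  stopifnot(inherits(model, "schoener_model"))
  sch <- model$schedule
  pts <- sch$points
  h1 <- if (length(pts)) sch$h[, 1] else numeric(0)
  h2 <- if (length(pts)) sch$h[, 2] else numeric(0)
  if (is.null(A)) A <- schedule_A(sch)
  theta <- schedule_theta(sch)
  r_u <- growth_suprema(model)
  if (any(r_u <= 0)) stop("degenerate model: r_i^u must be positive")

  one_M <- function(aii, hv, tau, ru) {
    eta <- .schedule_eta(hv)
    B <- coef_bounds(aii)[1] * .window_prod_extrema(pts, hv, tau)[1] *
      exp(-ru * tau)
    M <- ru / (eta * B * (1 - exp(-ru * theta)))
    list(eta = eta, B = B, M = M)
  }
  s1 <- one_M(model$a11, h1, model$delays[["tau11"]], r_u[["r1_u"]])
  s2 <- one_M(model$a22, h2, model$delays[["tau22"]], r_u[["r2_u"]])

  r_l <- c(
    coef_bounds(model$a10)[1] / (s1$M + coef_bounds(model$m1)[2]) -
      coef_bounds(model$a12)[2] * s2$M - coef_bounds(model$c1)[2],
    coef_bounds(model$a20)[1] / (s2$M + coef_bounds(model$m2)[2]) -
      coef_bounds(model$a21)[2] * s1$M - coef_bounds(model$c2)[2])

  one_N <- function(aii, hv, tau, rl, M) {
    au <- coef_bounds(aii)[2]
    D <- au * .window_prod_extrema(pts, hv, tau)[2] *
      exp(-(rl - au * M) * tau)
    xi <- .schedule_xi(hv)
    xip <- max(xi, 0)
    list(xi = xi, D = D,
         N = (rl - xip * A) / (exp(xip * A) * D),
         N_printed = (rl - xi * A) / (exp(xi * A) * D))
  }
  n1 <- one_N(model$a11, h1, model$delays[["tau11"]], r_l[1], s1$M)
  n2 <- one_N(model$a22, h2, model$delays[["tau22"]], r_l[2], s2$M)

  structure(list(
    r1_u = r_u[["r1_u"]], r2_u = r_u[["r2_u"]],
    r1_l = r_l[1], r2_l = r_l[2],
    B1 = s1$B, B2 = s2$B, D1 = n1$D, D2 = n2$D,
    eta1 = s1$eta, eta2 = s2$eta, xi1 = n1$xi, xi2 = n2$xi,
    theta = theta, A = A,
    M1 = s1$M, M2 = s2$M, N1 = n1$N, N2 = n2$N,
    N1_printed = n1$N_printed, N2_printed = n2$N_printed),
    class = "permanence_bounds")
}

#' @export
print.permanence_bounds <- function(x, ...) {
  cat(sprintf("<permanence_bounds> M = (%.4g, %.4g), N = (%.4g, %.4g), r^l = (%.4g, %.4g), A = %d\n",
              x$M1, x$M2, x$N1, x$N2, x$r1_l, x$r2_l, x$A))
  invisible(x)
}

#' Check the permanence condition H1
#'
#' H1 as printed: \eqn{r_i^l \ge \xi_i A} for both species. Because
#' \eqn{\xi_i \le 0} when \eqn{h \ge 0}, the printed condition does not by
#' itself make the lower bound meaningful; the comparison chain behind
#' \eqn{N_i} additionally needs a strictly positive growth infimum, reported
#' here as `strict` (\eqn{r_i^l > 0}, equivalently the corrected
#' \eqn{N_i > 0}). Permanence is certified when both hold.
#'
#' @param bounds A [permanence_bounds()].
#' @return List with `holds` (printed H1), `margins`
#'   (\eqn{r_i^l - \xi_i A}), and `strict`.
#' @export
check_H1 <- function(bounds) {
  stopifnot(inherits(bounds, "permanence_bounds"))
  m <- c(bounds$r1_l - bounds$xi1 * bounds$A,
         bounds$r2_l - bounds$xi2 * bounds$A)
  list(holds = all(m >= 0), margins = m,
       strict = bounds$r1_l > 0 && bounds$r2_l > 0)
}

#' Lyapunov-functional stability constants
#'
#' Evaluates the four constants entering the stability condition H2:
#' \deqn{\alpha_1 = \frac{a_{10}^l N_1}{(M_1 + m_1^u)^2} + a_{11}^l N_1
#'  - \Big(\frac{\sqrt{\tau_{10}}\, a_{10}^u M_1}{(N_1 + m_1^l)^2}\Big)^2
#'  - \frac{(\tau_{10} + \tau_{11}) a_{10}^u a_{11}^u M_1^2}{(N_1 + m_1^l)^2}
#'  - \tau_{11}\, (a_{11}^u)^2 M_1^2}
#' (and symmetrically for \eqn{\alpha_2}), with the cross terms
#' \deqn{\beta_1 = \frac{\tau_{20} a_{20}^u a_{21}^u M_1 M_2}{(N_2 + m_2^l)^2}
#'  + \tau_{22} a_{21}^u a_{22}^u M_1 M_2 + a_{21}^u M_1, \qquad
#' \beta_2 = \frac{\tau_{10} a_{10}^u a_{12}^u M_1 M_2}{(N_1 + m_1^l)^2}
#'  + \tau_{11} a_{11}^u a_{12}^u M_1 M_2 + a_{12}^u M_2.}
#'
#' @param model A [schoener_model()].
#' @param bounds A [permanence_bounds()], or any list carrying positive
#'   `M1, M2, N1, N2` (externally supplied window).
#' @return Named numeric vector `c(alpha1, alpha2, beta1, beta2)`.
#' @export
stability_constants <- function(model, bounds) {
  stopifnot(inherits(model, "schoener_model"))
  M1 <- bounds$M1; M2 <- bounds$M2; N1 <- bounds$N1; N2 <- bounds$N2
  if (is.null(N1) || is.null(N2) || N1 <= 0 || N2 <= 0)
    stop("stability constants require positive lower bounds N_i")
  b <- lapply(model[c("a10", "a20", "a11", "a12", "a21", "a22",
                      "m1", "m2", "c1", "c2")], coef_bounds)
  d <- model$delays
  alpha1 <- b$a10[1] * N1 / (M1 + b$m1[2])^2 + b$a11[1] * N1 -
    (sqrt(d[["tau10"]]) * b$a10[2] * M1 / (N1 + b$m1[1])^2)^2 -
    (d[["tau10"]] + d[["tau11"]]) * b$a10[2] * b$a11[2] * M1^2 /
      (N1 + b$m1[1])^2 -
    d[["tau11"]] * b$a11[2]^2 * M1^2
  alpha2 <- b$a20[1] * N2 / (M2 + b$m2[2])^2 + b$a22[1] * N2 -
    (sqrt(d[["tau20"]]) * b$a20[2] * M2 / (N2 + b$m2[1])^2)^2 -
    (d[["tau20"]] + d[["tau22"]]) * b$a20[2] * b$a22[2] * M2^2 /
      (N2 + b$m2[1])^2 -
    d[["tau22"]] * b$a22[2]^2 * M2^2
  beta1 <- d[["tau20"]] * b$a20[2] * b$a21[2] * M1 * M2 /
    (N2 + b$m2[1])^2 +
    d[["tau22"]] * b$a21[2] * b$a22[2] * M1 * M2 + b$a21[2] * M1
  beta2 <- d[["tau10"]] * b$a10[2] * b$a12[2] * M1 * M2 /
    (N1 + b$m1[1])^2 +
    d[["tau11"]] * b$a11[2] * b$a12[2] * M1 * M2 + b$a12[2] * M2
  c(alpha1 = alpha1, alpha2 = alpha2, beta1 = beta1, beta2 = beta2)
}

#' Check the stability condition H2 and pick canonical multipliers
#'
#' H2 asks for positive \eqn{\lambda_1, \lambda_2} with
#' \eqn{\lambda_1 \alpha_1 > \lambda_2 \beta_1} and
#' \eqn{\lambda_2 \alpha_2 > \lambda_1 \beta_2}. Such multipliers exist iff
#' \eqn{\alpha_1, \alpha_2 > 0} and
#' \eqn{\alpha_1 \alpha_2 > \beta_1 \beta_2}: the ratio
#' \eqn{\lambda_1/\lambda_2} must lie in the open interval
#' \eqn{(\beta_1/\alpha_1,\ \alpha_2/\beta_2)}. When feasible, the returned
#' \eqn{\lambda} is normalized to \eqn{\lambda_2 = 1} with the ratio at the
#' geometric mean of the interval endpoints (degenerate endpoints 0 and
#' \eqn{\infty} are replaced by the documented canonical fallbacks, so the
#' choice is reproducible).
#'
#' @param alpha1,alpha2,beta1,beta2 The constants from
#'   [stability_constants()] (`beta_i >= 0`).
#' @return An object of class `stability_report`: the inputs, `feasible`,
#'   `lambda1`, `lambda2` (`NA` if infeasible), the margin
#'   `Theta = min(lambda1 alpha1 - lambda2 beta1, lambda2 alpha2 - lambda1 beta2)`
#'   and `ratio_interval`.
#' @export
check_H2 <- function(alpha1, alpha2, beta1, beta2) {
  stopifnot(beta1 >= 0, beta2 >= 0)
  feasible <- alpha1 > 0 && alpha2 > 0 && alpha1 * alpha2 > beta1 * beta2
  lo <- if (alpha1 > 0) beta1 / alpha1 else Inf
  hi <- if (beta2 > 0) alpha2 / beta2 else Inf
  lam1 <- lam2 <- Theta <- NA_real_
  if (feasible) {
    ratio <- if (lo > 0 && is.finite(hi)) sqrt(lo * hi)
             else if (lo == 0 && is.finite(hi)) hi / 2
             else if (lo > 0) 2 * lo
             else 1
    lam1 <- ratio; lam2 <- 1
    Theta <- min(lam1 * alpha1 - lam2 * beta1, lam2 * alpha2 - lam1 * beta2)
  }
  structure(list(alpha1 = alpha1, alpha2 = alpha2, beta1 = beta1,
                 beta2 = beta2, feasible = feasible,
                 lambda1 = lam1, lambda2 = lam2, Theta = Theta,
                 ratio_interval = c(lo, hi)),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> %s: alpha = (%.4g, %.4g), beta = (%.4g, %.4g)",
              if (x$feasible) "feasible" else "infeasible",
              x$alpha1, x$alpha2, x$beta1, x$beta2))
  if (x$feasible)
    cat(sprintf(", lambda = (%.4g, 1), Theta = %.4g", x$lambda1, x$Theta))
  cat("\n")
  invisible(x)
}
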