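#' Load and validate a scenario configuration
#'
#' Scenario files are JSON with blocks `coefficients` (name ->
#' `{constant, harmonics: [{amp, freq, phase, waveform}]}` for all ten names
#' `a10, a20, a11, a12, a21, a22, m1, m2, c1, c2`), `delays`
#' (`tau10 ... tau22`), `schedule`
#' (`{base_period, jitter_amplitude, jitter_frequency, h1, h2}`), `horizon`,
#' `initial_history` (`{x1, x2}` constants), and optional `simulation`
#' (`{step, space}`), `analysis` (`{fraction, lambda1, lambda2}`) and `seed`.
#'
#' @param config A path to a JSON file or an already-parsed list.
#' @return A validated list of class `scenario_config`.
#' @export
scenario_config <- function(config) {
  cfg <- if (is.character(config))
    jsonlite::read_json(config, simplifyVector = TRUE)
  else config
  need <- c("coefficients", "delays", "schedule", "horizon",
            "initial_history")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("scenario config is missing block(s): ", toString(miss))
  cnames <- c("a10", "a20", "a11", "a12", "a21", "a22", "m1", "m2",
              "c1", "c2")
  miss <- setdiff(cnames, names(cfg$coefficients))
  if (length(miss)) stop("missing coefficient(s): ", toString(miss))
  dnames <- c("tau10", "tau11", "tau12", "tau20", "tau21", "tau22")
  miss <- setdiff(dnames, names(cfg$delays))
  if (length(miss)) stop("missing delay(s): ", toString(miss))
  if (!all(c("x1", "x2") %in% names(cfg$initial_history)))
    stop("initial_history must give x1 and x2")
  if (length(cfg$horizon) != 2L || cfg$horizon[2] <= cfg$horizon[1])
    stop("horizon must be an increasing length-2 interval")
  structure(cfg, class = "scenario_config")
}

.config_model <- function(cfg) {
  as_coef <- function(spec) {
    h <- spec$harmonics
    if (is.null(h) || (is.data.frame(h) && nrow(h) == 0L) || length(h) == 0L)
      return(qp_coef(spec$constant))
    if (!is.data.frame(h)) h <- do.call(rbind, lapply(h, as.data.frame))
    qp_coef(spec$constant, h$amp, h$freq,
            if (is.null(h$phase)) 0 else h$phase,
            if (is.null(h$waveform)) "cos" else h$waveform)
  }
  coefs <- lapply(cfg$coefficients, as_coef)
  sch <- cfg$schedule
  schedule <- schedule_generate(
    sch$base_period,
    if (is.null(sch$jitter_amplitude)) 0 else sch$jitter_amplitude,
    if (is.null(sch$jitter_frequency)) 0 else sch$jitter_frequency,
    h1 = sch$h1, h2 = sch$h2, horizon = as.numeric(cfg$horizon))
  delays <- unlist(cfg$delays)
  schoener_model(a10 = coefs$a10, a20 = coefs$a20, a11 = coefs$a11,
                 a12 = coefs$a12, a21 = coefs$a21, a22 = coefs$a22,
                 m1 = coefs$m1, m2 = coefs$m2, c1 = coefs$c1, c2 = coefs$c2,
                 delays = delays, schedule = schedule)
}

#' Run a packaged analysis scenario
#'
#' The programmatic entry point behind the command-line script: `simulate`
#' integrates the configured system and (optionally) writes the trajectory
#' CSV plus JSON jump sidecar; `bounds` computes the permanence constants;
#' `check` produces the H1/H2 certification report; `diagnose` runs the
#' trajectory-level diagnostics (tail extrema, invariant-set flag,
#' convergence, Lyapunov checkpoints); `example1` runs the full pipeline on
#' the built-in worked-example parameterization with its published initial
#' histories.
#'
#' @param command One of `"simulate"`, `"bounds"`, `"check"`, `"diagnose"`,
#'   `"example1"`.
#' @param config A [scenario_config()] (path or list); not needed for
#'   `example1`.
#' @param out_dir Optional output directory for artifacts (created if
#'   needed); when `NULL` nothing is written.
#' @param horizon,step Optional overrides of the config values.
#' @return The computed result, invisibly for commands that mainly write
#'   artifacts: a trajectory, a [permanence_bounds()], a certification list,
#'   or a diagnostics list.
#' @export
run_scenario <- function(command = c("simulate", "bounds", "check",
                                     "diagnose", "example1"),
                         config = NULL, out_dir = NULL, horizon = NULL,
                         step = NULL) {
  command <- match.arg(command)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  if (command == "example1") {
    horizon <- if (is.null(horizon)) c(0, 200) else horizon
    step <- if (is.null(step)) 0.01 else step
    model <- example1_model(horizon = horizon)
    history <- initial_history(0.12, 0.02, range = c(-1, 0))
    traj <- integrate_schoener(model, history, horizon, step = step)
    bounds <- permanence_bounds(model)
    h1 <- check_H1(bounds)
    ext <- tail_extrema(traj, 0.25)
    res <- list(model = model, trajectory = traj, bounds = bounds,
                H1 = h1, tail = ext)
    if (!is.null(out_dir)) {
      write_trajectory(traj, file.path(out_dir, "example1_trajectory.csv"),
                       file.path(out_dir, "example1_jumps.json"))
      jsonlite::write_json(
        list(bounds = .report_list(bounds), H1 = h1, tail = ext),
        file.path(out_dir, "example1_report.json"),
        digits = NA, pretty = TRUE, auto_unbox = TRUE)
    }
    return(invisible(res))
  }

  cfg <- scenario_config(config)
  model <- .config_model(cfg)
  horizon <- if (is.null(horizon)) as.numeric(cfg$horizon) else horizon
  step <- if (!is.null(step)) step
          else if (!is.null(cfg$simulation$step)) cfg$simulation$step
          else NULL
  space <- if (!is.null(cfg$simulation$space)) cfg$simulation$space else "log"
  history <- initial_history(cfg$initial_history$x1, cfg$initial_history$x2,
                             range = c(-max(model$tau_max, 1), 0))

  if (command == "simulate") {
    traj <- integrate_schoener(model, history, horizon, step = step,
                               space = space)
    if (!is.null(out_dir))
      write_trajectory(traj, file.path(out_dir, "trajectory.csv"),
                       file.path(out_dir, "jumps.json"))
    return(invisible(traj))
  }

  bounds <- permanence_bounds(model)
  if (command == "bounds") {
    if (!is.null(out_dir))
      jsonlite::write_json(.report_list(bounds),
                           file.path(out_dir, "bounds.json"),
                           digits = NA, pretty = TRUE, auto_unbox = TRUE)
    return(invisible(bounds))
  }

  h1 <- check_H1(bounds)
  h2 <- if (h1$strict) {
    ab <- stability_constants(model, bounds)
    check_H2(ab[["alpha1"]], ab[["alpha2"]], ab[["beta1"]], ab[["beta2"]])
  } else NULL
  cert <- list(bounds = .report_list(bounds), H1 = h1,
               H2 = if (!is.null(h2)) .report_list(h2) else
                 "not evaluated: H1 lacks a strictly positive growth infimum")
  if (command == "check") {
    if (!is.null(out_dir))
      jsonlite::write_json(cert, file.path(out_dir, "certification.json"),
                           digits = NA, pretty = TRUE, auto_unbox = TRUE)
    return(invisible(cert))
  }

  # diagnose: simulate, tail window, invariant set when certified, and a
  # second trajectory from a perturbed history for the convergence curve
  traj <- integrate_schoener(model, history, horizon, step = step,
                             space = space)
  fraction <- if (!is.null(cfg$analysis$fraction)) cfg$analysis$fraction
              else 0.25
  ext <- tail_extrema(traj, fraction)
  hist2 <- initial_history(cfg$initial_history$x1 * 1.2,
                           cfg$initial_history$x2 * 0.8,
                           range = c(-max(model$tau_max, 1), 0))
  traj2 <- integrate_schoener(model, hist2, horizon, step = step,
                              space = space)
  diag <- list(certification = cert, tail = ext,
               pair_terminal = pair_distance(traj, traj2, "terminal"),
               pair_sup = pair_distance(traj, traj2, "sup"))
  if (h1$strict && !is.null(h2) && isTRUE(h2$feasible)) {
    cps <- seq(horizon[1] + model$tau_max + (horizon[2] - horizon[1]) / 10,
               horizon[2], length.out = 8L)
    diag$lyapunov <- lyapunov_checks(traj, traj2, model, bounds,
                                     h2$lambda1, h2$lambda2, cps)
  }
  if (!is.null(out_dir))
    jsonlite::write_json(diag[setdiff(names(diag), "certification")],
                         file.path(out_dir, "diagnostics.json"),
                         digits = NA, pretty = TRUE, auto_unbox = TRUE)
  invisible(diag)
}
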