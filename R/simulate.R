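#' Solver settings
#'
#' Controls for the adaptive stiff-capable integrator (\code{deSolve}'s
#' \code{lsoda}, which switches automatically between non-stiff and stiff
#' methods).  The accuracy contract is that halving both tolerances
#' changes any reported cycle periodicity by less than 0.1\%; the defaults
#' satisfy it with a wide margin.
#'
#' @param rel_tol relative tolerance (dimensionless).
#' @param abs_tol absolute tolerance, scalar or per-state (A, P).
#' @param max_step maximum internal step (yr); \code{Inf} leaves step
#'   selection entirely to the error control.
#' @param resample_dt spacing of the uniform output grid (yr).  Must
#'   resolve the shortest internal period (about 14 kyr); the default of
#'   100 yr oversamples it by two orders of magnitude.
#' @return An object of class \code{"solver_settings"}.
#' @export
solver_settings <- function(rel_tol = 1e-12, abs_tol = 1e-12,
                            max_step = Inf, resample_dt = 100) {
  if (!is.finite(rel_tol) || rel_tol <= 0)
    stop("'rel_tol' must be positive", call. = FALSE)
  if (any(!is.finite(abs_tol)) || any(abs_tol <= 0))
    stop("'abs_tol' must be positive", call. = FALSE)
  if (!is.finite(resample_dt) || resample_dt <= 0)
    stop("'resample_dt' must be positive", call. = FALSE)
  if (is.na(max_step) || max_step <= 0)
    stop("'max_step' must be positive (possibly Inf)", call. = FALSE)
  structure(list(rel_tol = rel_tol, abs_tol = abs_tol,
                 max_step = max_step, resample_dt = resample_dt),
            class = "solver_settings")
}

#' Default initial condition
#'
#' The equilibrium state with alkalinity perturbed by +0.05 mol eq m^-3.
#' Long-run cycle metrics are insensitive to this choice away from basin
#' boundaries, but transient behaviour (and which of several coexisting
#' locked states is reached) can depend on it.
#'
#' @inheritParams equilibrium
#' @param dA alkalinity perturbation (mol eq m^-3).
#' @return named numeric vector \code{c(A, P)}.
#' @export
default_init <- function(params, gamma = 0, dA = 0.05) {
  eq <- equilibrium(params, gamma)
  eq["A"] <- eq["A"] + dA
  eq
}

ode_piece <- function(y, times, parms, settings, nstates = 2L) {
  func <- if (nstates == 2L) "alk_derivs" else "alk_var_derivs"
  out <- deSolve::ode(y = y, times = times, func = func,
                      parms = parms, method = "lsoda",
                      dllname = "alkcycle", initfunc = "alk_initmod",
                      nout = 1, outnames = "gamma",
                      rtol = settings$rel_tol, atol = settings$abs_tol,
                      hmax = if (is.finite(settings$max_step))
                               settings$max_step else NULL,
                      maxsteps = 100000)
  if (any(!is.finite(out))) {
    bad <- which(rowSums(!is.finite(out)) > 0)[1]
    last_ok <- if (bad > 1) out[bad - 1, 1] else times[1]
    stop("integration blew up (non-finite state); last valid time t = ",
         format(last_ok), " yr", call. = FALSE)
  }
  if (nrow(out) < length(times) ||
      abs(out[nrow(out), 1] - times[length(times)]) > 1e-6)
    stop("integrator stopped early at t = ", format(out[nrow(out), 1]),
         " yr (of ", format(times[length(times)]),
         "); tolerances were NOT loosened — reduce the output interval ",
         "or tolerances explicitly", call. = FALSE)
  out
}

#' Integrate the model
#'
#' Adaptive integration of the forced calcifier-alkalinity system over a
#' time span, with output resampled onto a uniform grid.  Discontinuities
#' of a step (or the kinks of a ramp) schedule are honoured as integration
#' breakpoints: the solver is stopped and restarted there so the gamma
#' jump is never smoothed across a step.
#'
#' @param params an \code{\link{alk_params}} object.
#' @param schedule a \code{\link{gamma_schedule}} (or a single gamma
#'   value).
#' @param t_span length-2 numeric, start and end time (yr).
#' @param init initial state \code{c(A, P)}; default
#'   \code{\link{default_init}}.
#' @param settings a \code{\link{solver_settings}} object.
#' @return An object of class \code{"alk_trajectory"}: a data frame with
#'   columns \code{t}, \code{A}, \code{P}, \code{gamma} on the uniform
#'   output grid, carrying \code{params}, \code{schedule} and
#'   \code{settings} as attributes.
#' @examples
#' \donttest{
#' traj <- simulate_model(alk_params(), gamma_constant(0.07),
#'                        t_span = c(0, 2e6))
#' head(traj)
#' }
#' @export
simulate_model <- function(params, schedule, t_span, init = NULL,
                           settings = solver_settings()) {
  stopifnot(inherits(params, "alk_params"),
            inherits(settings, "solver_settings"))
  schedule <- as_schedule(schedule)
  if (length(t_span) != 2L || !all(is.finite(t_span)) ||
      t_span[2] <= t_span[1])
    stop("'t_span' must be an increasing pair of times", call. = FALSE)
  if (is.null(init)) init <- default_init(params, gamma_at(t_span[1],
                                                           schedule))
  if (length(init) != 2L || any(!is.finite(init)))
    stop("'init' must be a finite (A, P) pair", call. = FALSE)

  dt <- settings$resample_dt
  grid <- seq(t_span[1], t_span[2], by = dt)
  if (grid[length(grid)] < t_span[2]) grid <- c(grid, t_span[2])
  brk <- schedule_breakpoints(schedule)
  brk <- brk[brk > t_span[1] & brk < t_span[2]]
  parms <- pack_parms(params, schedule)

  pieces <- list()
  y <- c(A = unname(init[[1]]), P = unname(init[[2]]))
  t0 <- t_span[1]
  for (b in c(brk, t_span[2])) {
    tt <- grid[grid >= t0 & grid <= b]
    times <- unique(c(t0, tt, b))
    out <- ode_piece(y, times, parms, settings)
    y <- c(A = unname(out[nrow(out), "A"]), P = unname(out[nrow(out), "P"]))
    keep <- out[, 1] %in% tt
    pieces[[length(pieces) + 1L]] <- out[keep, , drop = FALSE]
    t0 <- b
  }
  m <- do.call(rbind, pieces)
  m <- m[!duplicated(m[, 1]), , drop = FALSE]
  traj <- data.frame(t = m[, "time"], A = m[, "A"], P = m[, "P"],
                     gamma = m[, "gamma"])
  structure(traj,
            params = params, schedule = schedule, settings = settings,
            init = init,
            class = c("alk_trajectory", "data.frame"))
}

#' @export
print.alk_trajectory <- function(x, ...) {
  cat(sprintf(
    "Calcifier-alkalinity trajectory: %d samples, t = %g .. %g yr (dt = %g)\n",
    nrow(x), x$t[1], x$t[nrow(x)], x$t[2] - x$t[1]))
  cat(sprintf("  A in [%.4g, %.4g] mol eq m^-3;  P in [%.4g, %.4g]\n",
              min(x$A), max(x$A), min(x$P), max(x$P)))
  print(attr(x, "schedule"))
  invisible(x)
}

#' Stroboscopic (period-advance) map
#'
#' Advances a state by exactly \code{n} forcing periods, starting at
#' forcing phase 0 (t = 0).  Fixed points of this map are orbits locked to
#' n times the forcing period.
#'
#' @param state numeric \code{c(A, P)} at forcing phase 0.
#' @inheritParams equilibrium
#' @param n number of forcing periods to advance (positive integer).
#' @param settings a \code{\link{solver_settings}} object.
#' @return the state after n forcing periods.
#' @export
stroboscopic_map <- function(state, params, gamma, n = 1,
                             settings = solver_settings()) {
  stopifnot(inherits(params, "alk_params"), n >= 1, n == round(n))
  parms <- pack_parms(params, gamma_constant(gamma))
  y <- c(A = unname(state[[1]]), P = unname(state[[2]]))
  out <- ode_piece(y, c(0, n * params$T_force[1]), parms, settings)
  c(A = unname(out[nrow(out), "A"]), P = unname(out[nrow(out), "P"]))
}

#' Propagate the variational (tangent) system
#'
#' Integrates \eqn{d\Phi/dt = J(t)\,\Phi} with \eqn{\Phi(0) = I} along the
#' concurrently integrated base trajectory of the forced system, starting
#' at forcing phase 0.  Over one period of a periodic orbit, \eqn{\Phi} is
#' the monodromy matrix whose eigenvalues are the Floquet multipliers.
#'
#' @param state initial state \code{c(A, P)} at forcing phase 0.
#' @inheritParams stroboscopic_map
#' @param duration integration time (yr), positive.
#' @param t0 start time (yr); nonzero values place the start at the
#'   corresponding forcing phase.
#' @return the 2 x 2 matrix \eqn{\Phi(duration)}, with attributes
#'   \code{state_end} (final base state) and \code{liouville}
#'   (\eqn{\int_0^\tau \mathrm{tr} J\, dt}, so that
#'   \eqn{\det \Phi = e^{\mathrm{liouville}}}).
#' @export
propagate_variational <- function(state, params, gamma, duration,
                                  settings = solver_settings(), t0 = 0) {
  stopifnot(inherits(params, "alk_params"))
  if (!is.finite(duration) || duration <= 0)
    stop("'duration' must be positive", call. = FALSE)
  parms <- pack_parms(params, gamma_constant(gamma))
  y <- c(A = unname(state[[1]]), P = unname(state[[2]]),
         phi11 = 1, phi21 = 0, phi12 = 0, phi22 = 1, liou = 0)
  out <- ode_piece(y, c(t0, t0 + duration), parms, settings, nstates = 7L)
  fin <- out[nrow(out), ]
  Phi <- matrix(c(fin[["phi11"]], fin[["phi21"]],
                  fin[["phi12"]], fin[["phi22"]]), 2, 2)
  attr(Phi, "state_end") <- c(A = fin[["A"]], P = fin[["P"]])
  attr(Phi, "liouville") <- fin[["liou"]]
  Phi
}
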