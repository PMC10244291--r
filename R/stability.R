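#' Locate a locked periodic orbit of the forced system
#'
#' A cycle locked to \code{n} forcing periods is a fixed point of the
#' n-period stroboscopic map.  Starting from a seed state at forcing
#' phase 0, Newton iteration is applied to
#' \eqn{F(x) = \Phi_n(x) - x}, using the variational (monodromy) matrix
#' as the map Jacobian.  Because Newton iteration does not care about
#' stability, unstable orbits (such as the pre-step orbit continued to a
#' higher feedback strength) are found just as readily as stable ones.
#'
#' @param params an \code{\link{alk_params}} object with
#'   \code{sum(alpha) > 0}.
#' @param gamma feedback strength (constant).
#' @param n integer forcing multiple of the sought orbit.
#' @param seed_state \code{c(A, P)} at forcing phase 0, reasonably near
#'   the orbit — e.g. the final state of a converged run whose length is
#'   a multiple of \code{n * T_force}, or a neighbouring orbit when
#'   continuing in gamma.
#' @param settings a \code{\link{solver_settings}} object.
#' @param tol convergence tolerance on the max-norm closure error.
#' @param max_iter Newton iteration cap.
#' @return An object of class \code{"periodic_orbit"}: list with
#'   \code{state0}, \code{n}, \code{period} (\code{= n * T_force}),
#'   \code{residual}, \code{stable}, \code{multipliers} and
#'   \code{iterations}.
#' @export
find_periodic_orbit <- function(params, gamma, n, seed_state,
                                settings = solver_settings(),
                                tol = 1e-10, max_iter = 30) {
  stopifnot(inherits(params, "alk_params"), n >= 1, n == round(n))
  if (sum(params$alpha) <= 0)
    stop("find_periodic_orbit needs a forced system (alpha > 0); the ",
         "unforced equilibrium is a trivial fixed point", call. = FALSE)
  period <- n * params$T_force[1]
  x <- c(A = unname(seed_state[[1]]), P = unname(seed_state[[2]]))
  res <- Inf; Phi <- NULL
  for (it in seq_len(max_iter)) {
    Phi <- propagate_variational(x, params, gamma, period, settings)
    Fx <- attr(Phi, "state_end") - x
    res <- max(abs(Fx))
    if (res < tol) break
    dx <- tryCatch(solve(Phi - diag(2), -Fx),
                   error = function(e)
                     stop("Newton step failed (singular map Jacobian): ",
                          conditionMessage(e), call. = FALSE))
    # damp absurd steps; the basin of Newton convergence is generous here
    scl <- max(abs(dx) / c(1, 5))
    if (scl > 1) dx <- dx / scl
    x <- x + dx
    if (any(!is.finite(x)))
      stop("Newton iterate diverged to non-finite state", call. = FALSE)
  }
  if (res >= tol)
    stop(sprintf(paste0("Newton did not converge in %d iterations; ",
                        "last residual %.3g"), max_iter, res),
         call. = FALSE)
  mu <- eigen(Phi, only.values = TRUE)$values
  structure(list(state0 = x, n = as.integer(n), period = period,
                 residual = res, stable = all(Mod(mu) < 1),
                 multipliers = mu, iterations = it),
            class = "periodic_orbit")
}

#' @export
print.periodic_orbit <- function(x, ...) {
  cat(sprintf(
    "Locked periodic orbit: n = %d (period %g kyr), %s\n",
    x$n, x$period / 1e3, if (x$stable) "stable" else "UNSTABLE"))
  cat(sprintf("  state0: A = %.6f, P = %.6f;  closure residual %.2e\n",
              x$state0[["A"]], x$state0[["P"]], x$residual))
  cat(sprintf("  |multipliers| = %.6f, %.3e\n",
              max(Mod(x$multipliers)), min(Mod(x$multipliers))))
  invisible(x)
}

#' Floquet multipliers and e-folding time constant of a locked orbit
#'
#' Integrates the variational system over one orbit period to obtain the
#' monodromy matrix; its eigenvalues are the Floquet multipliers
#' \eqn{\mu}.  A perturbation of the orbit contracts (or grows) by the
#' dominant \eqn{|\mu|} per period, giving the e-folding time constant
#' \eqn{\tau = \mathrm{period} / |\ln|\mu||}.  The determinant identity
#' \eqn{\det \Phi = \exp \int_0^\tau \mathrm{tr} J\, dt} (Liouville) is
#' verified on every computation.
#'
#' @param orbit a \code{\link{find_periodic_orbit}} result.
#' @inheritParams find_periodic_orbit
#' @return An object of class \code{"floquet_result"}: list with
#'   \code{multipliers}, \code{exponents} (\eqn{\ln|\mu|}/period, yr^-1),
#'   \code{time_constant} (yr), \code{direction} ("decay" or "growth"),
#'   \code{monodromy}, \code{liouville_rel_err}.
#' @export
floquet_multipliers <- function(orbit, params, gamma,
                                settings = solver_settings()) {
  stopifnot(inherits(orbit, "periodic_orbit"),
            inherits(params, "alk_params"))
  if (orbit$residual > 1e-8)
    warning("orbit closure residual exceeds 1e-8; multipliers may be ",
            "inaccurate", call. = FALSE)
  Phi <- propagate_variational(orbit$state0, params, gamma,
                               orbit$period, settings)
  mu <- eigen(Phi, only.values = TRUE)$values
  liou_err <- abs(det(Phi) - exp(attr(Phi, "liouville"))) /
    abs(exp(attr(Phi, "liouville")))
  if (liou_err > 1e-6)
    warning(sprintf("Liouville determinant identity violated (rel err %.2e)",
                    liou_err), call. = FALSE)
  amod <- Mod(mu)
  near_deg <- abs(amod[1] - amod[2]) < 1e-10 * max(amod)
  dom <- mu[which.max(amod)]
  expo <- log(Mod(mu)) / orbit$period
  structure(list(multipliers = mu,
                 exponents = expo,
                 time_constant = orbit$period / abs(log(Mod(dom))),
                 direction = if (Mod(dom) < 1) "decay" else "growth",
                 monodromy = Phi,
                 liouville_rel_err = liou_err,
                 near_degenerate = near_deg),
            class = "floquet_result")
}

#' @export
print.floquet_result <- function(x, ...) {
  cat("Floquet analysis of locked orbit\n")
  cat(sprintf("  |mu| = %.8f, %.3e  (%s)\n",
              max(Mod(x$multipliers)), min(Mod(x$multipliers)),
              x$direction))
  cat(sprintf("  e-folding time constant: %.3g Myr\n",
              x$time_constant / 1e6))
  cat(sprintf("  Liouville det check: rel err %.2e\n",
              x$liouville_rel_err))
  invisible(x)
}

#' Exponential time constant of a transient periodicity envelope
#'
#' During the approach to (or escape from) a locked state, the per-cycle
#' periodicity oscillates around the asymptote with an exponentially
#' shrinking (growing) envelope.  This extracts the envelope — local
#' maxima of the absolute deviation \eqn{|periodicity - asymptote|} over
#' cycle time — and fits \eqn{\log} deviation linearly in time;
#' \eqn{\tau = \mp 1/\mathrm{slope}}.
#'
#' Window selection: for decay, the fit runs from the envelope maximum
#' (transient onset) down to where the envelope has shrunk to 10\% of its
#' starting value (or \code{noise_floor}, whichever is larger); for
#' growth, from the start of the window until the deviation exceeds
#' \code{cap} (default half the inter-multiple gap, beyond which the
#' escape is no longer governed by the linearised orbit dynamics).
#'
#' @param cycles a \code{\link{detect_cycles}} result.
#' @param asymptote target periodicity (yr), e.g. the locked multiple.
#' @param direction \code{"decay"} or \code{"growth"}.
#' @param t_range optional length-2 time window (yr) restricting which
#'   cycles are used (e.g. before/after a feedback step).
#' @param noise_floor deviations below this (yr) are treated as noise and
#'   excluded.  The default, 30 yr, is a few times the peak-time
#'   refinement error on a 100-yr output grid.
#' @param cap half the spacing between locking plateaus (yr); growth fits
#'   stop, and decay fits start, where the deviation crosses it, since
#'   beyond it the dynamics are no longer governed by the linearised
#'   orbit.  Default half of the standard 40-kyr forcing period — pass
#'   explicitly for other forcings.
#' @return An object of class \code{"envelope_fit"}: list with \code{tau}
#'   (yr), \code{asymptote}, \code{r_squared}, \code{n_points},
#'   \code{window} (time range used), \code{env_times}, \code{env_dev}.
#' @export
envelope_time_constant <- function(cycles, asymptote,
                                   direction = c("decay", "growth"),
                                   t_range = NULL, noise_floor = 30,
                                   cap = 20000) {
  stopifnot(inherits(cycles, "cycle_series"))
  direction <- match.arg(direction)
  tt <- cycles$mid_times
  dev <- abs(cycles$periodicities - asymptote)
  if (!is.null(t_range)) {
    keep <- tt >= t_range[1] & tt <= t_range[2]
    tt <- tt[keep]; dev <- dev[keep]
  }
  if (length(dev) < 7)
    stop("too few cycles in the window for an envelope fit", call. = FALSE)
  # envelope: local maxima of the deviation series
  i <- which(diff(sign(diff(dev))) < 0) + 1L
  if (length(i) < 5)
    stop("fewer than 5 envelope points; no exponential regime to fit",
         call. = FALSE)
  et <- tt[i]; ed <- dev[i]
  if (direction == "decay") {
    # linearised decay toward the orbit only holds inside the locking
    # basin: drop leading envelope points beyond the half-gap cap (e.g.
    # the transit from a previous multiple)
    inside <- which(ed <= cap)
    if (length(inside) == 0)
      stop("deviation never enters the locking basin (all envelope ",
           "points exceed the cap)", call. = FALSE)
    et <- et[inside[1]:length(et)]; ed <- ed[inside[1]:length(ed)]
    start <- which.max(ed)
    et <- et[start:length(et)]; ed <- ed[start:length(ed)]
    floor_val <- max(0.1 * ed[1], noise_floor)
    below <- which(ed < floor_val)
    if (length(below) > 0 && below[1] > 2) {
      et <- et[seq_len(below[1] - 1)]; ed <- ed[seq_len(below[1] - 1)]
    } else {
      keep <- ed >= floor_val
      et <- et[keep]; ed <- ed[keep]
    }
  } else {
    above <- which(ed > cap)
    if (length(above) > 0 && above[1] > 2) {
      et <- et[seq_len(above[1] - 1)]; ed <- ed[seq_len(above[1] - 1)]
    }
    keep <- ed > noise_floor
    et <- et[keep]; ed <- ed[keep]
  }
  if (length(ed) < 5)
    stop("fewer than 5 usable envelope points after windowing",
         call. = FALSE)
  fit <- stats::lm(log(ed) ~ et)
  slope <- unname(coef(fit)[2])
  r2 <- summary(fit)$r.squared
  if ((direction == "decay" && slope >= 0) ||
      (direction == "growth" && slope <= 0))
    stop(sprintf(paste0("envelope slope (%.3g /yr) contradicts the ",
                        "requested %s direction; no exponential %s ",
                        "regime found"), slope, direction, direction),
         call. = FALSE)
  structure(list(tau = abs(1 / slope), asymptote = asymptote,
                 r_squared = r2, n_points = length(ed),
                 window = range(et), env_times = et, env_dev = ed,
                 direction = direction),
            class = "envelope_fit")
}

#' @export
print.envelope_fit <- function(x, ...) {
  cat(sprintf(
    "Envelope %s fit toward %g kyr: tau = %.3g Myr (r^2 = %.3f, %d points)\n",
    x$direction, x$asymptote / 1e3, x$tau / 1e6, x$r_squared, x$n_points))
  invisible(x)
}

#' Largest Lyapunov exponent of the forced system
#'
#' Benettin-style estimate: a tangent vector is propagated along a long
#' trajectory with the variational system and renormalised once per
#' forcing period; the exponent is the time-average of the log stretching
#' factors.  Negative for locked (and sub-threshold) regimes, positive in
#' the chaotic regime that sets in at forcing amplitudes near 0.008.
#'
#' @inheritParams find_periodic_orbit
#' @param alpha forcing amplitude override; \code{NULL} keeps
#'   \code{params$alpha}.
#' @param horizon total trajectory length (yr); the first
#'   \code{discard_frac} of it is discarded as transient.
#' @param discard_frac fraction of the horizon discarded.
#' @param init initial state; default \code{\link{default_init}}.
#' @return the exponent (yr^-1), with attributes \code{running}
#'   (cumulative estimate per renormalisation) and \code{converged}
#'   (TRUE when the last-quarter running estimate varies by < 20\% of its
#'   magnitude or < 1e-8 absolute).
#' @export
largest_lyapunov <- function(params, gamma, alpha = NULL, horizon = 8e6,
                             discard_frac = 0.2, init = NULL,
                             settings = solver_settings()) {
  stopifnot(inherits(params, "alk_params"))
  if (!is.null(alpha))
    params <- alk_params(I0 = params$I0, k0 = params$k0, M = params$M,
                         alpha = alpha,
                         T_force = rep_len(params$T_force,
                                           max(length(alpha), 1L)),
                         phase = rep_len(params$phase,
                                         max(length(alpha), 1L)),
                         A0 = params$A0, z0 = params$z0)
  if (is.null(init)) init <- default_init(params, gamma)
  Tr <- params$T_force[1]
  t_skip <- discard_frac * horizon
  # burn in to the attractor, landing on a renormalisation phase
  t_skip <- ceiling(t_skip / Tr) * Tr
  tr <- simulate_model(params, gamma_constant(gamma), c(0, t_skip),
                       init = init,
                       settings = solver_settings(
                         rel_tol = settings$rel_tol,
                         abs_tol = settings$abs_tol,
                         max_step = settings$max_step,
                         resample_dt = Tr))
  x <- c(A = tr$A[nrow(tr)], P = tr$P[nrow(tr)])
  n_int <- max(10L, floor((horizon - t_skip) / Tr))
  v <- c(1, 0)
  cumlog <- numeric(n_int)
  logsum <- 0
  for (j in seq_len(n_int)) {
    Phi <- propagate_variational(x, params, gamma, Tr, settings,
                                 t0 = t_skip + (j - 1) * Tr)
    x <- attr(Phi, "state_end")
    v <- as.numeric(Phi %*% v)
    s <- sqrt(sum(v^2))
    logsum <- logsum + log(s)
    v <- v / s
    cumlog[j] <- logsum
  }
  # slope of cumulative log stretch vs time: averages out the periodic
  # oscillation of the per-interval stretching (non-normal bursts within
  # each sawtooth cycle) that biases the endpoint estimate
  tj <- seq_len(n_int) * Tr
  est <- unname(coef(stats::lm(cumlog ~ tj))[2])
  half <- floor(n_int / 2)
  e1 <- unname(coef(stats::lm(cumlog[1:half] ~ tj[1:half]))[2])
  e2 <- unname(coef(stats::lm(cumlog[(half + 1):n_int] ~
                                tj[(half + 1):n_int]))[2])
  conv <- abs(e2 - e1) < max(0.5 * abs(est), 1e-7)
  if (!conv)
    warning("running Lyapunov estimate has not settled; increase horizon",
            call. = FALSE)
  structure(est, running = cumlog / tj, half_slopes = c(e1, e2),
            converged = conv)
}
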