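#' Model parameters for the calcifier-alkalinity system
#'
#' Constructs and validates the parameter set of the calcifier-alkalinity
#' model.  The state variables are ocean alkalinity \eqn{A} (mol eq m^-3)
#' and the natural log of the calcifier concentration, \eqn{P = \ln C}.
#' Alkalinity is supplied by continental weathering at rate
#' \eqn{I_0 (1 + \gamma S(A))}, consumed by calcifier growth at rate
#' \eqn{k A}, and calcite is buried at rate \eqn{M}.  The periodic
#' (astronomical) forcing acts multiplicatively on the reaction rate
#' \eqn{k}.
#'
#' Defaults are the standard parameter set of the model: they place the
#' equilibrium alkalinity \eqn{A^* = M/k_0 = 2} mol eq m^-3 exactly at the
#' feedback midpoint \code{A0}, so the equilibrium itself is independent of
#' the feedback strength gamma.
#'
#' @param I0 alkalinity input rate (mol eq m^-3 yr^-1).
#' @param k0 mean reaction rate ((mol eq)^-1 m^3 yr^-1).
#' @param M calcite sedimentation rate (yr^-1).
#' @param alpha forcing amplitude (dimensionless, in [0, 1)).  May be a
#'   vector of up to two components for a mixed forcing.
#' @param T_force forcing period (yr); same length as \code{alpha}.
#' @param phase forcing phase offset (radians); recycled to the length of
#'   \code{alpha}.  The default 0 puts a forcing maximum at t = 0.
#' @param A0 feedback midpoint alkalinity (mol eq m^-3).
#' @param z0 feedback scaling (mol eq m^-3); sets the slope of the sigmoid
#'   at the midpoint, S'(A0) = 1/z0.
#'
#' @return An object of class \code{"alk_params"}: a validated named list.
#' @examples
#' p <- alk_params()                     # standard parameter set
#' p20 <- alk_params(T_force = 2e4)      # precession-period forcing
#' @export
alk_params <- function(I0 = 4e-6, k0 = 0.05, M = 0.1,
                       alpha = 0, T_force = 4e4, phase = 0,
                       A0 = 2.0, z0 = 0.1) {
  for (nm in c("I0", "k0", "M", "A0", "z0")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single positive finite number", nm),
           call. = FALSE)
  }
  if (!is.numeric(alpha) || length(alpha) < 1L || length(alpha) > 2L ||
      any(!is.finite(alpha)) || any(alpha < 0))
    stop("'alpha' must be one or two finite non-negative numbers",
         call. = FALSE)
  if (sum(alpha) >= 1)
    stop("total forcing amplitude sum(alpha) must be < 1 so that the ",
         "reaction rate k stays positive", call. = FALSE)
  if (length(T_force) != length(alpha))
    T_force <- rep_len(T_force, length(alpha))
  if (any(!is.finite(T_force)) || any(T_force <= 0))
    stop("'T_force' must be positive and finite", call. = FALSE)
  phase <- rep_len(phase, length(alpha))
  if (any(!is.finite(phase)))
    stop("'phase' must be finite", call. = FALSE)
  structure(list(I0 = I0, k0 = k0, M = M,
                 alpha = alpha, T_force = T_force, phase = phase,
                 A0 = A0, z0 = z0),
            class = "alk_params")
}

#' @export
print.alk_params <- function(x, ...) {
  cat("Calcifier-alkalinity model parameters\n")
  cat(sprintf("  I0 = %g mol eq m^-3 yr^-1   (alkalinity input)\n", x$I0))
  cat(sprintf("  k0 = %g (mol eq)^-1 m^3 yr^-1   (reaction rate)\n", x$k0))
  cat(sprintf("  M  = %g yr^-1   (sedimentation rate)\n", x$M))
  if (sum(x$alpha) == 0) {
    cat("  forcing: none (alpha = 0)\n")
  } else {
    for (i in seq_along(x$alpha))
      cat(sprintf("  forcing %d: alpha = %g, T = %g kyr, phase = %g rad\n",
                  i, x$alpha[i], x$T_force[i] / 1e3, x$phase[i]))
  }
  cat(sprintf("  feedback sigmoid: A0 = %g, z0 = %g mol eq m^-3\n",
              x$A0, x$z0))
  invisible(x)
}

#' Feedback-strength schedules
#'
#' The feedback strength gamma may be held constant, stepped abruptly from
#' \code{gamma1} to \code{gamma2} at time \code{t_c}, or ramped linearly
#' from \code{gamma1} to \code{gamma2} over \code{[t_c, t_c + delta_t]}.
#' A ramp with \code{delta_t = 0} is identical to a step.
#'
#' @param gamma1 feedback strength before the transition (dimensionless,
#'   in [0, 1)).
#' @param gamma2 feedback strength after the transition (step and ramp).
#' @param t_c transition start time (yr).
#' @param delta_t ramp duration (yr).
#' @return An object of class \code{"gamma_schedule"}.
#' @examples
#' gamma_constant(0.07)
#' gamma_step(0.06, 0.09, t_c = 5e7)
#' gamma_ramp(0.06, 0.12, t_c = 5e7, delta_t = 1e8)
#' @name gamma_schedule
NULL

check_gamma <- function(g, nm) {
  if (!is.numeric(g) || length(g) != 1L || !is.finite(g) || g < 0 || g >= 1)
    stop(sprintf("'%s' must be a single number in [0, 1)", nm),
         call. = FALSE)
  g
}

#' @rdname gamma_schedule
#' @export
gamma_constant <- function(gamma1) {
  structure(list(kind = "constant", gamma1 = check_gamma(gamma1, "gamma1")),
            class = "gamma_schedule")
}

#' @rdname gamma_schedule
#' @export
gamma_step <- function(gamma1, gamma2, t_c = 5e7) {
  if (!is.finite(t_c)) stop("'t_c' must be finite", call. = FALSE)
  structure(list(kind = "step",
                 gamma1 = check_gamma(gamma1, "gamma1"),
                 gamma2 = check_gamma(gamma2, "gamma2"),
                 t_c = t_c),
            class = "gamma_schedule")
}

#' @rdname gamma_schedule
#' @export
gamma_ramp <- function(gamma1, gamma2, t_c = 5e7, delta_t = 1e7) {
  if (!is.finite(t_c)) stop("'t_c' must be finite", call. = FALSE)
  if (!is.finite(delta_t) || delta_t < 0)
    stop("'delta_t' must be a non-negative finite number", call. = FALSE)
  structure(list(kind = "ramp",
                 gamma1 = check_gamma(gamma1, "gamma1"),
                 gamma2 = check_gamma(gamma2, "gamma2"),
                 t_c = t_c, delta_t = delta_t),
            class = "gamma_schedule")
}

#' @export
print.gamma_schedule <- function(x, ...) {
  switch(x$kind,
    constant = cat(sprintf("gamma schedule: constant gamma = %g\n",
                           x$gamma1)),
    step = cat(sprintf(
      "gamma schedule: step %g -> %g at t_c = %g yr\n",
      x$gamma1, x$gamma2, x$t_c)),
    ramp = cat(sprintf(
      "gamma schedule: linear ramp %g -> %g over [%g, %g] yr\n",
      x$gamma1, x$gamma2, x$t_c, x$t_c + x$delta_t)))
  invisible(x)
}

#' Evaluate a feedback schedule
#'
#' @param t time or vector of times (yr).
#' @param schedule a \code{\link{gamma_schedule}}.
#' @return gamma(t), vectorised over \code{t}.
#' @examples
#' gamma_at(c(4.9e7, 5.1e7), gamma_step(0.06, 0.09, t_c = 5e7))
#' @export
gamma_at <- function(t, schedule) {
  stopifnot(inherits(schedule, "gamma_schedule"))
  switch(schedule$kind,
    constant = rep_len(schedule$gamma1, length(t)),
    step = ifelse(t < schedule$t_c, schedule$gamma1, schedule$gamma2),
    ramp = {
      if (schedule$delta_t == 0) {
        ifelse(t < schedule$t_c, schedule$gamma1, schedule$gamma2)
      } else {
        frac <- pmin(pmax((t - schedule$t_c) / schedule$delta_t, 0), 1)
        schedule$gamma1 + (schedule$gamma2 - schedule$gamma1) * frac
      }
    })
}

# Times at which gamma(t) is non-smooth; integration restarts there.
schedule_breakpoints <- function(schedule) {
  switch(schedule$kind,
    constant = numeric(0),
    step = schedule$t_c,
    ramp = if (schedule$delta_t == 0) schedule$t_c
           else c(schedule$t_c, schedule$t_c + schedule$delta_t))
}

# Flat parameter vector handed to the compiled right-hand sides.
pack_parms <- function(params, schedule) {
  stopifnot(inherits(params, "alk_params"),
            inherits(schedule, "gamma_schedule"))
  nf <- if (sum(params$alpha) == 0) 0L else length(params$alpha)
  a <- c(params$alpha, 0, 0)[1:2]
  Tf <- c(params$T_force, 1, 1)[1:2]
  ph <- c(params$phase, 0, 0)[1:2]
  kind <- match(schedule$kind, c("constant", "step", "ramp")) - 1L
  c(params$I0, params$k0, params$M, params$A0, params$z0,
    nf, a[1], Tf[1], ph[1], a[2], Tf[2], ph[2],
    kind,
    schedule$gamma1,
    if (kind > 0) schedule$gamma2 else schedule$gamma1,
    if (kind > 0) schedule$t_c else 0,
    if (kind == 2) schedule$delta_t else 0)
}

#' Read and write model configurations
#'
#' Parameters, schedules and solver settings round-trip to a flat YAML or
#' JSON document whose keys are exactly the constructor argument names.
#'
#' @param params an \code{\link{alk_params}} object.
#' @param schedule a \code{\link{gamma_schedule}} object.
#' @param settings optional \code{\link{solver_settings}} object.
#' @param path file path; format from extension (.yaml/.yml or .json).
#' @return \code{read_config} returns a list with elements \code{params},
#'   \code{schedule} and (if present) \code{settings}.
#' @examples
#' cfg <- tempfile(fileext = ".yaml")
#' write_config(alk_params(alpha = 0.003), gamma_constant(0.07), path = cfg)
#' read_config(cfg)$params
#' @export
write_config <- function(params, schedule, settings = NULL, path) {
  stopifnot(inherits(params, "alk_params"),
            inherits(schedule, "gamma_schedule"))
  doc <- list(params = unclass(params), schedule = unclass(schedule))
  if (!is.null(settings)) doc$settings <- unclass(settings)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(doc, path)
  }
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  p <- doc$params
  params <- alk_params(I0 = p$I0, k0 = p$k0, M = p$M,
                       alpha = unlist(p$alpha),
                       T_force = unlist(p$T_force),
                       phase = unlist(p$phase),
                       A0 = p$A0, z0 = p$z0)
  s <- doc$schedule
  schedule <- switch(s$kind,
    constant = gamma_constant(s$gamma1),
    step = gamma_step(s$gamma1, s$gamma2, s$t_c),
    ramp = gamma_ramp(s$gamma1, s$gamma2, s$t_c, s$delta_t),
    stop("unknown schedule kind: ", s$kind))
  out <- list(params = params, schedule = schedule)
  if (!is.null(doc$settings)) {
    st <- doc$settings
    out$settings <- solver_settings(rel_tol = as.numeric(st$rel_tol),
                                    abs_tol = as.numeric(st$abs_tol),
                                    max_step = as.numeric(st$max_step),
                                    resample_dt = as.numeric(st$resample_dt))
  }
  out
}
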