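#' Bounded weathering-feedback sigmoid
#'
#' The weathering input responds to alkalinity through
#' \deqn{S(A) = \frac{2}{\pi}\arctan\!\Big(\frac{\pi (A - A_0)}{2 z_0}\Big),}
#' an odd, strictly increasing function of \eqn{A - A_0}, bounded in
#' (-1, 1), with slope exactly \eqn{1/z_0} at the midpoint.  The bounds
#' express the finite extent of the continental shelves that supply the
#' extra weathering.
#'
#' @param A alkalinity (mol eq m^-3); vectorised.
#' @param A0 midpoint alkalinity (mol eq m^-3).
#' @param z0 scaling (mol eq m^-3); must be positive.
#' @return S(A), dimensionless in (-1, 1).
#' @examples
#' sigmoid_feedback(2.1, A0 = 2.0, z0 = 0.1)   # (2/pi) * atan(pi/2)
#' @export
sigmoid_feedback <- function(A, A0 = 2.0, z0 = 0.1) {
  if (!is.numeric(z0) || length(z0) != 1L || !is.finite(z0) || z0 <= 0)
    stop("'z0' must be a single positive number", call. = FALSE)
  (2 / pi) * atan(pi * (A - A0) / (2 * z0))
}

# dS/dA
sigmoid_feedback_prime <- function(A, A0 = 2.0, z0 = 0.1) {
  x <- pi * (A - A0) / (2 * z0)
  1 / (z0 * (1 + x^2))
}

#' Forced reaction rate
#'
#' The astronomical forcing modulates the calcifier reaction rate:
#' \deqn{k(t) = k_0\Big(1 + \sum_i \alpha_i
#'   \cos(2\pi t / T_i + \phi_i)\Big).}
#' With the default single component this is
#' \eqn{k_0 (1 + \alpha \cos(2\pi t/T))}; a second component supports
#' mixed obliquity + precession forcing.
#'
#' @param t time (yr); vectorised.
#' @param params an \code{\link{alk_params}} object.
#' @return k(t) ((mol eq)^-1 m^3 yr^-1).
#' @examples
#' forcing_rate(0, alk_params(alpha = 0.003))     # k0 * 1.003
#' @export
forcing_rate <- function(t, params) {
  stopifnot(inherits(params, "alk_params"))
  mod <- rep_len(1, length(t))
  if (sum(params$alpha) > 0) {
    for (i in seq_along(params$alpha))
      mod <- mod + params$alpha[i] *
        cos(2 * pi * t / params$T_force[i] + params$phase[i])
  }
  params$k0 * mod
}

#' Model time derivatives
#'
#' Right-hand side of the calcifier-alkalinity system in log-calcifier
#' form:
#' \deqn{dA/dt = I_0 (1 + \gamma S(A)) - k(t)\, A\, e^P, \qquad
#'       dP/dt = k(t)\, A - M.}
#' With gamma = 0 this reduces to the base model; the change of variables
#' \eqn{P = \ln C} maps it exactly to the (A, C) form
#' \eqn{dA/dt = I - kAC}, \eqn{dC/dt = kAC - MC}.
#'
#' An R-level reference implementation; long integrations use the
#' identical compiled version through \code{\link{simulate_model}}.
#'
#' @param t time (yr).
#' @param state numeric vector \code{c(A = , P = )}.
#' @param params an \code{\link{alk_params}} object.
#' @param schedule a \code{\link{gamma_schedule}}; a plain number is
#'   accepted as shorthand for a constant schedule.
#' @return numeric vector \code{c(dA, dP)} (per yr).
#' @examples
#' eq <- equilibrium(alk_params())
#' model_rhs(0, eq, alk_params(), 0)     # zero at the fixed point
#' @export
model_rhs <- function(t, state, params, schedule = gamma_constant(0)) {
  stopifnot(inherits(params, "alk_params"))
  schedule <- as_schedule(schedule)
  if (any(!is.finite(state)))
    stop("non-finite state passed to model_rhs", call. = FALSE)
  A <- state[[1]]; P <- state[[2]]
  C <- exp(P)
  if (!is.finite(C))
    stop("exp(P) overflowed: the calcifier population left the ",
         "representable range (P = ", format(P), ")", call. = FALSE)
  k <- forcing_rate(t, params)
  g <- gamma_at(t, schedule)
  c(A = params$I0 * (1 + g * sigmoid_feedback(A, params$A0, params$z0)) -
      k * A * C,
    P = k * A - params$M)
}

as_schedule <- function(schedule) {
  if (inherits(schedule, "gamma_schedule")) return(schedule)
  if (is.numeric(schedule) && length(schedule) == 1L)
    return(gamma_constant(schedule))
  stop("'schedule' must be a gamma_schedule or a single gamma value",
       call. = FALSE)
}

#' Equilibrium of the unforced system
#'
#' The autonomous system (alpha = 0) has a unique positive fixed point:
#' \eqn{A^* = M/k_0} from the P-nullcline, and
#' \eqn{C^* = I_0 (1 + \gamma S(A^*))/M} from the A-nullcline.
#' With the standard parameter set \eqn{A^* = A_0}, so \eqn{S(A^*) = 0}
#' and the equilibrium is independent of gamma.
#'
#' @param params an \code{\link{alk_params}} object.
#' @param gamma feedback strength (dimensionless).
#' @return named numeric vector \code{c(A = A*, P = ln C*)}.
#' @examples
#' equilibrium(alk_params())             # A* = 2, C* = 4e-5
#' @export
equilibrium <- function(params, gamma = 0) {
  stopifnot(inherits(params, "alk_params"))
  check_gamma(gamma, "gamma")
  A_star <- params$M / params$k0
  C_star <- params$I0 *
    (1 + gamma * sigmoid_feedback(A_star, params$A0, params$z0)) / params$M
  if (C_star <= 0)
    stop("no positive equilibrium: C* = ", format(C_star), call. = FALSE)
  c(A = A_star, P = log(C_star))
}

#' Jacobian of the unforced system
#'
#' Linearisation of the autonomous (alpha = 0) system at a state:
#' \deqn{J = \begin{pmatrix}
#'   I_0 \gamma S'(A) - k_0 e^P & -k_0 A e^P \\ k_0 & 0
#' \end{pmatrix}.}
#'
#' @param state numeric vector \code{c(A, P)}.
#' @inheritParams equilibrium
#' @return 2 x 2 numeric matrix, rows/columns ordered (A, P).
#' @examples
#' jacobian_at(equilibrium(alk_params()), alk_params(), gamma = 0)
#' @export
jacobian_at <- function(state, params, gamma = 0) {
  stopifnot(inherits(params, "alk_params"))
  if (any(!is.finite(state))) stop("non-finite state", call. = FALSE)
  A <- state[[1]]; C <- exp(state[[2]])
  k0 <- params$k0
  Sp <- sigmoid_feedback_prime(A, params$A0, params$z0)
  matrix(c(params$I0 * gamma * Sp - k0 * C, k0,
           -k0 * A * C, 0),
         nrow = 2, dimnames = list(c("A", "P"), c("A", "P")))
}

#' Hopf bifurcation threshold of the feedback strength
#'
#' As gamma increases, the equilibrium's complex eigenvalue pair crosses
#' the imaginary axis and a small stable limit cycle is born (supercritical
#' Hopf bifurcation).  The crossing is where the Jacobian trace vanishes,
#' \eqn{I_0 \gamma S'(A^*) = k_0 C^*}.  When \eqn{A^* = A_0} (the standard
#' parameter set) this has the closed form
#' \deqn{\gamma_H = k_0 z_0 / M.}
#' Otherwise, and for \code{method = "scan"}, the crossing of the maximal
#' eigenvalue real part is located numerically over gamma in [0, 1).
#'
#' @inheritParams equilibrium
#' @param method \code{"closed_form"} (requires A* = A0) or \code{"scan"}
#'   (numeric root of the leading real part).
#' @param tol tolerance of the numeric scan.
#' @return the threshold gamma_H (dimensionless).
#' @examples
#' hopf_threshold(alk_params())                       # 0.05
#' hopf_threshold(alk_params(), method = "scan")
#' @export
hopf_threshold <- function(params, method = c("closed_form", "scan"),
                           tol = 1e-10) {
  stopifnot(inherits(params, "alk_params"))
  method <- match.arg(method)
  A_star <- params$M / params$k0
  at_midpoint <- isTRUE(all.equal(A_star, params$A0, tolerance = 1e-12))
  if (method == "closed_form") {
    if (!at_midpoint)
      stop("closed form gamma_H = k0*z0/M requires A* = M/k0 to equal ",
           "A0; use method = \"scan\"", call. = FALSE)
    return(params$k0 * params$z0 / params$M)
  }
  lead_re <- function(g) {
    eq <- equilibrium(params, g)
    max(Re(eigen(jacobian_at(eq, params, g), only.values = TRUE)$values))
  }
  lo <- 0; hi <- 1 - 1e-9
  if (lead_re(lo) >= 0)
    stop("equilibrium already unstable at gamma = 0", call. = FALSE)
  if (lead_re(hi) <= 0)
    stop("no stability crossing found for gamma in [0, 1)", call. = FALSE)
  stats::uniroot(lead_re, c(lo, hi), tol = tol)$root
}

#' Internal period of the linearised oscillation
#'
#' Below the Hopf threshold the equilibrium is a spiral sink; perturbations
#' decay with oscillation period \eqn{2\pi / \omega}, where \eqn{\omega}
#' is the imaginary part of the equilibrium eigenvalues,
#' \eqn{\omega = \sqrt{\det J - (\mathrm{tr}\, J)^2/4}}.  With standard
#' parameters and gamma = 0 this is about 14 kyr, and it changes only
#' negligibly with gamma below the threshold.
#'
#' @inheritParams equilibrium
#' @return oscillation period (yr).
#' @examples
#' linear_internal_period(alk_params())      # about 14,050 yr
#' @export
linear_internal_period <- function(params, gamma = 0) {
  stopifnot(inherits(params, "alk_params"))
  J <- jacobian_at(equilibrium(params, gamma), params, gamma)
  disc <- det(J) - (sum(diag(J)))^2 / 4
  if (disc <= 0)
    stop("equilibrium eigenvalues are real (non-oscillatory); ",
         "no internal period is defined", call. = FALSE)
  2 * pi / sqrt(disc)
}
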