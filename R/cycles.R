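#' Detect sawtooth cycles in a trajectory
#'
#' Locates the alternating local maxima and minima of the alkalinity
#' series and derives the two per-cycle metrics: \emph{periodicity}, the
#' time between successive alkalinity maxima, and \emph{amplitude}, the
#' alkalinity difference between a maximum and the following minimum.
#'
#' Low-prominence wiggles are pruned: adjacent extremum pairs whose
#' alkalinity difference is below \code{prominence_frac} times the overall
#' alkalinity range of the trajectory are removed (smallest first), which
#' leaves genuine sawtooth cycles untouched while ignoring ripple at the
#' percent level.  Extremum times are then refined by parabolic
#' interpolation on the uniform grid, giving peak times far more precise
#' than the output spacing.  Boundary-truncated cycles are dropped: the
#' series starts at the first retained maximum, and a trailing maximum
#' with no following minimum contributes no amplitude.
#'
#' @param traj an \code{\link{alk_trajectory}} (or any data frame with
#'   columns \code{t} and \code{A} on a uniform grid).
#' @param prominence_frac minimum extremum prominence as a fraction of the
#'   overall alkalinity range.
#' @return An object of class \code{"cycle_series"}: a list with elements
#'   \code{max_times}, \code{max_values}, \code{min_times},
#'   \code{min_values}, \code{periodicities}, \code{amplitudes} and
#'   \code{mid_times} (midpoints of successive maxima, the natural time
#'   coordinate of each periodicity).
#' @examples
#' t <- seq(0, 1e6, by = 100)
#' traj <- data.frame(t = t, A = 2 + 0.2 * sin(2 * pi * t / 4e4))
#' cyc <- detect_cycles(traj)
#' mean(cyc$periodicities)    # 40,000 yr
#' @export
detect_cycles <- function(traj, prominence_frac = 0.01) {
  if (!all(c("t", "A") %in% names(traj)))
    stop("'traj' must have columns 't' and 'A'", call. = FALSE)
  if (!is.finite(prominence_frac) || prominence_frac < 0)
    stop("'prominence_frac' must be non-negative", call. = FALSE)
  t <- traj$t; A <- traj$A
  n <- length(A)
  empty <- function() {
    warning("fewer than 2 alkalinity maxima found; empty cycle series",
            call. = FALSE)
    structure(list(max_times = numeric(0), max_values = numeric(0),
                   min_times = numeric(0), min_values = numeric(0),
                   periodicities = numeric(0), amplitudes = numeric(0),
                   mid_times = numeric(0)),
              class = "cycle_series")
  }
  if (n < 5) return(empty())

  d <- diff(A)
  s <- sign(d)
  # carry signs across flat segments so plateaus count once
  for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  turn <- diff(s)
  idx <- which(turn != 0) + 1L
  kind <- ifelse(turn[idx - 1L] < 0, 1L, -1L)  # 1 = max, -1 = min

  # prune low-prominence adjacent pairs, smallest difference first
  thr <- prominence_frac * (max(A) - min(A))
  vals <- A[idx]
  repeat {
    if (length(idx) < 2L) break
    dif <- abs(diff(vals))
    j <- which.min(dif)
    if (dif[j] >= thr) break
    keep <- setdiff(seq_along(idx), c(j, j + 1L))
    idx <- idx[keep]; vals <- vals[keep]; kind <- kind[keep]
  }
  if (sum(kind == 1L) < 2L) return(empty())

  # parabolic refinement of extremum time and value
  refine <- function(i) {
    if (i <= 1L || i >= n) return(c(t[i], A[i]))
    den <- A[i - 1L] - 2 * A[i] + A[i + 1L]
    if (den == 0) return(c(t[i], A[i]))
    dt <- t[i + 1L] - t[i]
    off <- 0.5 * (A[i - 1L] - A[i + 1L]) / den
    # a quadratic extremum lies within half a grid step of the sampled
    # one; larger offsets flag a kink (sawtooth drop), where the sample
    # itself is the best estimate.  Only the time is refined: the sampled
    # value is kept, so asymmetric kinks cannot distort amplitudes.
    if (!is.finite(off) || abs(off) > 0.5) off <- 0
    c(t[i] + off * dt, A[i])
  }
  ref <- vapply(idx, refine, numeric(2))
  times <- ref[1, ]; values <- ref[2, ]

  # start at the first maximum; alternation is guaranteed by construction
  first_max <- which(kind == 1L)[1]
  times <- times[first_max:length(times)]
  values <- values[first_max:length(values)]
  kind <- kind[first_max:length(kind)]

  max_i <- which(kind == 1L); min_i <- which(kind == -1L)
  max_times <- times[max_i]; max_values <- values[max_i]
  min_times <- times[min_i]; min_values <- values[min_i]
  # amplitude pairs each maximum with the following minimum
  n_pair <- min(length(max_i), length(min_i))
  amplitudes <- max_values[seq_len(n_pair)] - min_values[seq_len(n_pair)]
  periodicities <- diff(max_times)
  structure(list(max_times = max_times, max_values = max_values,
                 min_times = min_times, min_values = min_values,
                 periodicities = periodicities,
                 amplitudes = amplitudes,
                 mid_times = (max_times[-1] + max_times[-length(max_times)]) / 2),
            class = "cycle_series")
}

#' @export
print.cycle_series <- function(x, ...) {
  np <- length(x$periodicities)
  cat(sprintf("Cycle series: %d maxima, %d periodicities\n",
              length(x$max_times), np))
  if (np > 0)
    cat(sprintf("  periodicity: mean %.0f yr (last: %.0f);  amplitude: mean %.4g\n",
                mean(x$periodicities), x$periodicities[np],
                mean(x$amplitudes)))
  invisible(x)
}

#' Asymptotic cycle periodicity
#'
#' The headline observable of the model: the periodicity the system tends
#' toward asymptotically, estimated as the mean of the final
#' \code{n_last} inter-maximum intervals of a long run.  With
#' \code{alpha = 0} this is the \emph{internal period} T0; with
#' \code{alpha > 0} it is the \emph{average duration} D.
#'
#' Below the Hopf threshold the oscillations are not self-sustained; the
#' damped-spiral periodicity is still returned, flagged via
#' \code{below_hopf}.  A convergence diagnostic flags estimates whose
#' trailing periodicities spread over more than 5\% of their mean (which
#' is also the signature of unlocked or high-order-locked states, whose
#' individual cycle lengths alternate around the mean).
#'
#' @param params an \code{\link{alk_params}} object (its \code{T_force}
#'   and \code{phase} are kept).
#' @param gamma feedback strength.
#' @param alpha forcing amplitude override; \code{NULL} keeps
#'   \code{params$alpha}.
#' @param horizon run length (yr).  The default is long enough for the
#'   slowest relevant transients (decay time constants of order 10 Myr);
#'   the estimate is insensitive to the horizon once the run represents
#'   long-term behaviour.
#' @param n_last number of trailing cycles to average.
#' @param init initial state; default \code{\link{default_init}}.
#' @param settings a \code{\link{solver_settings}} object.
#' @return An object of class \code{"periodicity_estimate"}: a list with
#'   \code{periodicity} (yr), \code{n_cycles}, \code{spread_frac},
#'   \code{converged}, \code{below_hopf}, \code{final_state}, and the
#'   \code{cycles} used.
#' @examples
#' \donttest{
#' asymptotic_periodicity(alk_params(), gamma = 0.07, horizon = 2e7)
#' }
#' @export
asymptotic_periodicity <- function(params, gamma, alpha = NULL,
                                   horizon = 1e8, n_last = 50,
                                   init = NULL,
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
  below <- gamma < hopf_gamma(params)
  traj <- simulate_model(params, gamma_constant(gamma), c(0, horizon),
                         init = init, settings = settings)
  cyc <- detect_cycles(traj)
  per <- cyc$periodicities
  if (length(per) < 2) {
    warning("no cycles detected; returning NA periodicity", call. = FALSE)
    return(structure(list(periodicity = NA_real_, n_cycles = 0L,
                          spread_frac = NA_real_, converged = FALSE,
                          below_hopf = below,
                          final_state = c(A = traj$A[nrow(traj)],
                                          P = traj$P[nrow(traj)]),
                          cycles = cyc),
                     class = "periodicity_estimate"))
  }
  use <- tail(per, n_last)
  m <- mean(use)
  spread <- (max(use) - min(use)) / m
  conv <- spread <= 0.05
  if (!conv)
    warning(sprintf(paste0("trailing periodicities spread over %.1f%% of ",
                           "their mean; the state may be unlocked or not ",
                           "yet converged"), 100 * spread), call. = FALSE)
  structure(list(periodicity = m, n_cycles = length(use),
                 spread_frac = spread, converged = conv,
                 below_hopf = below,
                 final_state = c(A = traj$A[nrow(traj)],
                                 P = traj$P[nrow(traj)]),
                 cycles = cyc),
            class = "periodicity_estimate")
}

# closed form when A* = A0, numeric scan otherwise
hopf_gamma <- function(params) {
  A_star <- params$M / params$k0
  if (isTRUE(all.equal(A_star, params$A0, tolerance = 1e-12)))
    params$k0 * params$z0 / params$M
  else
    tryCatch(hopf_threshold(params, method = "scan"),
             error = function(e) NA_real_)
}

#' @export
print.periodicity_estimate <- function(x, ...) {
  cat(sprintf("Asymptotic periodicity: %.0f yr (mean of final %d cycles)\n",
              x$periodicity, x$n_cycles))
  cat(sprintf("  trailing spread %.2f%%; converged: %s; below Hopf: %s\n",
              100 * x$spread_frac, x$converged, x$below_hopf))
  invisible(x)
}

#' Nearest locked multiple of the forcing period
#'
#' @param D average duration (yr).
#' @param T_force forcing period (yr).
#' @param tol_frac locking tolerance as a fraction of \code{T_force}.
#' @return list with \code{n} (nearest integer multiple), \code{locked}
#'   (TRUE iff \code{|D - n T| <= tol_frac * T}) and \code{residual}
#'   (\code{D - n T}, yr).
#' @examples
#' lock_multiple(80000, 40000)   # n = 2, locked
#' lock_multiple(87000, 40000)   # n = 2, not locked
#' @export
lock_multiple <- function(D, T_force, tol_frac = 0.02) {
  stopifnot(D > 0, T_force > 0, tol_frac >= 0)
  n <- round(D / T_force)
  res <- D - n * T_force
  list(n = as.integer(n), locked = abs(res) <= tol_frac * T_force,
       residual = res)
}

#' Devil's staircase of average duration versus feedback strength
#'
#' For each gamma on a grid, computes the internal period T0 (a run with
#' \code{alpha = 0}) and the average duration D (a run at the given
#' forcing amplitude).  Plotting D against T0 exhibits the staircase of
#' locking plateaus at integer multiples of the forcing period.
#'
#' By default each grid point is seeded from the final state of the
#' previous one (\code{continue = TRUE}).  This continuation emulates a
#' system whose feedback strength ramps slowly upward — the regime the
#' staircase describes — and it selects consistently among coexisting
#' attractors where locked states overlap (near the upper end of a
#' plateau a locked orbit can coexist with an unlocked state reached from
#' cold starts).
#'
#' @inheritParams asymptotic_periodicity
#' @param gamma_grid increasing vector of feedback strengths.
#' @param alpha forcing amplitude for the D runs.
#' @param continue seed each point from the previous point's final state.
#' @param tol_frac locking tolerance passed to \code{\link{lock_multiple}}.
#' @return An object of classes \code{"staircase_result"} and
#'   \code{"data.frame"}: one row per gamma with columns \code{gamma},
#'   \code{T0}, \code{D}, \code{lock_n}, \code{locked}, \code{residual},
#'   \code{converged_T0}, \code{converged_D}, \code{below_hopf}, plus
#'   attribute \code{alpha}.
#' @export
staircase <- function(params, gamma_grid, alpha = 0.003,
                      horizon = 1e8, n_last = 50, continue = TRUE,
                      tol_frac = 0.02, compute_T0 = TRUE,
                      settings = solver_settings()) {
  stopifnot(inherits(params, "alk_params"), length(gamma_grid) >= 1)
  Tf <- params$T_force[1]
  init0 <- NULL; initA <- NULL
  rows <- vector("list", length(gamma_grid))
  for (i in seq_along(gamma_grid)) {
    g <- gamma_grid[i]
    row <- data.frame(gamma = g, T0 = NA_real_, D = NA_real_,
                      lock_n = NA_integer_, locked = NA,
                      residual = NA_real_, converged_T0 = NA,
                      converged_D = NA, below_hopf = NA)
    ok <- tryCatch({
      e0 <- if (compute_T0) suppressWarnings(asymptotic_periodicity(
        params, g, alpha = 0, horizon = horizon, n_last = n_last,
        init = init0, settings = settings)) else NULL
      eA <- suppressWarnings(asymptotic_periodicity(
        params, g, alpha = alpha, horizon = horizon, n_last = n_last,
        init = initA, settings = settings))
      if (continue) {
        if (compute_T0) init0 <- e0$final_state
        initA <- eA$final_state
      }
      lk <- lock_multiple(eA$periodicity, Tf, tol_frac)
      row$D <- eA$periodicity
      row$lock_n <- lk$n; row$locked <- lk$locked
      row$residual <- lk$residual
      row$converged_D <- eA$converged
      if (compute_T0) {
        row$T0 <- e0$periodicity
        row$converged_T0 <- e0$converged
        row$below_hopf <- e0$below_hopf
      } else {
        row$below_hopf <- g < hopf_gamma(params)
      }
      TRUE
    }, error = function(e) {
      warning(sprintf("staircase point gamma = %g failed: %s",
                      g, conditionMessage(e)), call. = FALSE)
      FALSE
    })
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  structure(out, alpha = alpha,
            class = c("staircase_result", "data.frame"))
}

#' @export
print.staircase_result <- function(x, ...) {
  cat(sprintf("Devil's staircase: %d gamma points, alpha = %g\n",
              nrow(x), attr(x, "alpha")))
  print.data.frame(x, digits = 6, row.names = FALSE)
  invisible(x)
}

#' Linear relation between cycle length and amplitude
#'
#' The sawtooth geometry of the model predicts amplitude roughly
#' proportional to cycle length: longer cycles accumulate more alkalinity
#' before the calcifier bloom cuts them off.  Fits a least-squares line of
#' amplitude against periodicity over the (pooled) cycles.
#'
#' @param cycles a \code{\link{detect_cycles}} result, or a list of them
#'   to pool (e.g. across gamma values).
#' @return list with \code{slope} ((mol eq m^-3) per yr),
#'   \code{intercept}, \code{r_squared}, \code{n} and \code{degenerate}
#'   (TRUE when the periodicities have essentially no variance, as in a
#'   single locked run, making the slope meaningless).
#' @export
length_amplitude_fit <- function(cycles) {
  if (inherits(cycles, "cycle_series")) cycles <- list(cycles)
  # pair periodicity i (max i -> max i+1) with the amplitude of cycle i
  per <- unlist(lapply(cycles, function(cs) {
    k <- min(length(cs$periodicities), length(cs$amplitudes))
    cs$periodicities[seq_len(k)]
  }))
  amp <- unlist(lapply(cycles, function(cs) {
    k <- min(length(cs$periodicities), length(cs$amplitudes))
    cs$amplitudes[seq_len(k)]
  }))
  if (length(per) < 5)
    stop("need at least 5 complete cycles for the fit", call. = FALSE)
  degen <- stats::sd(per) < 1e-2 * mean(per)
  if (degen) {
    warning("periodicities are essentially constant; slope is meaningless",
            call. = FALSE)
    return(list(slope = NA_real_, intercept = mean(amp),
                r_squared = NA_real_, n = length(per), degenerate = TRUE))
  }
  fit <- stats::lm(amp ~ per)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((amp - mean(amp))^2)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = r2, n = length(per),
       degenerate = FALSE)
}
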