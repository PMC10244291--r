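#' Feedback-step experiment
#'
#' Reproduces the core numerical experiment on the delayed periodicity
#' response: the system settles into a locked state at feedback strength
#' \code{gamma1}, gamma is stepped to \code{gamma2} at \code{t_c}, and the
#' per-cycle periodicity series is analysed for the escape from the old
#' lock and the settling into the new one.
#'
#' Two delay metrics are reported.  \code{transition_delay} is the time
#' from \code{t_c} until the periodicity \emph{jump}: the first run of 20
#' consecutive cycles whose nearest forcing multiple is the new one.
#' This band-free criterion matches the visually evident transition and
#' is insensitive to how tightly "locked" is defined.
#' \code{settle_delay} is the stricter time until 20 consecutive cycles
#' lie within \code{tol_frac} of the new locked periodicity n T;
#' it is dominated by the final exponential decay tail and therefore
#' grows by several e-folding times (of order 10 Myr each) for every
#' factor-of-e tightening of the band.
#'
#' @param gamma1,gamma2 feedback strengths before/after the step.
#' @param alpha forcing amplitude.
#' @param t_c step time (yr).
#' @param horizon run length (yr); must leave room for the transition
#'   (delays are of order 1-10 Myr).
#' @param params base \code{\link{alk_params}} (its alpha is overridden).
#' @param init initial state; default \code{\link{default_init}}.
#' @param tol_frac per-cycle locking tolerance (fraction of the forcing
#'   period).
#' @param n_sustained consecutive locked cycles required.
#' @param settings a \code{\link{solver_settings}} object.
#' @param schedule internal override used by \code{\link{ramp_experiment}}.
#' @return An object of class \code{"step_experiment"}: list with the
#'   trajectory, cycle series, \code{pre_lock} and \code{post_lock}
#'   multiples, \code{transition_delay} and \code{settle_delay} (yr;
#'   \code{NA} with \code{censored = TRUE} if the post-step multiple is
#'   never sustained),
#'   envelope fits \code{fit_pre_decay}, \code{fit_post_growth},
#'   \code{fit_post_decay} (each possibly a try-error when the
#'   corresponding regime is absent), and \code{visited_multiples}.
#' @export
step_experiment <- function(gamma1, gamma2, alpha = 0.003, t_c = 5e7,
                            horizon = 1.5e8, params = alk_params(),
                            init = NULL, tol_frac = 0.02,
                            n_sustained = 20,
                            settings = solver_settings(),
                            schedule = NULL) {
  if (is.null(schedule)) schedule <- gamma_step(gamma1, gamma2, t_c)
  params <- alk_params(I0 = params$I0, k0 = params$k0, M = params$M,
                       alpha = alpha,
                       T_force = rep_len(params$T_force,
                                         max(length(alpha), 1L)),
                       phase = rep_len(params$phase,
                                       max(length(alpha), 1L)),
                       A0 = params$A0, z0 = params$z0)
  Tf <- params$T_force[1]
  traj <- simulate_model(params, schedule, c(0, horizon), init = init,
                         settings = settings)
  cyc <- detect_cycles(traj)
  per <- cyc$periodicities
  tt <- cycles_time <- cyc$mid_times
  n_cyc <- length(per)
  if (n_cyc < n_sustained + 5)
    stop("too few cycles for the step analysis", call. = FALSE)

  n_i <- as.integer(round(per / Tf))
  # per-cycle locking, relative to the locked periodicity n*T itself
  locked_i <- n_i >= 1 & abs(per - n_i * Tf) <= tol_frac * n_i * Tf

  sustained_from <- function(idx_set) {
    # first index in idx_set starting a run of n_sustained locked cycles
    # with a constant multiple
    for (j in idx_set) {
      if (j + n_sustained - 1 > n_cyc) break
      w <- j:(j + n_sustained - 1)
      if (all(locked_i[w]) && length(unique(n_i[w])) == 1L) return(j)
    }
    NA_integer_
  }

  pre_idx <- which(tt < t_c)
  post_idx <- which(tt >= t_c)
  pre_lock <- NA_integer_
  j_pre <- sustained_from(pre_idx)
  if (!is.na(j_pre)) pre_lock <- n_i[j_pre]

  # eventual post-step multiple: the sustained lock at the end of the run
  post_lock <- NA_integer_
  tail_idx <- tail(post_idx, n_sustained)
  if (length(tail_idx) == n_sustained && all(locked_i[tail_idx]) &&
      length(unique(n_i[tail_idx])) == 1L)
    post_lock <- n_i[tail_idx[1]]

  # first index in idx_set starting n_sustained consecutive cycles whose
  # NEAREST multiple is n_target (band-free arrival criterion)
  arrival_from <- function(idx_set, n_target) {
    for (j in idx_set) {
      if (j + n_sustained - 1 > n_cyc) break
      w <- j:(j + n_sustained - 1)
      if (all(n_i[w] == n_target)) return(j)
    }
    NA_integer_
  }

  censored <- is.na(post_lock) ||
    (!is.na(pre_lock) && post_lock == pre_lock && gamma2 != gamma1)
  transition_delay <- NA_real_
  settle_delay <- NA_real_
  if (gamma2 == gamma1) {
    transition_delay <- 0; settle_delay <- 0; censored <- FALSE
    if (is.na(post_lock)) post_lock <- pre_lock
  } else if (!is.na(post_lock)) {
    # delay to the periodicity jump: the periodicity now oscillates
    # around the new multiple (matches the visually evident transition)
    j_arr <- arrival_from(post_idx, post_lock)
    # delay to strict settling: 20 consecutive cycles within tol_frac
    cand <- post_idx[n_i[post_idx] == post_lock]
    j_set <- sustained_from(cand)
    if (!is.na(j_arr)) {
      transition_delay <- max(tt[j_arr] - t_c, 0)
      censored <- FALSE
    }
    if (!is.na(j_set)) settle_delay <- max(tt[j_set] - t_c, 0)
  }

  visited <- unique(n_i[post_idx][locked_i[post_idx]])

  tf <- function(expr) tryCatch(expr, error = function(e) e)
  fit_pre_decay <- if (!is.na(pre_lock))
    tf(envelope_time_constant(cyc, pre_lock * Tf, "decay",
                              t_range = c(0, t_c))) else NULL
  fit_post_growth <- if (!is.na(pre_lock) && gamma2 != gamma1)
    tf(envelope_time_constant(cyc, pre_lock * Tf, "growth",
                              t_range = c(t_c, horizon),
                              cap = Tf / 2)) else NULL
  fit_post_decay <- if (!is.na(post_lock) && gamma2 != gamma1)
    tf(envelope_time_constant(cyc, post_lock * Tf, "decay",
                              t_range = c(t_c, horizon))) else NULL

  structure(list(trajectory = traj, cycles = cyc,
                 gamma1 = gamma1, gamma2 = gamma2, alpha = alpha,
                 t_c = t_c, horizon = horizon, T_force = Tf,
                 pre_lock = pre_lock, post_lock = post_lock,
                 transition_delay = transition_delay,
                 settle_delay = settle_delay,
                 censored = censored,
                 visited_multiples = visited,
                 fit_pre_decay = fit_pre_decay,
                 fit_post_growth = fit_post_growth,
                 fit_post_decay = fit_post_decay),
            class = "step_experiment")
}

#' @export
print.step_experiment <- function(x, ...) {
  cat(sprintf("Feedback %s experiment: gamma %g -> %g, alpha = %g\n",
              if (!is.null(x$delta_t)) "ramp" else "step",
              x$gamma1, x$gamma2, x$alpha))
  cat(sprintf("  pre-step lock: n = %s (%s kyr);  post-step lock: n = %s (%s kyr)\n",
              x$pre_lock, format(x$pre_lock * x$T_force / 1e3),
              x$post_lock, format(x$post_lock * x$T_force / 1e3)))
  if (isTRUE(x$censored)) {
    cat("  transition delay: censored (no sustained post-step lock)\n")
  } else {
    cat(sprintf("  transition delay (arrival at new multiple): %.2f Myr\n",
                x$transition_delay / 1e6))
    if (!is.na(x$settle_delay))
      cat(sprintf("  settling delay (within 2%% band): %.2f Myr\n",
                  x$settle_delay / 1e6))
  }
  for (nm in c("fit_pre_decay", "fit_post_growth", "fit_post_decay")) {
    f <- x[[nm]]
    if (inherits(f, "envelope_fit"))
      cat(sprintf("  %s: tau = %.3g Myr (r^2 = %.3f)\n",
                  nm, f$tau / 1e6, f$r_squared))
  }
  invisible(x)
}

#' Feedback-ramp experiment
#'
#' As \code{\link{step_experiment}}, but gamma rises linearly from
#' \code{gamma1} to \code{gamma2} over \code{[t_c, t_c + delta_t]}.
#' Reports additionally whether the intermediate locked multiples between
#' the pre- and post-ramp locks are visited: slow ramps (of order the
#' transition delay or longer) pass through each locking plateau in turn,
#' while fast ramps skip the middle step.
#'
#' @inheritParams step_experiment
#' @param delta_t ramp duration (yr); 0 reduces exactly to the step.
#' @return A \code{"step_experiment"} object with additional fields
#'   \code{delta_t} and \code{intermediate_visited}.
#' @export
ramp_experiment <- function(gamma1, gamma2, alpha = 0.003, t_c = 5e7,
                            delta_t = 1e7, horizon = 1.5e8,
                            params = alk_params(), init = NULL,
                            tol_frac = 0.02, n_sustained = 20,
                            settings = solver_settings()) {
  res <- step_experiment(gamma1, gamma2, alpha = alpha, t_c = t_c,
                         horizon = horizon, params = params, init = init,
                         tol_frac = tol_frac, n_sustained = n_sustained,
                         settings = settings,
                         schedule = gamma_ramp(gamma1, gamma2, t_c,
                                               delta_t))
  res$delta_t <- delta_t
  if (!is.na(res$pre_lock) && !is.na(res$post_lock) &&
      res$post_lock - res$pre_lock > 1L) {
    mids <- (res$pre_lock + 1L):(res$post_lock - 1L)
    res$intermediate_visited <- mids %in% res$visited_multiples
    names(res$intermediate_visited) <- mids
  } else {
    res$intermediate_visited <- logical(0)
  }
  res
}

#' Compare staircases under different forcing periods
#'
#' Computes the Devil's staircase under each single forcing period in
#' \code{periods} and, when \code{mixture_weights} are supplied, under
#' the two-component mixture
#' \eqn{k = k_0 (1 + \alpha w_1 \cos(2\pi t/T_1)
#'                 + \alpha w_2 \cos(2\pi t/T_2))}.
#' The response is essentially set by the internal period, not by the
#' forcing period: a 20-kyr forcing produces the same 40-80-120-kyr
#' succession through double jumps.
#'
#' @inheritParams staircase
#' @param periods vector of forcing periods (yr).
#' @param mixture_weights optional non-negative weights, one per period
#'   (only the two-period case is supported for the mixture).
#' @return list of \code{\link{staircase}} results, one per forcing
#'   (named by period, plus \code{"mixture"}), with attribute
#'   \code{comparison}: a data frame of per-gamma D values side by side
#'   and their differences from the first forcing.
#' @export
forcing_comparison <- function(params, gamma_grid, alpha = 0.003,
                               periods = c(2e4, 4e4),
                               mixture_weights = NULL,
                               horizon = 1e8, n_last = 50,
                               settings = solver_settings()) {
  stopifnot(all(periods > 0))
  out <- list()
  for (Tf in periods) {
    p <- alk_params(I0 = params$I0, k0 = params$k0, M = params$M,
                    alpha = alpha, T_force = Tf,
                    A0 = params$A0, z0 = params$z0)
    out[[format(Tf)]] <- staircase(p, gamma_grid, alpha = alpha,
                                   horizon = horizon, n_last = n_last,
                                   settings = settings)
  }
  if (!is.null(mixture_weights)) {
    if (length(mixture_weights) != length(periods) ||
        any(mixture_weights < 0))
      stop("'mixture_weights' must be non-negative, one per period",
           call. = FALSE)
    w <- mixture_weights
    keep <- w > 0
    a <- alpha * w[keep]; Ts <- periods[keep]
    p <- alk_params(I0 = params$I0, k0 = params$k0, M = params$M,
                    alpha = a, T_force = Ts,
                    A0 = params$A0, z0 = params$z0)
    out[["mixture"]] <- staircase(p, gamma_grid, alpha = a,
                                  horizon = horizon, n_last = n_last,
                                  settings = settings)
  }
  D <- sapply(out, function(s) s$D)
  cmp <- data.frame(gamma = gamma_grid, D)
  names(cmp) <- c("gamma", names(out))
  for (nm in names(out)[-1])
    cmp[[paste0("dD_", nm)]] <- cmp[[nm]] - cmp[[names(out)[1]]]
  attr(out, "comparison") <- cmp
  out
}
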