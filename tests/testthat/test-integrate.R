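# Time integration: solver contract, breakpoints, stroboscopic map,
# variational system.

test_that("trajectory at the exact equilibrium stays constant", {
  p <- alk_params()
  eq <- equilibrium(p)
  tr <- simulate_model(p, gamma_constant(0), c(0, 1e6), init = eq)
  expect_lt(max(abs(tr$A - 2.0)), 1e-8)
  expect_lt(max(abs(tr$P - eq[["P"]])), 1e-6)
})

test_that("below the Hopf threshold perturbations spiral back to equilibrium", {
  p <- alk_params()
  tr <- simulate_model(p, gamma_constant(0.02), c(0, 1.5e7))
  eq <- equilibrium(p, 0.02)
  # oscillatory on the way in ...
  expect_gt(length(detect_cycles(tr)$periodicities), 10)
  # ... and the envelope of the distance to equilibrium decays
  d <- abs(tr$A - eq[["A"]])
  n <- nrow(tr)
  thirds <- split(d, cut(seq_len(n), 3, labels = FALSE))
  peaks <- vapply(thirds, max, numeric(1))
  expect_true(all(diff(peaks) < 0))
  expect_lt(tail(d, 1), 0.05 * 0.05)
})

test_that("above the threshold a self-sustained sawtooth persists", {
  p <- alk_params()
  tr <- simulate_model(p, gamma_constant(0.07), c(0, 1.5e7))
  cyc <- detect_cycles(tr)
  late <- tail(cyc$amplitudes, 30)
  expect_gt(min(late), 0.1)                 # finite amplitude, not decaying
  expect_lt(diff(range(late)) / mean(late), 0.01)   # settled limit cycle
  # sawtooth asymmetry: rise (max - preceding min interval) longer than fall
  k <- length(cyc$min_times)
  fall <- cyc$min_times[seq_len(k)] - cyc$max_times[seq_len(k)]
  rise <- cyc$max_times[-1][seq_len(k - 1)] - cyc$min_times[seq_len(k - 1)]
  expect_gt(mean(tail(rise, 20)), 3 * mean(tail(fall, 20)))
})

test_that("periodicity estimates obey the tolerance-halving and grid contracts", {
  p <- alk_params()
  span <- c(0, 6e6)
  per_of <- function(settings) {
    tr <- simulate_model(p, gamma_constant(0.07), span, settings = settings)
    mean(tail(detect_cycles(tr)$periodicities, 20))
  }
  base <- per_of(solver_settings())
  halved <- per_of(solver_settings(rel_tol = 5e-13, abs_tol = 5e-13))
  loose <- per_of(solver_settings(rel_tol = 1e-10, abs_tol = 1e-10))
  fine_grid <- per_of(solver_settings(resample_dt = 50))
  expect_lt(abs(halved - base) / base, 1e-3)
  expect_lt(abs(loose - base) / base, 1e-3)
  expect_lt(abs(fine_grid - base) / base, 1e-3)
})

test_that("a step schedule and a 1-yr ramp produce near-identical trajectories", {
  p <- alk_params(alpha = 0.003)
  t_c <- 2e6
  span <- c(0, 4e6)
  tr_step <- simulate_model(p, gamma_step(0.06, 0.09, t_c), span)
  tr_ramp <- simulate_model(p, gamma_ramp(0.06, 0.09, t_c, 1), span)
  before <- tr_step$t < t_c
  expect_lt(max(abs(tr_step$A[before] - tr_ramp$A[before])), 1e-12)
  # just after the ramp window, before trajectory divergence can amplify
  # the O(1 yr) difference
  after <- tr_step$t > t_c + 1 & tr_step$t <= t_c + 1e4
  expect_lt(max(abs(tr_step$A[after] - tr_ramp$A[after])), 1e-6)
  # and the gamma column reflects the schedule exactly
  expect_equal(tr_step$gamma[tr_step$t < t_c][1], 0.06)
  expect_equal(tail(tr_step$gamma, 1), 0.09)
})

test_that("stroboscopic map fixes the equilibrium and composes over periods", {
  p0 <- alk_params(alpha = 0)
  eq <- equilibrium(p0, 0.03)
  expect_equal(stroboscopic_map(eq, p0, 0.03, n = 3), eq, tolerance = 1e-9)
  pf <- alk_params(alpha = 0.003)
  st <- c(A = 2.05, P = log(4e-5))
  one <- stroboscopic_map(st, pf, 0.06, n = 1)
  # composing n = 1 from the advanced state differs from n = 2 only by
  # the forcing phase, which is identical after a full period
  two_a <- stroboscopic_map(one, pf, 0.06, n = 1)
  two_b <- stroboscopic_map(st, pf, 0.06, n = 2)
  expect_equal(two_a, two_b, tolerance = 1e-8)
})

test_that("variational matrix obeys Liouville and matches finite differences", {
  p <- alk_params(alpha = 0.003)
  st <- c(A = 2.05, P = log(4e-5))
  dur <- 4e4
  Phi <- propagate_variational(st, p, 0.06, dur)
  expect_equal(det(Phi), exp(attr(Phi, "liouville")), tolerance = 1e-8)
  # short-duration limit: Phi ~ I + J(0) dt, with the forced reaction
  # rate k(0) in the Jacobian
  k0t <- forcing_rate(0, p)
  C <- exp(st[["P"]])
  J0 <- matrix(c(p$I0 * 0.06 * alkcycle:::sigmoid_feedback_prime(
                   st[["A"]], p$A0, p$z0) - k0t * C,
                 k0t, -k0t * st[["A"]] * C, 0), 2, 2)
  Phi0 <- propagate_variational(st, p, 0.06, 1)
  expect_equal(matrix(as.numeric(Phi0), 2, 2), diag(2) + J0,
               tolerance = 1e-6)
  # columns from finite-difference perturbations of the initial state
  h <- 1e-7
  prop <- function(s) {
    parms <- alkcycle:::pack_parms(p, gamma_constant(0.06))
    out <- alkcycle:::ode_piece(c(A = unname(s[1]), P = unname(s[2])),
                                c(0, dur), parms, solver_settings())
    c(out[nrow(out), "A"], out[nrow(out), "P"])
  }
  fd <- cbind((prop(st + c(h, 0)) - prop(st - c(h, 0))) / (2 * h),
              (prop(st + c(0, h)) - prop(st - c(0, h))) / (2 * h))
  expect_equal(matrix(as.numeric(Phi), 2, 2), unname(fd),
               tolerance = 1e-4)
})

test_that("blow-up and bad inputs produce diagnosable errors", {
  p <- alk_params()
  expect_error(simulate_model(p, gamma_constant(0.07), c(5, 5)), "t_span")
  expect_error(simulate_model(p, gamma_constant(0.07), c(0, 1e6),
                              init = c(A = Inf, P = 0)), "init")
  expect_error(solver_settings(rel_tol = 0), "rel_tol")
  expect_error(propagate_variational(c(A = 2, P = -10), p, 0.06, -5),
               "duration")
})
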