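# Cycle metrics: peak detection on constructed fixtures, asymptotic
# periodicity, locking, staircase degeneracies, length-amplitude fit.

test_that("peak detector is exact on a synthetic sawtooth", {
  traj <- make_sawtooth(period = 4e4, amplitude = 0.4)
  cyc <- detect_cycles(traj)
  expect_equal(unique(round(cyc$periodicities, 6)), 4e4)
  expect_equal(unique(round(cyc$amplitudes, 10)), 0.4)
  expect_equal(length(cyc$periodicities), length(cyc$max_times) - 1L)
})

test_that("peak detector is exact on a pure sinusoid", {
  traj <- make_sine(period = 4e4, half_amp = 0.2)
  cyc <- detect_cycles(traj)
  expect_equal(mean(cyc$periodicities), 4e4, tolerance = 1e-6)
  expect_lt(diff(range(cyc$periodicities)), 1)
  expect_equal(mean(cyc$amplitudes), 0.4, tolerance = 1e-4)
})

test_that("small high-frequency ripple does not change the cycle count", {
  base <- make_sawtooth(period = 4e4, amplitude = 0.4)
  n0 <- length(detect_cycles(base)$periodicities)
  rippled <- base
  rippled$A <- rippled$A + 0.004 * sin(2 * pi * rippled$t / 1500)
  cyc <- detect_cycles(rippled)
  expect_equal(length(cyc$periodicities), n0)
  expect_equal(mean(cyc$periodicities), 4e4, tolerance = 1e-3)
})

test_that("degenerate series yield an empty result with a warning", {
  flat <- data.frame(t = seq(0, 1e5, by = 100), A = 2)
  expect_warning(cyc <- detect_cycles(flat), "fewer than 2")
  expect_length(cyc$periodicities, 0)
  ramp <- data.frame(t = seq(0, 1e5, by = 100),
                     A = seq(2, 3, length.out = 1001))
  expect_warning(detect_cycles(ramp), "fewer than 2")
})

test_that("lock_multiple classifies durations against the forcing period", {
  l1 <- lock_multiple(80000, 40000)
  expect_identical(l1$n, 2L); expect_true(l1$locked)
  expect_equal(l1$residual, 0)
  l2 <- lock_multiple(87000, 40000)
  expect_identical(l2$n, 2L); expect_false(l2$locked)
  l3 <- lock_multiple(120000, 40000)
  expect_identical(l3$n, 3L); expect_true(l3$locked)
  # tolerance boundary
  expect_true(lock_multiple(40800, 40000)$locked)
  expect_false(lock_multiple(40801, 40000)$locked)
})

test_that("below the bifurcation the damped periodicity matches the linear one", {
  p <- alk_params()
  for (g in c(0.01, 0.03)) {
    est <- suppressWarnings(asymptotic_periodicity(
      p, g, alpha = 0, horizon = 6e6, n_last = 30,
      init = default_init(p, g, dA = 0.01)))
    expect_true(est$below_hopf)
    expect_equal(est$periodicity, linear_internal_period(p, g),
                 tolerance = 0.02)
  }
})

test_that("unforced staircase degenerates to the diagonal D = T0", {
  st <- staircase(alk_params(), c(0.06, 0.07), alpha = 0, horizon = 1e7)
  expect_equal(st$D, st$T0, tolerance = 1e-12)
})

test_that("internal period grows roughly linearly with gamma above threshold", {
  st <- cached("stair_T0_coarse", {
    staircase(alk_params(), seq(0.06, 0.12, by = 0.01), alpha = 0.003,
              horizon = 2e7, continue = FALSE)
  })
  expect_true(all(diff(st$T0) > 0))
  fit <- lm(T0 ~ gamma, data = as.data.frame(st))
  expect_gt(summary(fit)$r.squared, 0.95)
})

test_that("length-amplitude relation: exact proportional data and model cycles", {
  # exact synthetic proportional cycles
  per <- seq(4e4, 1.2e5, by = 1e4)
  amp <- 3e-6 * per
  fake <- structure(list(periodicities = per, amplitudes = amp,
                         max_times = cumsum(c(0, per)),
                         mid_times = cumsum(c(0, per))[-1] - per / 2),
                    class = "cycle_series")
  fit <- length_amplitude_fit(fake)
  expect_equal(fit$slope, 3e-6, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  # pooled simulator output across gamma: strong positive linear relation
  cycs <- cached("pooled_cycles", {
    lapply(c(0.07, 0.09, 0.11), function(g) {
      tr <- simulate_model(alk_params(), gamma_constant(g), c(5e6, 2e7))
      detect_cycles(tr)
    })
  })
  pooled <- length_amplitude_fit(cycs)
  expect_gt(pooled$slope, 0)
  expect_gt(pooled$r_squared, 0.9)
  # single locked run is degenerate
  tr <- settled_run_009()
  cyc9 <- detect_cycles(tr)
  tail_cyc <- structure(list(
    periodicities = tail(cyc9$periodicities, 30),
    amplitudes = tail(cyc9$amplitudes, 30)), class = "cycle_series")
  expect_warning(dfit <- length_amplitude_fit(tail_cyc), "constant")
  expect_true(dfit$degenerate)
})
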