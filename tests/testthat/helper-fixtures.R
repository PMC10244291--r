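# Shared fixtures and a memo cache so expensive simulations run once per
# test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

std_params <- function(alpha = 0) alk_params(alpha = alpha)

# synthetic uniform-grid series -------------------------------------------

# triangle sawtooth: slow linear rise, fast linear fall, extrema on grid
make_sawtooth <- function(period = 4e4, amplitude = 0.4, t_end = 1e6,
                          dt = 100, fall_frac = 0.05) {
  t <- seq(0, t_end, by = dt)
  ph <- (t %% period) / period
  rise <- ph < (1 - fall_frac)
  A <- ifelse(rise, ph / (1 - fall_frac),
              (1 - ph) / fall_frac)
  data.frame(t = t, A = 2 + amplitude * A)
}

make_sine <- function(period = 4e4, half_amp = 0.2, t_end = 1e6,
                      dt = 100) {
  t <- seq(0, t_end, by = dt)
  data.frame(t = t, A = 2 + half_amp * sin(2 * pi * t / period))
}

# converged runs shared across files --------------------------------------

settled_run_006 <- function() cached("settled_006", {
  simulate_model(std_params(0.003), gamma_constant(0.06), c(0, 2e7))
})

settled_run_009 <- function() cached("settled_009", {
  simulate_model(std_params(0.003), gamma_constant(0.09), c(0, 4e7))
})

orbit_006_n1 <- function() cached("orbit_006_n1", {
  tr <- settled_run_006()
  find_periodic_orbit(std_params(0.003), 0.06, 1,
                      c(A = tr$A[nrow(tr)], P = tr$P[nrow(tr)]))
})

orbit_009_n1 <- function() cached("orbit_009_n1", {
  find_periodic_orbit(std_params(0.003), 0.09, 1, orbit_006_n1()$state0)
})

orbit_009_n2 <- function() cached("orbit_009_n2", {
  tr <- settled_run_009()
  find_periodic_orbit(std_params(0.003), 0.09, 2,
                      c(A = tr$A[nrow(tr)], P = tr$P[nrow(tr)]))
})

step_experiment_0609 <- function() cached("step_0609", {
  step_experiment(0.06, 0.09)
})

step_experiment_0912 <- function() cached("step_0912", {
  step_experiment(0.09, 0.12, horizon = 1e8)
})
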