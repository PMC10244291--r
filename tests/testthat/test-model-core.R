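# Local analysis of the calcifier-alkalinity system: feedback sigmoid,
# forcing, right-hand side, equilibrium, Jacobian, Hopf threshold,
# linearised internal period.

test_that("feedback sigmoid is odd, bounded, increasing, with slope 1/z0", {
  A0 <- 2.0; z0 <- 0.1
  grid <- seq(-3, 3, length.out = 241)
  s_plus <- sigmoid_feedback(A0 + grid, A0, z0)
  s_minus <- sigmoid_feedback(A0 - grid, A0, z0)
  expect_equal(s_plus, -s_minus, tolerance = 1e-14)
  expect_true(all(s_plus > -1 & s_plus < 1))
  expect_true(all(diff(sigmoid_feedback(seq(0, 4, by = 0.01), A0, z0)) > 0))
  # midpoint and printed-formula value at A = 2.1
  expect_identical(sigmoid_feedback(A0, A0, z0), 0)
  expect_equal(sigmoid_feedback(2.1, A0, z0), (2 / pi) * atan(pi / 2),
               tolerance = 1e-15)
  # slope at midpoint equals 1/z0 (central difference)
  h <- 1e-6
  slope <- (sigmoid_feedback(A0 + h, A0, z0) -
              sigmoid_feedback(A0 - h, A0, z0)) / (2 * h)
  expect_equal(slope, 1 / z0, tolerance = 1e-6)
  # saturation limits
  expect_equal(sigmoid_feedback(1e9, A0, z0), 1, tolerance = 1e-8)
  expect_equal(sigmoid_feedback(-1e9, A0, z0), -1, tolerance = 1e-8)
  expect_error(sigmoid_feedback(2, A0, z0 = -1), "z0")
})

test_that("forcing rate has the prescribed amplitude, phase and period", {
  p <- alk_params(alpha = 0.003)
  expect_equal(forcing_rate(0, p), 0.05015)
  expect_equal(forcing_rate(p$T_force / 2, p), 0.05 * (1 - 0.003))
  t <- seq(0, 4e5, by = 1000)
  k <- forcing_rate(t, p)
  expect_true(all(k >= 0.05 * 0.997 - 1e-15 & k <= 0.05 * 1.003 + 1e-15))
  expect_equal(forcing_rate(t + 4e4, p), k, tolerance = 1e-12)
  # unforced limit
  p0 <- alk_params(alpha = 0)
  expect_equal(forcing_rate(c(0, 1e4, 3.3e5), p0), rep(0.05, 3))
  # amplitude >= 1 would let k change sign
  expect_error(alk_params(alpha = 1.0), "alpha")
})

test_that("rhs matches the (A, C) formulation under the log transform", {
  p <- alk_params()
  set.seed(42)
  for (i in 1:25) {
    A <- runif(1, 0.5, 4); C <- 10^runif(1, -7, -3)
    g <- runif(1, 0, 0.12)
    d <- model_rhs(0, c(A = A, P = log(C)), p, g)
    I <- p$I0 * (1 + g * sigmoid_feedback(A, p$A0, p$z0))
    dA <- I - p$k0 * A * C
    dC <- p$k0 * A * C - p$M * C
    expect_equal(unname(d[1]), dA, tolerance = 1e-12)
    # dP/dt = (dC/dt)/C
    expect_equal(unname(d[2]), dC / C, tolerance = 1e-12)
  }
})

test_that("rhs vanishes at the closed-form equilibrium, for any gamma", {
  p <- alk_params()
  for (g in c(0, 0.07, 0.12)) {
    eq <- equilibrium(p, g)
    expect_equal(eq[["A"]], 2.0)
    expect_equal(exp(eq[["P"]]), 4e-5, tolerance = 1e-12)
    expect_lt(max(abs(model_rhs(0, eq, p, g))), 1e-12)
  }
  # perturbed k0 moves A* and makes C* gamma-dependent
  p2 <- alk_params(k0 = 0.1)
  eq2 <- equilibrium(p2, 0.07)
  expect_equal(eq2[["A"]], 1.0)
  expect_equal(exp(eq2[["P"]]),
               p2$I0 * (1 + 0.07 * sigmoid_feedback(1, 2, 0.1)) / p2$M,
               tolerance = 1e-12)
  expect_lt(max(abs(model_rhs(0, eq2, p2, 0.07))), 1e-12)
})

test_that("rhs rejects non-finite states and overflowing exp(P)", {
  p <- alk_params()
  expect_error(model_rhs(0, c(A = NaN, P = -10), p, 0), "non-finite")
  expect_error(model_rhs(0, c(A = 2, P = 800), p, 0), "overflow")
})

test_that("analytic Jacobian agrees with central finite differences", {
  p <- alk_params()
  # frozen reference at the default equilibrium
  J_eq <- jacobian_at(equilibrium(p), p, gamma = 0)
  expect_equal(unname(J_eq),
               matrix(c(-2e-6, 0.05, -4e-6, 0), 2, 2), tolerance = 1e-10)
  set.seed(7)
  for (i in 1:10) {
    st <- c(A = runif(1, 1, 3), P = log(10^runif(1, -6, -4)))
    g <- runif(1, 0, 0.12)
    J <- jacobian_at(st, p, g)
    h <- 1e-6
    fd <- matrix(0, 2, 2)
    for (j in 1:2) {
      e <- c(0, 0); e[j] <- h
      fd[, j] <- (model_rhs(0, st + e, p, g) -
                    model_rhs(0, st - e, p, g)) / (2 * h)
    }
    expect_equal(unname(J), fd, tolerance = 1e-5)
  }
})

test_that("Jacobian trace and determinant at equilibrium follow the closed forms", {
  p <- alk_params()
  for (g in c(0, 0.05, 0.09)) {
    J <- jacobian_at(equilibrium(p, g), p, g)
    C_star <- 4e-5
    expect_equal(sum(diag(J)), p$I0 * g / p$z0 - p$k0 * p$I0 / p$M,
                 tolerance = 1e-12)
    expect_equal(det(J), p$k0 * p$M * C_star, tolerance = 1e-12)
  }
})

test_that("Hopf threshold: closed form, eigenvalue scan, and sign change agree", {
  p <- alk_params()
  expect_equal(hopf_threshold(p), 0.05)
  expect_equal(hopf_threshold(p, method = "scan"), 0.05, tolerance = 1e-6)
  # z0 scales the threshold linearly
  expect_equal(hopf_threshold(alk_params(z0 = 0.2)), 0.10)
  # randomized parameter sets preserving A* = A0
  set.seed(11)
  for (i in 1:8) {
    k0 <- runif(1, 0.02, 0.2)
    M <- runif(1, 0.5, 2) # A* = M/k0
    z0 <- runif(1, 0.02, 0.5)
    pp <- alk_params(k0 = k0, M = M, z0 = z0, A0 = M / k0)
    gH <- k0 * z0 / M
    if (gH >= 1) next
    expect_equal(hopf_threshold(pp), gH, tolerance = 1e-12)
    expect_equal(hopf_threshold(pp, method = "scan"), gH, tolerance = 1e-6)
  }
  # eigenvalue real part changes sign across the threshold
  lead_re <- function(g) max(Re(eigen(jacobian_at(equilibrium(p, g), p, g),
                                      only.values = TRUE)$values))
  expect_lt(lead_re(0.049), 0)
  expect_gt(lead_re(0.051), 0)
})

test_that("linearised internal period is about 14 kyr and scales with I0", {
  p <- alk_params()
  # 2*pi / sqrt(det - tr^2/4) with det = 2e-7, tr = -2e-6
  expect_equal(linear_internal_period(p), 2 * pi / sqrt(2e-7 - 1e-12),
               tolerance = 1e-12)
  expect_equal(linear_internal_period(p) / 1e3, 14.05, tolerance = 1e-3)
  # period ~ 1/sqrt(I0): quadrupling I0 halves it (to leading order)
  p4 <- alk_params(I0 = 1.6e-5)
  expect_equal(linear_internal_period(p4) / linear_internal_period(p),
               0.5, tolerance = 2e-3)
  # gamma below the threshold barely changes it
  ratio <- linear_internal_period(p, 0.04) / linear_internal_period(p, 0)
  expect_equal(ratio, 1, tolerance = 0.01)
})

test_that("parameter validation is strict", {
  expect_error(alk_params(I0 = -1), "I0")
  expect_error(alk_params(k0 = 0), "k0")
  expect_error(alk_params(z0 = Inf), "z0")
  expect_error(alk_params(alpha = c(0.5, 0.6)), "sum")
  expect_error(equilibrium(alk_params(), gamma = 1.2), "gamma")
})
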