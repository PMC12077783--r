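# Constitutive laws: hand-evaluated forces, Newton's third law, modulus
# switching, detachment, and the closed-form relaxation oracles.

test_that("Kelvin-Voigt bond force follows Hooke's law with modulus switching", {
  # stretched bond: tensile modulus active, attractive
  expect_equal(kv_bond_force(1, 0, ka = 10, kr = 1, eta_i = 0), 10)
  # compressed bond: repulsive modulus active, force reverses sign
  expect_equal(kv_bond_force(-0.5, 0, ka = 10, kr = 2, eta_i = 0), -1)
  # viscous term opposes gap change
  expect_equal(kv_bond_force(0, 1, ka = 10, kr = 1, eta_i = 0.3), 0.3)
  # detached bond exerts nothing
  expect_equal(kv_bond_force(5, 1, ka = 10, kr = 1, eta_i = 0.3,
                             zone_max = 4), 0)
  # rest state is force-free
  expect_equal(kv_bond_force(0, 0, 10, 1, 0.5), 0)
})

test_that("two-agent KV accelerations are equal, opposite, and attractive", {
  cl <- cluster_config(2, gradient_strength = 1, k_min = 10)
  rh <- rheology_params("KV", eta_i = 0)
  # gap +1 (positions 0, 3): trailing +10, leading -10
  acc <- chain_accelerations(c(0, 3), c(0, 0), cl, rh)
  expect_equal(acc$a, c(10, -10))
  # beyond zone_max: both zero
  far <- chain_accelerations(c(0, 8), c(0, 0), cl, rh)
  expect_equal(far$a, c(0, 0))
})

test_that("paired force contributions cancel for random chain states", {
  set.seed(42)
  cl <- cluster_config(6, gradient_strength = 10, k_min = 0.3)
  for (model in c("KV", "SLS")) {
    rh <- rheology_params(model, eta_i = 0.2)
    for (i in 1:20) {
      gaps <- runif(5, -0.5, 3)
      x <- cumsum(c(0, gaps + 2))
      v <- rnorm(6, 0, 0.5)
      h <- rnorm(5, 0, 0.5)
      acc <- chain_accelerations(x, v, cl, rh, h)
      expect_lt(abs(sum(acc$a)), 1e-12)
    }
  }
})

test_that("SLS jerk is zero at rest and rejects non-positive tau", {
  expect_equal(sls_jerk(0, 0, 0, ka = 1, kr = 1, k2 = 1, tau = 2), 0)
  expect_error(sls_jerk(1, 0, 0, 1, 1, 1, tau = 0), "tau")
})

test_that("SLS step-strain stress relaxes to the K1 plateau with constant tau", {
  # hold the gap fixed at g0: the bond stress sigma(t) = -h(t) must follow
  # the closed form g0 * (K1 + K2 * exp(-t / tau))
  g0 <- 0.8; k1 <- 0.2; k2 <- 1; tau <- 12
  h <- -(k1 + k2) * g0          # unrelaxed stress right after the step
  dt <- 1
  for (t in seq_len(8 * tau)) {
    f1 <- sls_jerk(g0, 0, h, k1, 1, k2, tau)
    f2 <- sls_jerk(g0, 0, h + dt / 2 * f1, k1, 1, k2, tau)
    f3 <- sls_jerk(g0, 0, h + dt / 2 * f2, k1, 1, k2, tau)
    f4 <- sls_jerk(g0, 0, h + dt * f3, k1, 1, k2, tau)
    h <- h + dt / 6 * (f1 + 2 * f2 + 2 * f3 + f4)
    sigma_exact <- g0 * (k1 + k2 * exp(-t / tau))
    expect_lt(abs(-h - sigma_exact) / sigma_exact, 0.01)
  }
})

test_that("two-agent KV relaxation matches the velocity-zeroing closed form", {
  # with velocities zeroed every step (eta_env = 0) and eta_i = 0, each unit
  # step from rest maps the gap by the undamped factor cos(sqrt(2 K) dt)
  k <- 0.1; delta <- 0.5
  cfg <- relax_config("KV", n = 2, n_steps = 40, k_min = k, grad = 1)
  cfg$rheology$eta_i <- 0
  state <- list(x = c(0, 2 + delta), v = c(0, 0))
  factor <- cos(sqrt(2 * k))
  for (s in 1:40) {
    state <- step_cluster(state, cfg)
    gap_exact <- delta * factor^s
    gap_sim <- state$x[2] - state$x[1] - 2
    expect_lt(abs(gap_sim - gap_exact) / gap_exact, 0.01)
  }
  # monotone decay toward touching, no overshoot
  expect_gt(state$x[2] - state$x[1], 2)
})

test_that("SLS relaxation approaches KV as tau -> 0 at fixed bond viscosity", {
  # independent fine-step RK4 on the two constitutive kernels in gap
  # coordinates, both in the bond-level normalisation of the third-order law
  eta <- 0.4; k1 <- 0.5; g0 <- 1
  kv_deriv <- function(y) {         # y = (gap, gap_rate)
    c(y[2], -kv_bond_force(y[1], y[2], k1, k1, eta))
  }
  sls_deriv <- function(tau) function(y) {  # y = (gap, gap_rate, gap_accel)
    k2 <- eta / tau
    c(y[2], y[3], sls_jerk(y[1], y[2], y[3], k1, k1, k2, tau))
  }
  tgrid <- seq(0, 10, by = 0.01)
  kv_traj <- rk4(kv_deriv, c(g0, 0), 0.01, length(tgrid) - 1)[, 1]
  err <- sapply(c(0.3, 0.1, 0.03), function(tau) {
    sls_traj <- rk4(sls_deriv(tau), c(g0, 0, 0), 0.01,
                    length(tgrid) - 1)[, 1]
    max(abs(sls_traj - kv_traj))
  })
  expect_true(all(diff(err) < 0))   # converges as tau shrinks
  expect_lt(err[3], 0.05)
})

test_that("total energy of an unforced damped chain is non-increasing", {
  cl <- cluster_config(5, gradient_strength = 10, k_min = 0.1)
  cfg <- relax_config("KV", n = 5, n_steps = 200, eta_env = 0.9,
                      k_min = 0.1)
  cfg$rheology$eta_i <- 0.3
  ka <- initialize_cluster(cl)$bonds$ka
  energy <- function(st) {
    gaps <- diff(st$x) - 2
    k_active <- ifelse(gaps > 0, ka, cl$kr)
    sum(st$v^2) / 2 + sum(k_active * gaps^2) / 2
  }
  state <- list(x = c(0, 2.5, 4.5, 7, 9.5), v = rep(0, 5))
  e <- energy(state)
  for (s in 1:200) {
    state <- step_cluster(state, cfg)
    e_new <- energy(state)
    expect_lte(e_new, e + 1e-10)
    e <- e_new
  }
})
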