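# Shared configuration factories for the test suite.

# The reference cluster: 5 cells, gradient strength 10, package defaults.
ref_config <- function(model = "SLS", grad = 10, n = 5, amp = 1, T = 5,
                       mode = "ends_only", n_steps = 2000, seed = 1,
                       interior_scale = 0.25, k_min = 0.02) {
  simulation_config(
    cluster = cluster_config(n_cells = n, gradient_strength = grad,
                             k_min = k_min),
    rheology = rheology_params(model),
    protrusion = protrusion_config(mode, amplitude = amp, period = T,
                                   interior_scale = interior_scale),
    n_steps = n_steps, seed = seed)
}

# A relaxation-only configuration (no protrusion event ever fires).
relax_config <- function(model = "SLS", n = 5, n_steps = 100, eta_env = NULL,
                         k_min = 0.02, grad = 10) {
  suppressWarnings(simulation_config(
    cluster = cluster_config(n_cells = n, gradient_strength = grad,
                             k_min = k_min),
    rheology = rheology_params(model),
    protrusion = protrusion_config("ends_only", period = n_steps + 1L),
    eta_env = eta_env, n_steps = n_steps, seed = 1))
}

# Minimal fake trajectory carrying only a COM series (for analysis tests).
fake_traj <- function(com) {
  structure(list(com = com), class = "cohesim_trajectory")
}

# Classical RK4 integrator used as an independent oracle in rheology tests.
rk4 <- function(deriv, y0, dt, nsteps) {
  y <- y0
  out <- matrix(NA_real_, nsteps + 1L, length(y0))
  out[1L, ] <- y
  for (s in seq_len(nsteps)) {
    k1 <- deriv(y)
    k2 <- deriv(y + dt / 2 * k1)
    k3 <- deriv(y + dt / 2 * k2)
    k4 <- deriv(y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[s + 1L, ] <- y
  }
  out
}
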