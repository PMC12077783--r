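#' Cluster geometry and cohesion-gradient configuration
#'
#' Defines a linear cluster of `n_cells` unit-radius, unit-mass agents whose
#' neighbouring pairs are joined by bonds with tensile stiffness increasing
#' linearly from `k_min` (trailing bond) to `gradient_strength * k_min`
#' (leading bond).  The repulsive stiffness `kr` and the detachment distance
#' `zone_max` are shared by all bonds.
#'
#' @param n_cells integer >= 2, number of agents. Agent 1 is the trailing
#'   cell, agent `n_cells` the leading cell (the gradient increases with x).
#' @param gradient_strength ratio >= 1 of the strongest to the weakest
#'   tensile stiffness in the linear gradient; 1 means no gradient.
#' @param k_min tensile stiffness of the weakest (trailing) bond, > 0.
#' @param kr compressive (repulsive) stiffness, identical for all bonds.
#' @param zone_max detachment gap in radii: a bond whose gap exceeds
#'   `zone_max` exerts no force.  Must exceed one cell diameter (2 radii).
#' @param bond_gradient how per-bond stiffnesses are derived from the
#'   gradient: `"midpoint"` (default) spaces the `n_cells - 1` bond
#'   stiffnesses linearly from `k_min` to `k_max`; `"leading"` assigns each
#'   bond the per-agent stiffness of its leading member.
#' @return an object of class `cluster_config`.
#' @examples
#' cluster_config(n_cells = 5, gradient_strength = 10)
#' @export
cluster_config <- function(n_cells = 5, gradient_strength = 10,
                           k_min = 0.02, kr = 1, zone_max = 4,
                           bond_gradient = c("midpoint", "leading")) {
  bond_gradient <- match.arg(bond_gradient)
  if (length(n_cells) != 1L || n_cells < 2 || n_cells != round(n_cells))
    stop("'n_cells' must be a single integer >= 2")
  if (gradient_strength < 1)
    stop("'gradient_strength' must be >= 1")
  if (k_min <= 0) stop("'k_min' must be > 0")
  if (kr <= 0) stop("'kr' must be > 0")
  if (zone_max <= 2) stop("'zone_max' must exceed one cell diameter (2 radii)")
  structure(list(n_cells = as.integer(n_cells),
                 gradient_strength = gradient_strength,
                 k_min = k_min,
                 k_max = gradient_strength * k_min,
                 kr = kr, zone_max = zone_max,
                 bond_gradient = bond_gradient,
                 r = 1, m = 1),
            class = "cluster_config")
}

#' Bond rheology parameters
#'
#' Constitutive law of the intercellular bonds.  `"KV"` is a Kelvin-Voigt
#' element (spring and damper in parallel; no creep): bond force
#' `K * gap + eta_i * d(gap)/dt`.  `"SLS"` is a Standard Linear Solid (a
#' second spring `k2` in series with the damper), which adds stress
#' relaxation with time constant `tau = eta / k2`; its bond stress obeys a
#' third-order law in the gap and is integrated as per-bond dynamic state.
#'
#' @param model `"SLS"` (default) or `"KV"`.
#' @param eta_i bond (intracellular) viscosity for the KV damper, >= 0.
#' @param k2 SLS series spring modulus, > 0 (SLS only).
#' @param tau SLS relaxation time `eta / k2`, > 0 (SLS only).
#' @return an object of class `rheology_params`.
#' @export
rheology_params <- function(model = c("SLS", "KV"), eta_i = 0.1,
                            k2 = 1, tau = 12) {
  model <- match.arg(model)
  if (eta_i < 0) stop("'eta_i' must be >= 0")
  if (model == "SLS") {
    if (k2 <= 0) stop("'k2' must be > 0 for the SLS model")
    if (tau <= 0) stop("'tau' must be > 0 for the SLS model")
  }
  structure(list(model = model, eta_i = eta_i, k2 = k2, tau = tau),
            class = "rheology_params")
}

#' Protrusion protocol configuration
#'
#' Protrusions are instantaneous displacement events applied every `period`
#' timesteps.  In the stochastic modes each selected agent draws a signed
#' displacement from a zero-mean Gaussian with standard deviation
#' `amplitude` (scaled by `interior_scale` for interior agents in `"hybrid"`
#' mode); a proposal that would bring the agent within one diameter of a
#' neighbour is rejected outright and the agent does not move.  The
#' deterministic mode instead displaces the two outermost agents by the
#' fixed length `deterministic_amplitude` according to `deterministic_submode`.
#'
#' @param mode `"ends_only"` (default; only agents 1 and N protrude),
#'   `"all_cells"`, `"hybrid"` (ends at full amplitude, interior at
#'   `interior_scale * amplitude`), or `"deterministic"`.
#' @param amplitude Gaussian standard deviation of proposed displacements,
#'   in radii; must be > 0 for the stochastic modes.
#' @param period number of timesteps between protrusion events (>= 1); the
#'   intervening steps are pure relaxation.
#' @param interior_scale multiplier in `[0, 1]` applied to `amplitude` for
#'   interior agents in `"hybrid"` mode.
#' @param deterministic_submode `"outward_step"` (both ends step away from
#'   the centre of mass), `"inphase_oscillation"` (both ends step in the
#'   same axial direction, alternating each event) or
#'   `"antiphase_oscillation"` (both ends step toward/away from the centre,
#'   alternating each event).
#' @param deterministic_amplitude fixed displacement length (radii) used by
#'   the deterministic submodes.
#' @return an object of class `protrusion_config`.
#' @export
protrusion_config <- function(mode = c("ends_only", "all_cells", "hybrid",
                                       "deterministic"),
                              amplitude = 1, period = 15,
                              interior_scale = 0.25,
                              deterministic_submode = c("outward_step",
                                                        "inphase_oscillation",
                                                        "antiphase_oscillation"),
                              deterministic_amplitude = 1) {
  mode <- match.arg(mode)
  deterministic_submode <- match.arg(deterministic_submode)
  if (mode != "deterministic" && amplitude <= 0)
    stop("'amplitude' must be > 0 for stochastic protrusion modes")
  if (period < 1 || period != round(period))
    stop("'period' must be a positive integer")
  if (interior_scale < 0 || interior_scale > 1)
    stop("'interior_scale' must lie in [0, 1]")
  if (mode == "deterministic" && deterministic_amplitude <= 0)
    stop("'deterministic_amplitude' must be > 0")
  structure(list(mode = mode, amplitude = amplitude,
                 period = as.integer(period),
                 interior_scale = interior_scale,
                 deterministic_submode = deterministic_submode,
                 deterministic_amplitude = deterministic_amplitude),
            class = "protrusion_config")
}

#' Full simulation configuration
#'
#' Bundles cluster geometry, rheology, protrusion protocol, environmental
#' damping and run length into one reproducible specification: identical
#' configurations with identical seeds yield bit-identical trajectories.
#'
#' @param cluster a [cluster_config()].
#' @param rheology a [rheology_params()].
#' @param protrusion a [protrusion_config()].
#' @param eta_env environmental damping retention factor in `[0, 1]`: the
#'   fraction of each velocity retained per timestep.  0 is the fully
#'   viscous (Stokes) limit, 1 is no environmental damping.  Defaults to 0
#'   for KV and 0.75 for SLS (the SLS damper already dissipates internally).
#' @param n_steps total number of timesteps (>= 1).
#' @param seed integer RNG seed for this run.
#' @return an object of class `simulation_config`.
#' @examples
#' cfg <- simulation_config(n_steps = 200, seed = 1)
#' @export
simulation_config <- function(cluster = cluster_config(),
                              rheology = rheology_params(),
                              protrusion = protrusion_config(),
                              eta_env = NULL, n_steps = 2000, seed = 1) {
  stopifnot(inherits(cluster, "cluster_config"),
            inherits(rheology, "rheology_params"),
            inherits(protrusion, "protrusion_config"))
  if (is.null(eta_env))
    eta_env <- if (rheology$model == "KV") 0 else 0.75
  if (eta_env < 0 || eta_env > 1) stop("'eta_env' must lie in [0, 1]")
  if (n_steps < 1 || n_steps != round(n_steps))
    stop("'n_steps' must be a positive integer")
  if (protrusion$period >= n_steps)
    warning("protrusion period >= n_steps: no protrusion event will occur")
  structure(list(cluster = cluster, rheology = rheology,
                 protrusion = protrusion, eta_env = eta_env,
                 n_steps = as.integer(n_steps), dt = 1,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  cluster:    N = %d, gradient %g (K %g..%g), Kr %g, zone_max %g\n",
              x$cluster$n_cells, x$cluster$gradient_strength,
              x$cluster$k_min, x$cluster$k_max, x$cluster$kr,
              x$cluster$zone_max))
  cat(sprintf("  rheology:   %s", x$rheology$model))
  if (x$rheology$model == "SLS")
    cat(sprintf(" (k2 = %g, tau = %g)", x$rheology$k2, x$rheology$tau))
  else
    cat(sprintf(" (eta_i = %g)", x$rheology$eta_i))
  cat(sprintf("\n  protrusion: %s, amplitude %g, period %d\n",
              x$protrusion$mode, x$protrusion$amplitude, x$protrusion$period))
  cat(sprintf("  damping:    eta_env = %g; n_steps = %d; seed = %d\n",
              x$eta_env, x$n_steps, x$seed))
  invisible(x)
}

#' Read or write a simulation configuration as JSON
#'
#' The file mirrors [simulation_config()] field-for-field so that a run is
#' fully reproducible from the file plus its seed.  Files ending in `.yaml`
#' or `.yml` are read with the yaml package if it is installed.
#'
#' @param path file path.
#' @return `read_simulation_config()` returns a `simulation_config`;
#'   `write_simulation_config()` invisibly returns `path`.
#' @export
read_simulation_config <- function(path) {
  j <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  simulation_config(
    cluster = do.call(cluster_config, j$cluster),
    rheology = do.call(rheology_params, j$rheology),
    protrusion = do.call(protrusion_config, j$protrusion),
    eta_env = j$eta_env, n_steps = j$n_steps, seed = j$seed)
}

#' @param config a `simulation_config` to serialise.
#' @rdname read_simulation_config
#' @export
write_simulation_config <- function(config, path) {
  stopifnot(inherits(config, "simulation_config"))
  j <- list(
    cluster = config$cluster[c("n_cells", "gradient_strength", "k_min",
                               "kr", "zone_max", "bond_gradient")],
    rheology = config$rheology[c("model", "eta_i", "k2", "tau")],
    protrusion = config$protrusion[c("mode", "amplitude", "period",
                                     "interior_scale", "deterministic_submode",
                                     "deterministic_amplitude")],
    eta_env = config$eta_env, n_steps = config$n_steps, seed = config$seed)
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
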