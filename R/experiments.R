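#' Parameter sweep of the cluster migration speed
#'
#' Runs a seeded replicate ensemble at each value of one swept parameter
#' and estimates the mean centre-of-mass speed with [estimate_speed()].
#' Where the theory applies, the strong-gradient prediction
#' [predicted_speed()] (evaluated at `delta = 0`) is attached for overlay.
#'
#' @param parameter one of `"gradient_strength"`, `"n_cells"`,
#'   `"amplitude"`, `"period"`.
#' @param values ordered vector of parameter values to sweep.
#' @param config template [simulation_config()]; the swept field is
#'   overridden at each value.
#' @param n_replicates replicates per value (>= 2).
#' @param base_seed base RNG seed; value `i` uses
#'   `base_seed + (i - 1) * n_replicates` as its ensemble base seed, so no
#'   two replicates anywhere in the sweep share a seed.
#' @return data frame of class `cohesim_sweep` with one row per value:
#'   `parameter`, `value`, `mean_speed_mr_per_tau`, `stderr_mr_per_tau`,
#'   `n_replicates`, `theory_mr_per_tau`; per-replicate slopes (mr/tau) are
#'   in `attr(, "replicates")` (long format, for violin-style summaries).
#' @export
run_sweep <- function(parameter = c("gradient_strength", "n_cells",
                                    "amplitude", "period"),
                      values, config = simulation_config(),
                      n_replicates = 100, base_seed = 1) {
  parameter <- match.arg(parameter)
  stopifnot(length(values) >= 1, !is.unsorted(values), n_replicates >= 2)
  rows <- vector("list", length(values))
  reps <- vector("list", length(values))
  for (i in seq_along(values)) {
    cfg <- sweep_override(config, parameter, values[i])
    ens <- run_ensemble(cfg, n_replicates,
                        base_seed = base_seed + (i - 1L) * n_replicates)
    sp <- estimate_speed(ens)
    th <- predicted_speed(0, cfg$protrusion$amplitude,
                          cfg$cluster$n_cells, cfg$protrusion$period,
                          mr_per_tau = TRUE)
    rows[[i]] <- data.frame(parameter = parameter, value = values[i],
                            mean_speed_mr_per_tau = sp$mean_mr_per_tau,
                            stderr_mr_per_tau = sp$stderr_mr_per_tau,
                            n_replicates = sp$n_replicates,
                            theory_mr_per_tau = th)
    reps[[i]] <- data.frame(parameter = parameter, value = values[i],
                            replicate = seq_len(n_replicates),
                            speed_mr_per_tau = 1000 * sp$slopes)
  }
  out <- do.call(rbind, rows)
  attr(out, "replicates") <- do.call(rbind, reps)
  class(out) <- c("cohesim_sweep", "data.frame")
  out
}

sweep_override <- function(config, parameter, value) {
  cl <- config$cluster
  pr <- config$protrusion
  switch(parameter,
         gradient_strength = {
           config$cluster <- cluster_config(cl$n_cells, value, cl$k_min,
                                            cl$kr, cl$zone_max,
                                            cl$bond_gradient)
         },
         n_cells = {
           config$cluster <- cluster_config(value, cl$gradient_strength,
                                            cl$k_min, cl$kr, cl$zone_max,
                                            cl$bond_gradient)
         },
         amplitude = {
           config$protrusion$amplitude <- value
         },
         period = {
           config$protrusion$period <- as.integer(value)
         })
  config
}

#' Interior-migration scenarios
#'
#' Compares the migration speed of clusters in which only the outermost
#' cells protrude (`ends_only`), all cells protrude at full amplitude
#' (`all_cells`), and a hybrid in which interior cells protrude at a
#' reduced amplitude (`interior_scale * amplitude`).  All other parameters
#' are held identical across modes.  Persistent migration requires
#' suppression of interior wandering: the ends-only cluster migrates, the
#' all-cells cluster does not, and the hybrid rescues part of the speed.
#'
#' @param amplitudes protrusion amplitudes to test.
#' @param config template [simulation_config()] (SLS by default).
#' @param n_replicates replicates per (mode, amplitude) cell.
#' @param interior_scale amplitude multiplier for interior cells in the
#'   hybrid mode.
#' @param base_seed base RNG seed (offset per cell as in [run_sweep()]).
#' @return data frame with columns `mode`, `amplitude`,
#'   `mean_speed_mr_per_tau`, `stderr_mr_per_tau`, `n_replicates`.
#' @export
run_interior_scenarios <- function(amplitudes = c(0.5, 1),
                                   config = simulation_config(),
                                   n_replicates = 100,
                                   interior_scale = 0.25,
                                   base_seed = 1) {
  modes <- c("ends_only", "all_cells", "hybrid")
  rows <- list()
  cell <- 0L
  for (mode in modes) {
    for (a in amplitudes) {
      cfg <- config
      cfg$protrusion$mode <- mode
      cfg$protrusion$amplitude <- a
      cfg$protrusion$interior_scale <- interior_scale
      ens <- run_ensemble(cfg, n_replicates,
                          base_seed = base_seed + cell * n_replicates)
      sp <- estimate_speed(ens)
      rows[[length(rows) + 1L]] <-
        data.frame(mode = mode, amplitude = a,
                   mean_speed_mr_per_tau = sp$mean_mr_per_tau,
                   stderr_mr_per_tau = sp$stderr_mr_per_tau,
                   n_replicates = n_replicates)
      cell <- cell + 1L
    }
  }
  do.call(rbind, rows)
}

#' Deterministic forcing baseline
#'
#' Runs one deterministic-forcing simulation (fixed-length displacements of
#' the two outermost cells) and reports how far the centre of mass moves:
#' the maximum excursion `max |com(t) - com(0)|` and the asymptotic drift
#' rate.  The drift rate is the OLS slope, over the second half of the run,
#' of the centre of mass averaged over each full forcing cycle (one period
#' for the outward step, two periods for the alternating oscillations);
#' cycle averaging removes the bounded oscillation that the axial in-phase
#' protocol imposes on the centre of mass, isolating secular drift.  Under
#' deterministic forcing the cluster elongates to a periodic steady state
#' but its centre of mass does not drift, for any gradient strength,
#' amplitude or period.
#'
#' @param submode deterministic submode (see [protrusion_config()]).
#' @param gradient_strength cohesion gradient strength.
#' @param n_cells cluster size.
#' @param amplitude fixed displacement length.
#' @param period timesteps between events.
#' @param n_steps run length.
#' @param model rheology model, `"SLS"` or `"KV"`.
#' @return list with `submode`, `max_excursion`, `drift_rate` (radii per
#'   timestep) and the `trajectory`.
#' @export
run_deterministic_baseline <- function(submode = c("outward_step",
                                                   "inphase_oscillation",
                                                   "antiphase_oscillation"),
                                       gradient_strength = 10, n_cells = 5,
                                       amplitude = 1, period = 15,
                                       n_steps = 2000,
                                       model = c("SLS", "KV")) {
  submode <- match.arg(submode)
  model <- match.arg(model)
  cfg <- simulation_config(
    cluster = cluster_config(n_cells = n_cells,
                             gradient_strength = gradient_strength),
    rheology = rheology_params(model),
    protrusion = protrusion_config(mode = "deterministic",
                                   period = period,
                                   deterministic_submode = submode,
                                   deterministic_amplitude = amplitude),
    n_steps = n_steps, seed = 0L)
  traj <- run_simulation(cfg)
  com <- traj$com
  cycle <- if (submode == "outward_step") period else 2L * period
  n_cyc <- length(com) %/% cycle
  cyc_mean <- vapply(seq_len(n_cyc), function(c)
    mean(com[((c - 1L) * cycle + 1L):(c * cycle)]), numeric(1))
  half <- cyc_mean[(n_cyc %/% 2):n_cyc]
  tt <- (seq_along(half) - mean(seq_along(half))) * cycle
  drift <- sum(tt * (half - mean(half))) / sum(tt^2)
  list(submode = submode,
       max_excursion = max(abs(com - com[1L])),
       drift_rate = drift,
       trajectory = traj)
}
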