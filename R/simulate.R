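#' Run one seeded simulation
#'
#' Executes `n_steps` timesteps of the relax/protrude cycle: every
#' `period`-th step first applies the configured protrusion events and then
#' runs one step of relaxation dynamics; all other steps are pure
#' relaxation.  Relaxation integrates the coupled bond dynamics with
#' classical 4th-order Runge-Kutta at `dt = 1` and then applies
#' environmental damping (each velocity is multiplied by `eta_env`; for the
#' SLS model the per-bond stress memory is damped likewise).  Identical
#' configuration and seed give a bit-identical trajectory.
#'
#' @param config a [simulation_config()].
#' @return an object of class `cohesim_trajectory`: a list with
#'   `positions` (matrix, `n_steps + 1` rows including the initial state,
#'   one column per agent), `time` (0-based timesteps), `com`
#'   (centre-of-mass series), `events` (data frame: `timestep`, `agent`,
#'   `proposal`, `accepted`) and `config`.
#' @examples
#' traj <- run_simulation(simulation_config(n_steps = 100, seed = 42))
#' tail(traj$com, 3)
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cl <- config$cluster
  rh <- config$rheology
  n <- cl$n_cells
  n_steps <- config$n_steps
  model <- if (rh$model == "KV") 0L else 1L
  ka <- bond_stiffnesses(cl)

  set.seed(config$seed)
  x <- 2 * cl$r * (seq_len(n) - 1)
  v <- numeric(n)
  h <- numeric(n - 1L)

  P <- matrix(NA_real_, nrow = n_steps + 1L, ncol = n,
              dimnames = list(NULL, paste0("agent_", seq_len(n))))
  P[1L, ] <- x
  period <- config$protrusion$period
  event_times <- if (period < n_steps) seq.int(period, n_steps, by = period)
                 else integer(0)
  sel <- if (config$protrusion$mode != "deterministic")
    select_protruders(config$protrusion$mode, n, config$protrusion$amplitude,
                      config$protrusion$interior_scale) else NULL
  n_per_event <- if (is.null(sel)) 2L else nrow(sel)
  n_log <- length(event_times) * n_per_event
  log_time <- integer(n_log); log_agent <- integer(n_log)
  log_prop <- numeric(n_log); log_acc <- logical(n_log)

  t <- 0L
  ev_i <- 1L
  while (t < n_steps) {
    next_ev <- if (ev_i <= length(event_times)) event_times[ev_i]
               else n_steps + 1L
    if (t + 1L == next_ev) {
      ev <- apply_protrusion_event(x, v, h, config, ev_i, sel)
      x <- ev$x; v <- ev$v; h <- ev$h
      idx <- (ev_i - 1L) * n_per_event + seq_len(n_per_event)
      log_time[idx] <- next_ev
      log_agent[idx] <- ev$agents
      log_prop[idx] <- ev$proposals
      log_acc[idx] <- ev$accepted
      ev_i <- ev_i + 1L
      nrel <- 1L
    } else {
      nrel <- min(n_steps, next_ev - 1L) - t
    }
    res <- .relax_chain_cpp(x, v, h, nrel, model, ka, cl$kr, rh$eta_i,
                            rh$k2, rh$tau, cl$zone_max, cl$r, config$dt,
                            config$eta_env)
    if (res$bad_step > 0L)
      stop(sprintf("non-finite state at timestep %d: integration blew up %s",
                   t + res$bad_step,
                   "(reduce stiffness or increase damping)"))
    P[(t + 2L):(t + 1L + nrel), ] <- res$positions
    x <- res$x; v <- res$v; h <- res$h
    t <- t + nrel
  }

  events <- data.frame(timestep = log_time, agent = log_agent,
                       proposal = log_prop, accepted = log_acc)
  structure(list(positions = P,
                 time = 0:n_steps,
                 com = rowMeans(P),
                 events = events,
                 config = config),
            class = "cohesim_trajectory")
}

#' Advance a chain state by one timestep
#'
#' Single-step interface to the same integrator used by [run_simulation()],
#' useful for inspecting the relaxation dynamics.  In a `"protrude"` phase
#' the protrusion events are applied first and the relaxation step then
#' runs on the displaced state.
#'
#' @param state list with `x` (positions), `v` (velocities) and optionally
#'   `h` (per-bond SLS acceleration state, default zeros).
#' @param config a [simulation_config()].
#' @param phase `"relax"` (default) or `"protrude"`.
#' @param event_index event counter used by deterministic submodes.
#' @return updated state list (`x`, `v`, `h`), with an `events` element in a
#'   protrude phase.
#' @export
step_cluster <- function(state, config, phase = c("relax", "protrude"),
                         event_index = 1L) {
  phase <- match.arg(phase)
  stopifnot(inherits(config, "simulation_config"))
  cl <- config$cluster
  rh <- config$rheology
  x <- state$x
  v <- state$v
  h <- if (!is.null(state$h)) state$h else numeric(length(x) - 1L)
  if (any(diff(x) <= 0))
    stop("agents out of order: positions must be strictly increasing")
  ev <- NULL
  if (phase == "protrude") {
    pe <- apply_protrusion_event(x, v, h, config, event_index)
    x <- pe$x; v <- pe$v; h <- pe$h
    ev <- data.frame(agent = pe$agents, proposal = pe$proposals,
                     accepted = pe$accepted)
  }
  res <- .relax_chain_cpp(x, v, h, 1L,
                          if (rh$model == "KV") 0L else 1L,
                          bond_stiffnesses(cl), cl$kr, rh$eta_i, rh$k2,
                          rh$tau, cl$zone_max, cl$r, config$dt,
                          config$eta_env)
  if (res$bad_step > 0L)
    stop("non-finite state after step: integration blew up")
  out <- list(x = res$x, v = res$v, h = res$h)
  if (!is.null(ev)) out$events <- ev
  out
}

#' Run an ensemble of seeded replicates
#'
#' Replicate `k` uses seed `base_seed + k`, so the whole ensemble is
#' reproducible from `(config, base_seed)` alone.
#'
#' @param config a [simulation_config()] (its own `seed` is ignored).
#' @param n_replicates number of replicates (>= 2).
#' @param base_seed integer; replicate seeds are `base_seed + 1:n_replicates`.
#' @return an object of class `cohesim_ensemble`: list with `trajectories`
#'   (list of `cohesim_trajectory`), `com` (matrix, one column per
#'   replicate), `config`, `seeds`.
#' @export
run_ensemble <- function(config, n_replicates = 100, base_seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"), n_replicates >= 2)
  seeds <- base_seed + seq_len(n_replicates)
  trajectories <- vector("list", n_replicates)
  for (k in seq_len(n_replicates)) {
    cfg_k <- config
    cfg_k$seed <- seeds[k]
    trajectories[[k]] <- run_simulation(cfg_k)
  }
  com <- vapply(trajectories, `[[`, numeric(config$n_steps + 1L), "com")
  structure(list(trajectories = trajectories, com = com,
                 config = config, seeds = seeds),
            class = "cohesim_ensemble")
}

#' @export
print.cohesim_trajectory <- function(x, ...) {
  n <- ncol(x$positions)
  cat(sprintf("cohesim trajectory: %d agents, %d timesteps, %s model\n",
              n, length(x$time) - 1L, x$config$rheology$model))
  cat(sprintf("  COM drift: %.4f radii (%.2f mr/tau over the run)\n",
              x$com[length(x$com)] - x$com[1L],
              1000 * (x$com[length(x$com)] - x$com[1L]) /
                (length(x$time) - 1L)))
  cat(sprintf("  protrusion events: %d proposed, %d accepted\n",
              nrow(x$events), sum(x$events$accepted)))
  invisible(x)
}

#' @export
print.cohesim_ensemble <- function(x, ...) {
  cat(sprintf("cohesim ensemble: %d replicates of %d timesteps (%s model)\n",
              length(x$trajectories), x$config$n_steps,
              x$config$rheology$model))
  invisible(x)
}

#' @param y ignored.
#' @param ... passed to [graphics::matplot()].
#' @rdname run_simulation
#' @export
plot.cohesim_trajectory <- function(x, y, ...) {
  graphics::matplot(x$time, x$positions, type = "l", lty = 1,
                    xlab = "timestep", ylab = "position (radii)", ...)
  graphics::lines(x$time, x$com, lty = 2, lwd = 2)
  invisible(x)
}
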