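#' Draw stochastic protrusion proposals
#'
#' Proposed protrusion displacements are draws from a zero-mean Gaussian
#' whose standard deviation is the protrusion amplitude; the sign encodes
#' the direction along the gradient axis.  The mean is always zero, so
#' protrusions carry no intrinsic directional bias — any directed cluster
#' motion must come from the acceptance geometry, not the proposals.
#'
#' @param n number of draws.
#' @param sigma protrusion amplitude (Gaussian standard deviation), > 0.
#' @return numeric vector of signed displacements in radii.
#' @export
propose_stochastic <- function(n, sigma) {
  if (any(sigma <= 0)) stop("'sigma' must be > 0")
  rnorm(n, mean = 0, sd = sigma)
}

#' Select which agents protrude, and at what amplitude
#'
#' @param mode `"ends_only"`, `"all_cells"` or `"hybrid"`.
#' @param n_cells number of agents in the cluster.
#' @param sigma full protrusion amplitude.
#' @param interior_scale multiplier on `sigma` for interior agents in
#'   `"hybrid"` mode (e.g. 0.25 reduces interior wandering by 75%).
#' @return data frame with columns `agent` (ascending, trailing to leading)
#'   and `sigma`.
#' @examples
#' select_protruders("hybrid", 5, sigma = 1, interior_scale = 0.25)
#' @export
select_protruders <- function(mode = c("ends_only", "all_cells", "hybrid"),
                              n_cells, sigma = 1, interior_scale = 0.25) {
  mode <- match.arg(mode)
  agents <- switch(mode,
                   ends_only = c(1L, n_cells),
                   all_cells = seq_len(n_cells),
                   hybrid = seq_len(n_cells))
  s <- rep(sigma, length(agents))
  if (mode == "hybrid")
    s[agents != 1L & agents != n_cells] <- interior_scale * sigma
  data.frame(agent = agents, sigma = s)
}

#' Validate a protrusion proposal and apply it if admissible
#'
#' A proposal is rejected — the agent does not move at all — if the
#' displaced agent would come within one cell diameter (`2r`) of either
#' neighbour, i.e. an inward proposal longer than the accessible gap.  A
#' proposal that lands the agent exactly touching a neighbour is accepted
#' (the non-overlap invariant is `>=`, and the tie goes to accept).  The
#' outermost agents are unconstrained on their free side; there is no
#' simulation box.
#'
#' @param x agent positions (ascending).
#' @param agent index of the protruding agent.
#' @param proposal signed displacement in radii.
#' @param r agent radius.
#' @return list with `accepted` (logical) and `x` (positions after the
#'   event; unchanged if rejected).
#' @export
validate_and_apply <- function(x, agent, proposal, r = 1) {
  n <- length(x)
  xn <- x[agent] + proposal
  ok <- TRUE
  if (agent > 1L && xn - x[agent - 1L] < 2 * r) ok <- FALSE
  if (agent < n && x[agent + 1L] - xn < 2 * r) ok <- FALSE
  if (ok) x[agent] <- xn
  list(accepted = ok, x = x)
}

#' Apply one deterministic forcing event to the outermost agents
#'
#' The deterministic protocols displace the two outermost agents by a fixed
#' length: `"outward_step"` moves both ends away from the centre of mass at
#' every event; `"inphase_oscillation"` moves both ends in the same axial
#' direction, alternating direction between events; and
#' `"antiphase_oscillation"` moves the ends toward the centre on odd events
#' and away on even events.
#'
#' Unlike stochastic protrusions (which are rejected on contact),
#' deterministic displacements are imposed kinematically: a leg that drives
#' an agent into its neighbour produces transient compression that the
#' repulsive modulus resolves during the following relaxation.  This keeps
#' the forcing exactly symmetric — every event (outward, antiphase) or
#' every event cycle (in-phase) leaves the centre of mass unchanged — so
#' deterministic forcing produces no secular drift for any gradient,
#' amplitude or period.  Any contact constraint on the inward legs would
#' rectify the oscillation under a cohesion gradient and ratchet the
#' cluster forward, which deterministic forcing must not do.
#'
#' @param x agent positions (ascending).
#' @param submode one of `"outward_step"`, `"inphase_oscillation"`,
#'   `"antiphase_oscillation"`.
#' @param amplitude fixed displacement length in radii.
#' @param event_index 1-based index of the event (sets the oscillation
#'   phase).
#' @param r agent radius (unused; kept for interface symmetry with
#'   [validate_and_apply()]).
#' @return list with `x` (updated positions) and `log` (data frame: `agent`,
#'   `proposal`, `accepted`).
#' @export
apply_deterministic <- function(x, submode, amplitude, event_index, r = 1) {
  n <- length(x)
  sgn <- if (event_index %% 2L == 1L) 1 else -1
  d <- switch(submode,
              outward_step = c(-amplitude, amplitude),
              inphase_oscillation = c(sgn * amplitude, sgn * amplitude),
              antiphase_oscillation = c(sgn * amplitude, -sgn * amplitude),
              stop("unknown deterministic submode: ", submode))
  x[1L] <- x[1L] + d[1L]
  x[n] <- x[n] + d[2L]
  list(x = x, log = data.frame(agent = c(1L, n), proposal = d,
                               accepted = TRUE))
}

# One full protrusion event inside the simulation loop: draws proposals for
# all selected agents, validates trailing-to-leading against already-updated
# positions, zeroes the velocity (and adjacent SLS bond stress memory) of
# every displaced agent, and returns the event log as parallel vectors
# (agent, proposal, accepted).  `sel` is the precomputed protruder selection
# (data frame from select_protruders()); NULL for deterministic mode.
apply_protrusion_event <- function(x, v, h, config, event_index, sel = NULL) {
  pr <- config$protrusion
  n <- config$cluster$n_cells
  r <- config$cluster$r
  if (pr$mode == "deterministic") {
    res <- apply_deterministic(x, pr$deterministic_submode,
                               pr$deterministic_amplitude, event_index, r)
    # kinematic jump only: no velocity/stress reset, so the forcing stays
    # exactly momentum-neutral and deterministic runs cannot drift
    return(list(x = res$x, v = v, h = h, agents = res$log$agent,
                proposals = res$log$proposal, accepted = res$log$accepted))
  } else {
    if (is.null(sel))
      sel <- select_protruders(pr$mode, n, pr$amplitude, pr$interior_scale)
    agents <- sel$agent
    props <- rnorm(length(agents), 0, 1) * sel$sigma
    acc <- logical(length(agents))
    for (j in seq_along(agents)) {
      i <- agents[j]
      xn <- x[i] + props[j]
      ok <- (i == 1L || xn - x[i - 1L] >= 2 * r) &&
            (i == n  || x[i + 1L] - xn >= 2 * r)
      if (ok) x[i] <- xn
      acc[j] <- ok
    }
    moved <- agents[acc]
  }
  if (length(moved)) {
    v[moved] <- 0
    if (config$rheology$model == "SLS" && length(h)) {
      hb <- unique(c(moved - 1L, moved))
      hb <- hb[hb >= 1L & hb <= length(h)]
      h[hb] <- 0
    }
  }
  list(x = x, v = v, h = h, agents = agents, proposals = props,
       accepted = acc)
}
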