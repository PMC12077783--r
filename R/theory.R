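#' Mean protrusion length toward a constraining neighbour
#'
#' A protruding cell draws extension lengths from a half-Gaussian density
#' `f(x, sigma) = 2/(sigma * sqrt(2*pi)) * exp(-x^2 / (2*sigma^2))`, but a
#' protrusion cannot reach past a neighbour whose edge lies a distance
#' `delta` away; the region beyond is inaccessible.  The mean of the
#' accessible (truncated) distribution is
#' `sqrt(2/pi) * sigma * (1 - exp(-delta^2/(2*sigma^2))) / erf(delta/(sqrt(2)*sigma))`,
#' which tends to `delta / 2` for `delta << sigma` and to the half-normal
#' mean `sqrt(2/pi) * sigma` for `delta >> sigma`.
#'
#' @param delta accessible gap to the neighbour, in radii (>= 0, vectorised).
#' @param sigma protrusion amplitude (> 0).
#' @return truncated mean extension length in radii; 0 at `delta = 0` (the
#'   limit of a vanishing accessible region).
#' @seealso [net_displacement()], [predicted_speed()]
#' @export
truncated_mean <- function(delta, sigma) {
  if (any(sigma <= 0)) stop("'sigma' must be > 0")
  if (any(delta < 0)) stop("'delta' must be >= 0")
  u <- delta / sigma
  num <- -expm1(-u^2 / 2)              # 1 - exp(-u^2/2), accurately
  den <- erf(u / sqrt(2))
  out <- sqrt(2 / pi) * sigma * num / den
  out[u == 0] <- 0
  out
}

#' Net protrusion displacement of a half-constrained cell
#'
#' A cell with one free side and one side blocked by a neighbour at
#' accessible gap `delta` extends on average `sqrt(2/pi) * sigma` outward
#' but only [truncated_mean()]`(delta, sigma)` inward, so its net outward
#' displacement per protrusion is the difference:
#' `sqrt(2/pi) * sigma * (1 + (exp(-delta^2/(2*sigma^2)) - 1) / erf(delta/(sqrt(2)*sigma)))`.
#' It decays to 0 for `delta >> sigma` (an unconstrained cell drifts
#' nowhere) and saturates at `sqrt(2/pi) * sigma` for `delta << sigma` (a
#' fully blocked side rectifies every protrusion outward).
#'
#' @inheritParams truncated_mean
#' @return net outward displacement per protrusion event, in radii.
#' @export
net_displacement <- function(delta, sigma) {
  sqrt(2 / pi) * sigma - truncated_mean(delta, sigma)
}

#' Predicted cluster drift speed in the strong-gradient limit
#'
#' If the leading cell's net outward displacement is transmitted to a
#' cluster of `n_cells` equal masses once per protrusion period, the
#' centre of mass advances `net_displacement(delta, sigma) / n_cells` per
#' event, i.e. a drift speed of
#' `net_displacement(delta, sigma) / (n_cells * period)` radii per
#' timestep.  This is an upper envelope: it assumes the leading bond
#' re-closes completely between events (very strong leading cohesion) and a
#' fully detached trailing cell; finite-cohesion clusters move more slowly.
#'
#' @inheritParams truncated_mean
#' @param n_cells cluster size (>= 2).
#' @param period protrusion period in timesteps (>= 1).
#' @param mr_per_tau if `TRUE` return the speed in mr/tau (1e-3 radii per
#'   timestep) instead of radii per timestep.
#' @return predicted drift speed.
#' @examples
#' predicted_speed(delta = 0, sigma = 1, n_cells = 5, period = 15)
#' @export
predicted_speed <- function(delta, sigma, n_cells, period,
                            mr_per_tau = FALSE) {
  if (any(n_cells < 2)) stop("'n_cells' must be >= 2")
  if (any(period < 1)) stop("'period' must be >= 1")
  s <- net_displacement(delta, sigma) / (n_cells * period)
  if (mr_per_tau) 1000 * s else s
}

#' Table of analytic predictions
#'
#' Convenience wrapper producing the quantities of the closed-form theory
#' over a grid, suitable for overlaying on simulation sweeps.
#'
#' @inheritParams predicted_speed
#' @return data frame with columns `delta`, `sigma`, `n_cells`, `period`,
#'   `mean_to_neighbor`, `net_disp`, `cluster_disp`, `predicted_speed`
#'   (radii per timestep) and `predicted_speed_mr_per_tau`.
#' @export
prediction_table <- function(delta, sigma = 1, n_cells = 5, period = 15) {
  g <- expand.grid(delta = delta, sigma = sigma, n_cells = n_cells,
                   period = period)
  g$mean_to_neighbor <- truncated_mean(g$delta, g$sigma)
  g$net_disp <- net_displacement(g$delta, g$sigma)
  g$cluster_disp <- g$net_disp / g$n_cells
  g$predicted_speed <- g$cluster_disp / g$period
  g$predicted_speed_mr_per_tau <- 1000 * g$predicted_speed
  g
}

# error function via the normal CDF
erf <- function(z) 2 * pnorm(z * sqrt(2)) - 1
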