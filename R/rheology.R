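#' Kelvin-Voigt bond force
#'
#' Signed force exerted by one bond in gap coordinates.  For a bond with gap
#' `g = x_right - x_left - 2r` the active elastic modulus is the tensile
#' stiffness `ka` when `g > 0` (cells separated) and the repulsive stiffness
#' `kr` when `g < 0` (cells compressed); exactly one of the two is active at
#' any instant.  The returned value `F = K * gap + eta_i * gap_rate` is
#' applied as `+F` to the left (trailing) member and `-F` to the right
#' (leading) member, so separated cells are pulled together, overlapping
#' cells are pushed apart, and paired contributions always cancel.  A bond
#' whose gap exceeds `zone_max` is detached and exerts no force.
#'
#' @param gap bond gap `x_right - x_left - 2r`, in radii (vectorised).
#' @param gap_rate time derivative of the gap.
#' @param ka tensile stiffness of the bond.
#' @param kr compressive stiffness.
#' @param eta_i bond viscosity.
#' @param zone_max detachment gap; `Inf` disables detachment.
#' @return signed force on the trailing member (the leading member receives
#'   the negative).
#' @examples
#' kv_bond_force(gap = 1, gap_rate = 0, ka = 10, kr = 1, eta_i = 0) # +10
#' @export
kv_bond_force <- function(gap, gap_rate, ka, kr, eta_i = 0, zone_max = Inf) {
  k1 <- ifelse(gap > 0, ka, kr)
  f <- k1 * gap + eta_i * gap_rate
  ifelse(gap > zone_max, 0, f)
}

#' Standard Linear Solid bond jerk
#'
#' Third time-derivative of the bond gap under the SLS constitutive law,
#' written so that the just-touching, zero-gap state is attracting:
#' `d3(gap)/dt3 = -(K1/tau) * gap - (K1 + k2) * gap_rate - gap_accel / tau`,
#' with `K1` the active modulus (`ka` under tension, `kr` under
#' compression).  The integrated `gap_accel` of a bond, halved and signed,
#' is the force contribution applied to its two member agents.
#'
#' @inheritParams kv_bond_force
#' @param gap_accel second derivative of the gap (the bond's dynamic state).
#' @param k2 series spring modulus.
#' @param tau relaxation time `eta / k2`, > 0.
#' @return the jerk `d3(gap)/dt3` (vectorised).  For a detached bond
#'   (`gap > zone_max`) the stress memory relaxes as `-gap_accel / tau`.
#' @export
sls_jerk <- function(gap, gap_rate, gap_accel, ka, kr, k2, tau,
                     zone_max = Inf) {
  if (any(tau <= 0)) stop("'tau' must be > 0")
  k1 <- ifelse(gap > 0, ka, kr)
  ifelse(gap > zone_max,
         -gap_accel / tau,
         -(k1 / tau) * gap - (k1 + k2) * gap_rate - gap_accel / tau)
}

#' Per-agent accelerations of a chain state
#'
#' Assembles the net acceleration on every agent from its (at most two)
#' bonds, using the configured rheology: Kelvin-Voigt forces from the
#' instantaneous gaps and gap rates, or Standard Linear Solid forces from
#' the per-bond acceleration state `h` (each bond contributes `-h/2` to its
#' trailing and `+h/2` to its leading member).  This is the force kernel
#' evaluated inside every Runge-Kutta stage of [run_simulation()].
#'
#' @param x agent positions (length N, increasing).
#' @param v agent velocities.
#' @param cluster a [cluster_config()] for N agents.
#' @param rheology a [rheology_params()].
#' @param h per-bond gap-acceleration state (length N - 1; SLS only,
#'   defaults to all zero).
#' @return a list with `a` (per-agent accelerations, length N) and `dh`
#'   (per-bond jerk, length N - 1; zero for KV).
#' @examples
#' cl <- cluster_config(n_cells = 2, k_min = 10, gradient_strength = 1)
#' chain_accelerations(c(0, 3), c(0, 0), cl, rheology_params("KV", eta_i = 0))
#' @export
chain_accelerations <- function(x, v, cluster, rheology,
                                h = numeric(length(x) - 1L)) {
  stopifnot(inherits(cluster, "cluster_config"),
            inherits(rheology, "rheology_params"),
            length(x) == cluster$n_cells, length(v) == length(x),
            length(h) == length(x) - 1L)
  .chain_accel_cpp(x, v, h,
                   model = if (rheology$model == "KV") 0L else 1L,
                   ka = bond_stiffnesses(cluster),
                   kr = cluster$kr, eta_i = rheology$eta_i,
                   k2 = rheology$k2, tau = rheology$tau,
                   zone_max = cluster$zone_max, r = cluster$r)
}
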