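#' Initialize a cluster of agents and its bonds
#'
#' Places `n_cells` agents on the gradient axis with edges just touching
#' (positions `0, 2r, 4r, ...`), at rest, and derives the `n_cells - 1` bond
#' tensile stiffnesses from the cohesion gradient.  With
#' `bond_gradient = "midpoint"` the bond stiffnesses are linearly spaced from
#' `k_min` (bond 1, between agents 1 and 2) to `k_max` (the leading bond);
#' with `"leading"` each bond inherits the per-agent stiffness of its leading
#' member, the agents themselves being linearly graded from `k_min` to
#' `k_max`.
#'
#' @param config a [cluster_config()].
#' @return a list with components `agents` (data frame: `index`, `x`, `v`,
#'   `a`, `r`, `m`) and `bonds` (data frame: `bond`, `ka`, `kr`).
#' @examples
#' initialize_cluster(cluster_config(n_cells = 5, gradient_strength = 10,
#'                                   k_min = 1))$bonds
#' @export
initialize_cluster <- function(config) {
  stopifnot(inherits(config, "cluster_config"))
  n <- config$n_cells
  agents <- data.frame(index = seq_len(n),
                       x = 2 * config$r * (seq_len(n) - 1),
                       v = 0, a = 0, r = config$r, m = config$m)
  bonds <- data.frame(bond = seq_len(n - 1L),
                      ka = bond_stiffnesses(config),
                      kr = config$kr)
  list(agents = agents, bonds = bonds)
}

# Per-bond tensile stiffnesses implied by a cluster configuration.
bond_stiffnesses <- function(config) {
  n <- config$n_cells
  if (config$bond_gradient == "midpoint") {
    if (n == 2L) mean(c(config$k_min, config$k_max))
    else seq(config$k_min, config$k_max, length.out = n - 1L)
  } else {
    # per-agent stiffness, bond takes its leading member's value
    ka_agent <- seq(config$k_min, config$k_max, length.out = n)
    ka_agent[-1L]
  }
}
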