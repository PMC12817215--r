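# Monte-Carlo realization of the individual decision process. This is the
# ground-truth oracle for the analytic probabilities: an agent draws a
# benefit threshold (the maximum of m_origin draws from the origin-class
# distribution), then visits destinations in order of increasing distance
# and settles at the first whose opportunity (maximum of n_j draws from the
# destination-class distribution) exceeds the threshold.

#' Sample the maximum of n iid draws from a compressed uniform distribution
#'
#' Exact inverse-transform sampling of max of `n_draws` iid Uniform(0, 1/delta)
#' variables: `z = (1/delta) * U^(1/n_draws)`. O(1) per sample even for
#' populations of 1e6, and consumes exactly one uniform per sample.
#'
#' @param n_draws number of underlying draws (>= 1), e.g. a population.
#' @param delta compression factor of the class (> 0); support is \[0, 1/delta\].
#' @param n number of samples to return.
#' @return Numeric vector of `n` samples.
#' @export
sample_max <- function(n_draws, delta = 1, n = 1) {
  if (n_draws < 1) stop("n_draws must be >= 1")
  if (delta <= 0) stop("delta must be > 0")
  (1 / delta) * stats::runif(n)^(1 / n_draws)
}

# visit shells for an origin: groups of destinations at identical distance,
# in ascending distance, members in ascending location-id order. Within a
# shell no member blocks another — the analytic strict-circle convention —
# so acceptance is decided jointly for the whole shell.
visit_shells <- function(origin, distances, ids) {
  d <- distances[origin, ]
  ord <- order(d, ids)
  ord <- ord[ord != origin]
  split(ord, match(d[ord], unique(d[ord])))
}

#' Simulate a single agent's move decision
#'
#' Draws the agent's benefit threshold, then one opportunity per destination,
#' shell by shell (nearest first); the chosen destination is drawn uniformly
#' among the qualifying members of the nearest shell containing one whose
#' opportunity exceeds the threshold, or none. For generic (tie-free)
#' geometries this is exactly "the closest location whose opportunity is
#' greater than the benefit threshold".
#'
#' @param origin origin index.
#' @param locations location table.
#' @param distances distance matrix (computed if `NULL`).
#' @param scheme per-class deltas (all 1 if `NULL`).
#' @return List with `threshold`, `destination` (index or `NA`) and
#'   `visited` (the flattened visit order).
#' @export
simulate_agent <- function(origin, locations, distances = NULL, scheme = NULL) {
  locations <- validate_locations(locations)
  if (is.null(distances)) distances <- compute_distances(locations)
  C <- max(locations$class)
  if (is.null(scheme)) scheme <- rep(1, C)
  scheme <- inequality_scheme(scheme)
  d_loc <- scheme[locations$class]
  z <- sample_max(locations$population[origin], d_loc[origin])
  shells <- visit_shells(origin, distances, locations$id)
  dest <- NA_integer_
  for (shell in shells) {
    opp <- vapply(shell, function(j)
      sample_max(locations$population[j], d_loc[j]), numeric(1))
    ok <- shell[opp > z]
    if (length(ok)) {
      dest <- if (length(ok) == 1L) ok else ok[sample.int(length(ok), 1)]
      break
    }
  }
  list(threshold = z, destination = dest, visited = unlist(shells))
}

#' Empirical stopping probabilities from many simulated agents
#'
#' Runs `n_agents` independent agents from one origin and tabulates the
#' destination frequencies among agents that moved (agents that found no
#' acceptable destination are excluded, mirroring the analytic row
#' normalization, and their fraction is reported as a diagnostic).
#'
#' The random stream is consumed in a documented order: first all `n_agents`
#' thresholds; then, shell by shell (ascending distance), the opportunities
#' of each shell member in ascending-id order (all agents per member),
#' followed — only for shells with several members — by one tie-breaking
#' uniform per agent. Distributionally identical to per-agent interleaving
#' since all draws are independent.
#'
#' @param origin origin index.
#' @param n_agents number of agents (>= 1).
#' @param locations location table.
#' @param distances distance matrix (computed if `NULL`).
#' @param scheme per-class deltas (all 1 if `NULL`).
#' @param seed optional seed for reproducibility.
#' @return List with `prob` (length-L empirical probabilities, origin 0),
#'   `se` (binomial standard errors), `n_moved`, and `prop_no_destination`.
#' @export
estimate_probabilities <- function(origin, n_agents, locations,
                                   distances = NULL, scheme = NULL, seed = NULL) {
  if (n_agents < 1) stop("n_agents must be >= 1")
  locations <- validate_locations(locations)
  if (is.null(distances)) distances <- compute_distances(locations)
  C <- max(locations$class)
  if (is.null(scheme)) scheme <- rep(1, C)
  scheme <- inequality_scheme(scheme)
  if (!is.null(seed)) set.seed(seed)
  d_loc <- scheme[locations$class]
  pop <- locations$population
  L <- nrow(locations)
  z <- sample_max(pop[origin], d_loc[origin], n = n_agents)
  shells <- visit_shells(origin, distances, locations$id)
  chosen <- integer(n_agents)
  for (shell in shells) {
    if (length(shell) == 1L) {
      opp <- sample_max(pop[shell], d_loc[shell], n = n_agents)
      hit <- chosen == 0L & opp > z
      chosen[hit] <- shell
    } else {
      ok <- matrix(FALSE, n_agents, length(shell))
      for (t in seq_along(shell))
        ok[, t] <- sample_max(pop[shell[t]], d_loc[shell[t]], n = n_agents) > z
      u <- stats::runif(n_agents)  # tie-break among qualifying members
      nq <- rowSums(ok)
      hit <- which(chosen == 0L & nq > 0L)
      for (a in hit) {
        q <- shell[ok[a, ]]
        chosen[a] <- q[ceiling(u[a] * length(q))]
      }
    }
    if (all(chosen > 0L)) break
  }
  moved <- chosen > 0L
  n_moved <- sum(moved)
  if (n_moved == 0) stop("no agent found an acceptable destination; increase n_agents")
  counts <- tabulate(chosen[moved], nbins = L)
  p <- counts / n_moved
  list(prob = p, se = sqrt(p * (1 - p) / n_moved),
       n_moved = n_moved, prop_no_destination = 1 - n_moved / n_agents)
}
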