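# Synthetic urban systems with known ground truth. The generator emulates
# the study conditions: a country-scale system of L locations with
# heavy-tailed (Zipf rank-size) populations scattered uniformly in a planar
# box, a penalized top fraction of locations, and an observable covariate
# that tracks the true class up to configurable noise.

#' Generate a synthetic urban system
#'
#' Populations follow a Zipf rank-size law (`pop_max / rank^exponent`,
#' largest location `pop_max`) or a lognormal law; coordinates are uniform in
#' a `box_km` rectangle. A fraction of locations is drawn uniformly into the
#' penalized class 2; the `covariate` column equals the true class indicator
#' with a fraction `covariate_noise` of entries flipped, plus Uniform(0, 0.5)
#' jitter so that percentile-based assignment is well defined. With zero
#' noise, [assign_binary_top()] on the covariate recovers the true penalized
#' set exactly.
#'
#' @param L number of locations (>= 2).
#' @param pop_law `"zipf"` or `"lognormal"`.
#' @param pop_max largest Zipf population (default 1e5, county-like scale).
#' @param zipf_exponent Zipf exponent (default 1).
#' @param meanlog,sdlog lognormal parameters.
#' @param box_km width/height of the planar box (default 500 x 500 km).
#' @param penalized_fraction fraction of locations in class 2 (default 0.15).
#' @param covariate_noise fraction of class indicators flipped in the
#'   observable covariate (default 0 = perfect covariate).
#' @param seed RNG seed (generation is a pure function of it).
#' @return Location table with columns `id`, `x_km`, `y_km`, `population`,
#'   `class` (the TRUE classes) and `covariate`.
#' @export
generate_system <- function(L = 30, pop_law = c("zipf", "lognormal"),
                            pop_max = 1e5, zipf_exponent = 1,
                            meanlog = 9, sdlog = 1.2,
                            box_km = c(500, 500),
                            penalized_fraction = 0.15,
                            covariate_noise = 0, seed = NULL) {
  pop_law <- match.arg(pop_law)
  if (L < 2) stop("L must be >= 2")
  if (any(box_km <= 0)) stop("degenerate box: zero area")
  if (!(penalized_fraction > 0 && penalized_fraction < 1))
    stop("penalized_fraction must lie in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  pop <- switch(pop_law,
    zipf = {
      ranks <- sample(L)   # shuffle the rank-size law across locations
      pmax(1, round(pop_max / ranks^zipf_exponent))
    },
    lognormal = pmax(1, round(stats::rlnorm(L, meanlog, sdlog))))
  x <- stats::runif(L, 0, box_km[1])
  y <- stats::runif(L, 0, box_km[2])
  k <- ceiling(penalized_fraction * L)
  pen <- sample(L, k)
  cl <- rep(1L, L); cl[pen] <- 2L
  ind <- as.numeric(cl == 2L)
  if (covariate_noise > 0) {
    flip <- sample(L, round(covariate_noise * L))
    ind[flip] <- 1 - ind[flip]
  }
  covariate <- ind + stats::runif(L, 0, 0.5)
  data.frame(id = sprintf("loc%03d", seq_len(L)), x_km = x, y_km = y,
             population = pop, class = cl, covariate = covariate)
}

#' Generate ground-truth OD fluxes from a synthetic system
#'
#' Builds the chosen model variant on the system's TRUE classes and either
#' returns the rounded expected fluxes or samples each origin's movers
#' multinomially across destinations. Outflow totals are
#' `T_i = round(mobile_fraction * m_i)`.
#'
#' @param system a [generate_system()] table (or any location table).
#' @param model model variant for the ground truth.
#' @param delta true class-2 delta (scalar) or full per-class scheme.
#' @param mobile_fraction fraction of each population that moves
#'   (default 0.0785, the commuting-calibration value).
#' @param sampling `"multinomial"` (integer draws, row sums exactly T_i) or
#'   `"expected"` (rounded expectations).
#' @param seed RNG seed for the multinomial draws.
#' @return List with `observed` (L x L integer matrix), `outflow` (T_i) and
#'   `P` (the generating probability matrix).
#' @export
generate_od <- function(system, model = c("two_class", "standard", "linearized",
                                          "integral"),
                        delta = 1, mobile_fraction = 0.0785,
                        sampling = c("multinomial", "expected"), seed = NULL) {
  model <- match.arg(model)
  sampling <- match.arg(sampling)
  system <- validate_locations(system)
  C <- max(system$class)
  scheme <- if (length(delta) == C) delta else c(1, rep(delta, C - 1L))
  if (model == "standard") scheme <- rep(1, C)
  P <- build_probability_matrix(system, inequality_scheme(scheme), model)
  T_i <- round_half_away(mobile_fraction * system$population)
  if (!is.null(seed)) set.seed(seed)
  obs <- if (sampling == "expected") {
    round_half_away(P * T_i)
  } else {
    L <- nrow(P)
    out <- matrix(0, L, L, dimnames = dimnames(P))
    for (i in seq_len(L)) {
      if (T_i[i] == 0) next
      if (sum(P[i, ]) == 0) stop("zero-probability row ", i, " with T_i > 0")
      out[i, ] <- stats::rmultinom(1, T_i[i], P[i, ])
    }
    out
  }
  list(observed = obs, outflow = T_i, P = P)
}

#' Two-city fixture: crossover of migration direction with inequality
#'
#' The minimal system exhibiting the model's qualitative departure from the
#' standard radiation model: city 1 (population `n1`) is unaffected, city 2
#' (population `n2 >> n1`) is penalized with factor `delta`. Returns the
#' UNNORMALIZED modified probabilities in both directions; at `delta = 1`
#' these are `n2/(n1+n2)` and `n1/(n1+n2)`, so the larger city attracts
#' more — while for delta beyond the crossover the net propensity reverses.
#'
#' @param n1,n2 city populations.
#' @param delta penalization of city 2.
#' @return List with `locations`, `p12`, `p21` (unnormalized).
#' @export
two_city_fixture <- function(n1 = 1e4, n2 = 1e6, delta = 1) {
  locs <- data.frame(id = c("city1", "city2"), x_km = c(0, 100), y_km = 0,
                     population = c(n1, n2), class = c(1L, 2L))
  list(locations = locs,
       p12 = modified_probability_two_class(n1, n2, 0, 0, 1, 2, delta),
       p21 = modified_probability_two_class(n2, n1, 0, 0, 2, 1, delta))
}

#' Crossover delta of the two-city system
#'
#' Finds, by root bisection, the penalization `delta*` at which the
#' unnormalized probabilities cross (`p21 = p12`); beyond it the smaller,
#' unpenalized city attracts more movers than the penalized metropolis — a
#' regime unattainable in the standard radiation model.
#'
#' @param n1,n2 city populations.
#' @param upper upper bracket for the search (expanded automatically).
#' @return `delta*` (scalar, > 1).
#' @export
crossover_delta <- function(n1 = 1e4, n2 = 1e6, upper = NULL) {
  g <- function(d) {
    f <- two_city_fixture(n1, n2, d)
    f$p21 - f$p12
  }
  if (is.null(upper)) upper <- 1 + 20 / min(n1, n2)
  while (g(upper) <= 0) upper <- 1 + (upper - 1) * 4
  stats::uniroot(g, c(1 + 1e-12, upper), tol = 1e-13)$root
}
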