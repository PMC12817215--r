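# Vectorized matrix builders. All take the precomputed pieces so that the
# permutation-null machinery can rebuild the modified matrix thousands of
# times without re-deriving distances or the standard-model parts.

# standard radiation matrix (unnormalized, zero diagonal)
standard_matrix <- function(pop, S) {
  L <- length(pop)
  M <- matrix(pop, L, L)
  N <- matrix(pop, L, L, byrow = TRUE)
  P <- M * N / ((M + S) * (M + N + S))
  diag(P) <- 0
  P
}

# closed-form two-class matrix; classes is the per-location vector, delta the
# class-2 factor, S the total and S2 the class-2 intervening matrix
two_class_matrix <- function(pop, classes, delta, S, S2) {
  if (delta < 1) {  # scale equivalence: relabel so class 1 is the wider class
    classes <- 3L - classes
    S2 <- S - S2
    delta <- 1 / delta
  }
  L <- length(pop)
  M <- matrix(pop, L, L)
  N <- matrix(pop, L, L, byrow = TRUE)
  S1 <- S - S2
  pR <- M * N / ((M + S) * (M + N + S))
  ld <- log(delta)
  E1 <- exp(-S1 * ld)
  P22 <- pR * E1
  P12 <- pR * exp(-(M + S1) * ld)
  P21 <- pR * E1 * (1 + (M + S) / N * (1 - exp(-N * ld)))
  P11 <- pR * (S2 * (M + S) * exp(-(M + N + S1) * ld) / (N * (M + N + S1)) +
               (M + S) * (M + N + S) / ((M + S1) * (M + N + S1)) -
               S2 * (M + N + S) * exp(-(M + S1) * ld) / (N * (M + S1)))
  oi <- classes == 2L
  Mi <- matrix(oi, L, L)
  Mj <- matrix(oi, L, L, byrow = TRUE)
  P <- ifelse(Mi, ifelse(Mj, P22, P21), ifelse(Mj, P12, P11))
  diag(P) <- 0
  P
}

# linearized multi-class matrix; delta_loc is the per-location delta vector,
# W the (delta - 1)-weighted intervening matrix
linearized_matrix <- function(pop, delta_loc, S, W) {
  L <- length(pop)
  M <- matrix(pop, L, L)
  N <- matrix(pop, L, L, byrow = TRUE)
  pR <- M * N / ((M + S) * (M + N + S))
  Di <- matrix(delta_loc - 1, L, L)
  Dj <- matrix(delta_loc - 1, L, L, byrow = TRUE)
  P <- pR * (1 + M * Di - (M + S) * Dj + W)
  diag(P) <- 0
  nneg <- sum(P < 0)
  P[P < 0] <- 0
  attr(P, "clipped") <- nneg
  P
}

row_normalize <- function(P) {
  rs <- rowSums(P)
  pos <- rs > 0
  P[pos, ] <- P[pos, , drop = FALSE] / rs[pos]
  attr(P, "zero_rows") <- sum(!pos)
  P
}

#' Build a flux-probability matrix
#'
#' Assembles the L x L matrix of stopping probabilities p_ij for one of the
#' model variants, sets the diagonal to zero (movers leave their location)
#' and normalizes every row with positive mass to sum to one.
#'
#' @param locations location table (with `class` column for modified variants).
#' @param scheme numeric vector of per-class deltas (class 1 must have
#'   delta 1); `NULL` means all deltas 1.
#' @param model `"standard"`, `"two_class"` (closed forms, exactly 2 classes),
#'   `"linearized"` (first-order, any C) or `"integral"` (exact engine, any C).
#' @param distances,intervening optional precomputed pieces
#'   ([compute_distances()], [intervening_population()]).
#' @param normalize row-normalize (default TRUE).
#' @return Matrix of probabilities with attributes `model`, `clipped` (count
#'   of negative linearized entries clipped at 0) and `zero_rows`.
#' @export
build_probability_matrix <- function(locations, scheme = NULL,
                                     model = c("standard", "two_class",
                                               "linearized", "integral"),
                                     distances = NULL, intervening = NULL,
                                     normalize = TRUE) {
  model <- match.arg(model)
  locations <- validate_locations(locations)
  C <- max(locations$class)
  if (is.null(scheme)) scheme <- rep(1, C)
  scheme <- inequality_scheme(scheme)
  if (length(scheme) != C)
    stop("scheme must provide a delta for each of the ", C, " classes present")
  if (model == "two_class" && C != 2L)
    stop("two_class model requires exactly 2 classes (got ", C, ")")
  if (is.null(distances)) distances <- compute_distances(locations)
  if (is.null(intervening)) intervening <- intervening_population(locations, distances)
  pop <- locations$population
  S <- intervening$total
  clipped <- 0L
  P <- switch(model,
    standard = standard_matrix(pop, S),
    two_class = two_class_matrix(pop, locations$class, scheme[2], S,
                                 intervening$by_class[[2]]),
    linearized = {
      neigh <- neighbor_structure(distances)
      W <- intervening_weighted(neigh, pop * (scheme[locations$class] - 1))
      Pm <- linearized_matrix(pop, scheme[locations$class], S, W)
      clipped <- attr(Pm, "clipped")
      if (clipped > 0)
        warning(clipped, " negative linearized probabilities clipped at 0")
      Pm
    },
    integral = {
      L <- nrow(locations)
      Pm <- matrix(0, L, L)
      for (i in seq_len(L)) for (j in seq_len(L)) {
        if (i == j) next
        sk <- vapply(intervening$by_class, function(s) s[i, j], numeric(1))
        Pm[i, j] <- general_probability_integral(
          pop[i], pop[j], sk, locations$class[i], locations$class[j], scheme)
      }
      Pm
    })
  if (normalize) P <- row_normalize(P)
  dimnames(P) <- list(locations$id, locations$id)
  attr(P, "model") <- model
  attr(P, "clipped") <- clipped
  P
}

# nearest integer, ties rounded half away from zero
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Predicted origin-destination fluxes
#'
#' Multiplies each row of the (normalized) probability matrix by the known
#' outflow total of its origin; optionally rounds to the nearest integer
#' (ties half away from zero).
#'
#' @param P flux-probability matrix (rows normalized).
#' @param outflow vector T_i of movers leaving each location (>= 0).
#' @param round_to_int round the fluxes (default TRUE).
#' @return L x L flux matrix with attribute `outflow`.
#' @export
predict_fluxes <- function(P, outflow, round_to_int = TRUE) {
  if (length(outflow) != nrow(P)) stop("outflow length must match nrow(P)")
  if (any(outflow < 0)) stop("outflow totals must be >= 0")
  T_ij <- P * outflow
  if (round_to_int) T_ij <- round_half_away(T_ij)
  attr(T_ij, "outflow") <- outflow
  T_ij
}

#' Mobile fraction from observed outflows
#'
#' Slope of the no-intercept least-squares fit of observed outflow totals
#' (off-diagonal row sums of the observed OD matrix) against populations:
#' `sum(m T) / sum(m^2)`. This is how a commuting fraction such as
#' T_i = 0.0785 m_i is calibrated from data.
#'
#' @param observed observed OD matrix (or a vector of outflow totals).
#' @param locations location table supplying the populations.
#' @return The fitted fraction (scalar).
#' @export
estimate_mobile_fraction <- function(observed, locations) {
  pop <- if (is.data.frame(locations)) locations$population else locations
  if (is.null(pop) || any(pop < 0)) stop("populations missing or negative")
  outflow <- if (is.matrix(observed)) {
    O <- observed; diag(O) <- 0; rowSums(O)
  } else observed
  if (length(outflow) != length(pop)) stop("dimension mismatch")
  if (all(pop == 0)) stop("all populations are zero")
  sum(pop * outflow) / sum(pop^2)
}
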