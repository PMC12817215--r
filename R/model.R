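#' Fit an (inequality-aware) radiation model to an urban system
#'
#' Builds the full flux-probability structure for a system of locations:
#' distances, intervening populations (total and per class) and the
#' row-normalized stopping-probability matrix for the chosen model variant.
#' The returned object supports `print`, `summary`, `coef`, `predict`
#' (expected fluxes given outflow totals), `simulate` (multinomially sampled
#' integer fluxes), `residuals` (prediction minus observation) and `plot`.
#'
#' @param locations location table: columns `id`, `population`, coordinates
#'   (`lat`/`lon` or `x_km`/`y_km`), optional `class` (1..C) and covariates.
#' @param scheme per-class deltas (see [inequality_scheme()]); `NULL` means
#'   no inequality (all deltas 1).
#' @param model `"standard"`, `"two_class"`, `"linearized"` or `"integral"`.
#' @param metric distance metric, `"auto"` to infer from coordinate columns.
#' @return Object of class `"radiation"`.
#' @examples
#' locs <- data.frame(id = c("a", "b", "c"), x_km = c(0, 50, 120),
#'                    y_km = 0, population = c(1000, 500, 2000),
#'                    class = c(1L, 2L, 1L))
#' fit <- radiation(locs, scheme = c(1, 1.5), model = "two_class")
#' predict(fit, fraction = 0.1)
#' @export
radiation <- function(locations, scheme = NULL,
                      model = c("standard", "two_class", "linearized", "integral"),
                      metric = c("auto", "haversine", "euclidean")) {
  model <- match.arg(model)
  locations <- validate_locations(locations)
  distances <- compute_distances(locations, match.arg(metric))
  intervening <- intervening_population(locations, distances)
  C <- max(locations$class)
  if (is.null(scheme)) scheme <- rep(1, C)
  scheme <- inequality_scheme(scheme)
  P <- build_probability_matrix(locations, scheme, model,
                                distances = distances, intervening = intervening)
  structure(list(call = match.call(), locations = locations, scheme = scheme,
                 model = model, metric = attr(distances, "metric"),
                 distances = distances, intervening = intervening, P = P,
                 clipped = attr(P, "clipped")),
            class = "radiation")
}

#' @export
print.radiation <- function(x, ...) {
  cat("Radiation mobility model (", x$model, " variant)\n", sep = "")
  cat("  locations:", nrow(x$locations),
      "| classes:", max(x$locations$class),
      "| metric:", x$metric, "\n")
  cat("  deltas:", paste(signif(x$scheme, 6), collapse = ", "), "\n")
  if (!is.null(x$clipped) && x$clipped > 0)
    cat("  (", x$clipped, " negative linearized entries clipped at 0)\n", sep = "")
  invisible(x)
}

#' @export
summary.radiation <- function(object, ...) {
  cls <- table(object$locations$class)
  rs <- rowSums(object$P)
  out <- list(model = object$model, L = nrow(object$locations),
              class_sizes = cls, scheme = object$scheme,
              pop_range = range(object$locations$population),
              distance_range = range(object$distances[upper.tri(object$distances)]),
              zero_rows = sum(rs == 0), clipped = object$clipped)
  class(out) <- "summary.radiation"
  out
}

#' @export
print.summary.radiation <- function(x, ...) {
  cat("Radiation model summary —", x$model, "variant\n")
  cat("  L =", x$L, "locations; populations in [",
      paste(format(x$pop_range, big.mark = ","), collapse = ", "), "]\n")
  cat("  pairwise distances (km):",
      paste(signif(x$distance_range, 4), collapse = " – "), "\n")
  cat("  class sizes:", paste(names(x$class_sizes), unname(x$class_sizes),
                              sep = ":", collapse = "  "), "\n")
  cat("  per-class deltas:", paste(signif(x$scheme, 6), collapse = ", "), "\n")
  if (x$zero_rows) cat("  rows with zero mass:", x$zero_rows, "\n")
  invisible(x)
}

#' @export
coef.radiation <- function(object, ...) {
  d <- object$scheme
  names(d) <- paste0("delta_", seq_along(d))
  d
}

# resolve outflow totals: explicit vector > fraction of population >
# regression against an observed OD matrix
resolve_outflow <- function(object, outflow, fraction, observed) {
  pop <- object$locations$population
  if (!is.null(outflow)) return(outflow)
  if (!is.null(fraction)) return(round_half_away(fraction * pop))
  if (!is.null(observed)) {
    f <- estimate_mobile_fraction(observed, object$locations)
    return(round_half_away(f * pop))
  }
  stop("provide `outflow`, `fraction`, or `observed` to fix the totals T_i")
}

#' Predict origin-destination fluxes from a radiation model
#'
#' @param object a [radiation()] fit.
#' @param outflow explicit vector of movers T_i per origin.
#' @param fraction alternatively, the mobile fraction: T_i = fraction * m_i.
#' @param observed alternatively, an observed OD matrix from which the mobile
#'   fraction is calibrated by no-intercept regression.
#' @param round_to_int round fluxes to the nearest integer (default TRUE).
#' @param ... unused.
#' @return L x L predicted flux matrix.
#' @export
predict.radiation <- function(object, outflow = NULL, fraction = NULL,
                              observed = NULL, round_to_int = TRUE, ...) {
  predict_fluxes(object$P, resolve_outflow(object, outflow, fraction, observed),
                 round_to_int = round_to_int)
}

#' Simulate integer OD fluxes from a radiation model
#'
#' Each origin's movers choose destinations multinomially with the model's
#' row probabilities, so simulated row sums equal the outflow totals exactly.
#'
#' @inheritParams predict.radiation
#' @param nsim number of replicate matrices.
#' @param seed optional seed.
#' @return A flux matrix (`nsim = 1`) or a list of them.
#' @export
simulate.radiation <- function(object, nsim = 1, seed = NULL, outflow = NULL,
                               fraction = NULL, observed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  T_i <- resolve_outflow(object, outflow, fraction, observed)
  L <- nrow(object$P)
  one <- function() {
    out <- matrix(0, L, L, dimnames = dimnames(object$P))
    for (i in seq_len(L)) {
      if (T_i[i] == 0) next
      p <- object$P[i, ]
      if (sum(p) == 0) stop("origin ", i, " has zero probability mass but T_i > 0")
      out[i, ] <- stats::rmultinom(1, T_i[i], p)
    }
    out
  }
  if (nsim == 1) one() else replicate(nsim, one(), simplify = FALSE)
}

#' Residual flux matrix (predicted minus observed)
#'
#' @inheritParams predict.radiation
#' @param observed observed OD matrix (also used to calibrate T_i when no
#'   `outflow`/`fraction` is given: the totals default to the observed
#'   off-diagonal row sums, the known-T_i convention).
#' @return Signed matrix `predicted - observed`.
#' @export
residuals.radiation <- function(object, observed, outflow = NULL,
                                fraction = NULL, ...) {
  if (is.null(outflow) && is.null(fraction)) {
    O <- observed; diag(O) <- 0
    outflow <- rowSums(O)
  }
  predict(object, outflow = outflow, fraction = fraction) - observed
}

#' Plot stopping probabilities against distance
#'
#' Scatter of the normalized p_ij against r_ij on log-log axes, colored by
#' whether the destination belongs to a penalized class.
#'
#' @param x a [radiation()] fit; @param ... passed to [graphics::plot()].
#' @export
plot.radiation <- function(x, ...) {
  off <- upper.tri(x$P) | lower.tri(x$P)
  keep <- off & x$P > 0 & x$distances > 0
  dest_class <- matrix(x$locations$class, nrow(x$P), ncol(x$P), byrow = TRUE)
  col <- ifelse(x$scheme[dest_class[keep]] > 1, "firebrick", "gray30")
  graphics::plot(x$distances[keep], x$P[keep], log = "xy",
                 xlab = "distance r_ij (km)", ylab = "p_ij (normalized)",
                 col = col, pch = 16, cex = 0.6,
                 main = paste("radiation model,", x$model, "variant"), ...)
  invisible(x)
}
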