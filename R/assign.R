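#' Per-class delta scheme
#'
#' Validates a vector of per-class benefit-compression factors. Class 1 is
#' the reference class and must have delta exactly 1; every delta must be
#' positive. delta > 1 compresses the class's benefit distribution towards
#' zero, penalizing its locations as origins of high thresholds and as
#' attractive destinations.
#'
#' @param delta numeric vector, one entry per class.
#' @return The validated numeric vector.
#' @export
inequality_scheme <- function(delta) {
  delta <- as.numeric(delta)
  if (!length(delta)) stop("empty scheme")
  if (any(!is.finite(delta)) || any(delta <= 0)) stop("deltas must be finite and > 0")
  if (delta[1] != 1) stop("class 1 is the reference class and must have delta = 1")
  delta
}

#' Per-capita rates
#'
#' Scales raw per-location counts (e.g. conflict casualties) by population.
#'
#' @param counts non-negative counts per location.
#' @param populations positive populations.
#' @return Elementwise `counts / populations`.
#' @export
per_capita <- function(counts, populations) {
  if (any(populations <= 0)) stop("populations must be > 0")
  if (length(counts) != length(populations)) stop("length mismatch")
  counts / populations
}

#' Binary top-fraction penalization
#'
#' Assigns the top `ceiling(fraction * L)` locations by covariate value to
#' the penalized class 2 and the rest to the reference class 1. Ties at the
#' cut are resolved by stable original order (and flagged with a warning).
#' When `values` is a list of covariates, the penalized set is the union of
#' the per-covariate top sets (so possibly more than `fraction` of L).
#'
#' @param values numeric vector of covariate values, or a list of such
#'   vectors for union mode.
#' @param fraction fraction of locations to penalize, in (0, 1); default 0.15.
#' @return Integer class labels (1 = reference, 2 = penalized).
#' @export
assign_binary_top <- function(values, fraction = 0.15) {
  if (is.list(values)) {
    sets <- lapply(values, function(v) which(assign_binary_top(v, fraction) == 2L))
    pen <- sort(unique(unlist(sets)))
    cl <- rep(1L, length(values[[1]]))
    cl[pen] <- 2L
    return(cl)
  }
  L <- length(values)
  if (!(fraction > 0 && fraction < 1))
    stop("fraction must lie strictly between 0 and 1")
  k <- ceiling(fraction * L)
  if (k < 1 || k >= L) stop("penalized set would be empty or the whole system")
  if (length(unique(values)) == 1L)
    warning("constant covariate: penalized set depends only on location order")
  ord <- order(values, decreasing = TRUE)  # stable: ties keep original order
  vs <- values[ord]
  if (vs[k] == vs[k + 1L])
    warning("tie at the penalization cut resolved by stable location order")
  cl <- rep(1L, L)
  cl[ord[seq_len(k)]] <- 2L
  cl
}

#' Graded linear delta ramp above a percentile
#'
#' Locations at or below the given percentile of the covariate get delta = 1;
#' above it, delta grows linearly with the distance from the percentile, from
#' 1 at the percentile up to `1 + Delta` at the maximum value. Each distinct
#' delta value defines its own class (so C = number of locations above the
#' percentile + 1, absent ties). The percentile uses the linear-interpolation
#' estimator (R's default type 7).
#'
#' @param values covariate values.
#' @param percentile quantile level in (0, 1); default 0.9.
#' @param Delta maximum excess penalization (> 0).
#' @return List with `delta` (per-location deltas), `class` (per-location
#'   class labels, 1 = reference) and `scheme` (per-class deltas, ascending).
#' @export
assign_linear_ramp <- function(values, percentile = 0.9, Delta) {
  if (Delta <= 0) stop("Delta must be > 0")
  q <- stats::quantile(values, percentile, names = FALSE)
  vmax <- max(values)
  if (vmax <= q) stop("degenerate ramp: maximum equals the percentile value")
  delta_loc <- ifelse(values <= q, 1, 1 + Delta * (values - q) / (vmax - q))
  lev <- sort(unique(delta_loc))
  stopifnot(lev[1] == 1)
  list(delta = delta_loc,
       class = match(delta_loc, lev),
       scheme = inequality_scheme(lev))
}
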