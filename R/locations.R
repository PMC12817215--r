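#' Validate and normalize a location table
#'
#' A location table is a plain `data.frame` with one row per location and
#' columns `id` (unique labels), `population` (positive counts: houses the
#' origin populations m_i and destination populations n_j), a coordinate pair
#' (`lat`/`lon` in degrees, or `x_km`/`y_km` planar), and optionally `class`
#' (integer labels 1..C; class 1 is the reference class with delta = 1) plus
#' any number of covariate columns (casualties per capita, flood exposure,
#' Gini index, ...).
#'
#' @param locations data.frame as described above.
#' @return The validated data.frame with `id` as character, `class` filled in
#'   (all 1 when absent) and an attribute `coord_system` set to `"haversine"`
#'   or `"euclidean"`.
#' @export
validate_locations <- function(locations) {
  if (!is.data.frame(locations)) stop("`locations` must be a data.frame")
  need <- c("id", "population")
  miss <- setdiff(need, names(locations))
  if (length(miss)) stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (nrow(locations) < 2L) stop("at least 2 locations are required")
  locations$id <- as.character(locations$id)
  if (anyDuplicated(locations$id))
    stop("duplicate location id(s): ",
         paste(unique(locations$id[duplicated(locations$id)]), collapse = ", "))
  pop <- locations$population
  if (!is.numeric(pop) || anyNA(pop) || any(pop < 1))
    stop("populations must be numeric and >= 1 (offending row(s): ",
         paste(which(!is.finite(pop) | pop < 1), collapse = ", "), ")")

  has_geo <- all(c("lat", "lon") %in% names(locations))
  has_pla <- all(c("x_km", "y_km") %in% names(locations))
  if (has_geo && has_pla)
    stop("ambiguous coordinates: both lat/lon and x_km/y_km present")
  if (!has_geo && !has_pla)
    stop("no coordinates: provide lat/lon (degrees) or x_km/y_km (planar)")
  if (has_geo) {
    if (any(!is.finite(locations$lat)) || any(!is.finite(locations$lon)))
      stop("non-finite lat/lon")
    if (any(abs(locations$lat) > 90) || any(abs(locations$lon) > 180))
      stop("lat must lie in [-90, 90] and lon in [-180, 180]")
  } else {
    if (any(!is.finite(locations$x_km)) || any(!is.finite(locations$y_km)))
      stop("non-finite x_km/y_km")
  }

  if (is.null(locations$class)) locations$class <- 1L
  cl <- locations$class
  if (anyNA(cl) || any(cl != as.integer(cl)) || any(cl < 1L))
    stop("class labels must be positive integers")
  locations$class <- as.integer(cl)
  C <- max(locations$class)
  if (!setequal(unique(locations$class), seq_len(C)))
    stop("class labels must form a contiguous set 1..C")
  attr(locations, "coord_system") <- if (has_geo) "haversine" else "euclidean"
  locations
}

#' Pairwise distance matrix between locations
#'
#' Geographic input uses the haversine great-circle distance on the mean
#' Earth radius 6371.0088 km; planar input uses the Euclidean distance (km).
#'
#' @param locations location table (see [validate_locations()]).
#' @param metric `"auto"` (inferred from the coordinate columns),
#'   `"haversine"` or `"euclidean"`.
#' @return Symmetric L x L matrix of distances in km, zero diagonal, with the
#'   location ids as dimnames and the metric recorded in attribute `metric`.
#' @export
compute_distances <- function(locations, metric = c("auto", "haversine", "euclidean")) {
  metric <- match.arg(metric)
  locations <- validate_locations(locations)
  system <- attr(locations, "coord_system")
  if (metric == "auto") metric <- system
  if (metric != system)
    stop("requested metric '", metric, "' but coordinates are ", system)
  if (metric == "haversine") {
    p <- cbind(locations$lon, locations$lat)
    # distHaversine is linear in the radius: rescale its default to 6371.0088 km
    d <- geosphere::distm(p, fun = geosphere::distHaversine) / 6378137 * 6371.0088
  } else {
    d <- as.matrix(stats::dist(cbind(locations$x_km, locations$y_km)))
  }
  d <- (d + t(d)) / 2
  diag(d) <- 0
  dimnames(d) <- list(locations$id, locations$id)
  attr(d, "metric") <- metric
  d
}

# Sorted-neighbour structure reused by every intervening-population pass:
# for each origin, the visit order by increasing distance and, per position,
# how many locations lie STRICTLY closer (ties at equal distance excluded).
neighbor_structure <- function(distances) {
  L <- nrow(distances)
  lapply(seq_len(L), function(i) {
    d <- distances[i, ]
    ord <- order(d)                      # stable: ties resolved by index
    r <- rle(d[ord])
    strict <- rep.int(cumsum(c(0L, r$lengths[-length(r$lengths)])), r$lengths)
    list(ord = ord, strict = strict, d0 = d[ord] > 0)
  })
}

# Weighted intervening mass: S[i, j] = sum of w_l over locations l != i, j
# with r_il strictly less than r_ij. O(L log L) per origin.
intervening_weighted <- function(neigh, w) {
  L <- length(neigh)
  S <- matrix(0, L, L)
  for (i in seq_len(L)) {
    ns <- neigh[[i]]
    cw <- cumsum(w[ns$ord])
    val <- ifelse(ns$strict == 0L, 0, cw[pmax(ns$strict, 1L)])
    # origin i itself (distance 0) is inside every positive-radius circle
    val <- val - w[i] * ns$d0
    S[i, ns$ord] <- val
  }
  diag(S) <- 0
  S
}

#' Intervening populations, total and split by class
#'
#' `s_ij` is the total population strictly within the circle of radius
#' `r_ij` centred at origin i, excluding both origin and destination;
#' `s_ij^(k)` is its class-k part, so that `s_ij = sum_k s_ij^(k)` exactly.
#' Locations exactly at distance `r_ij` are excluded (strict circle
#' membership), which also makes ties deterministic.
#'
#' @param locations location table with populations and classes.
#' @param distances matrix from [compute_distances()].
#' @return List with `total` (L x L matrix) and `by_class` (list of C
#'   matrices).
#' @export
intervening_population <- function(locations, distances) {
  locations <- validate_locations(locations)
  neigh <- neighbor_structure(distances)
  pop <- locations$population
  C <- max(locations$class)
  nm <- list(locations$id, locations$id)
  by_class <- lapply(seq_len(C), function(k) {
    S <- intervening_weighted(neigh, pop * (locations$class == k))
    dimnames(S) <- nm
    S
  })
  total <- Reduce(`+`, by_class)
  list(total = total, by_class = by_class)
}

#' Region centroids from settlement coordinates
#'
#' Unweighted arithmetic mean of the settlement latitudes and longitudes in
#' each region, the convention used to place administrative units when only
#' settlement-level coordinates are available. Averaging is done on raw
#' lat/lon, which is inappropriate for regions straddling the antimeridian.
#'
#' @param settlements data.frame with columns `region`, `lat`, `lon`.
#' @param regions optional character vector of regions that must be present;
#'   any listed region without settlements is an error.
#' @return data.frame with columns `region`, `lat`, `lon` (one row per region).
#' @export
centroid_from_settlements <- function(settlements, regions = NULL) {
  if (!all(c("region", "lat", "lon") %in% names(settlements)))
    stop("settlements need columns region, lat, lon")
  if (!is.null(regions)) {
    missing_regions <- setdiff(regions, unique(settlements$region))
    if (length(missing_regions))
      stop("region(s) without settlements: ", paste(missing_regions, collapse = ", "))
  }
  out <- aggregate(cbind(lat, lon) ~ region, data = settlements, FUN = mean)
  out[order(out$region), , drop = FALSE]
}
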