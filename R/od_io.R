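# Readers/writers for the two CSV interchange formats (location tables and
# long-format OD matrices) and the reproducibility metadata record.

#' Read a location table from CSV
#'
#' Expects a header with `id`, `population`, either `lat`/`lon` or
#' `x_km`/`y_km`, and optionally `class` plus covariate columns.
#'
#' @param path CSV file path.
#' @return Validated location table (see [validate_locations()]).
#' @export
read_locations <- function(path) {
  validate_locations(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_locations
#' @param locations location table to write.
#' @export
write_locations <- function(locations, path) {
  utils::write.csv(locations, path, row.names = FALSE)
  invisible(path)
}

#' Read a long-format OD matrix from CSV
#'
#' Columns `origin_id, destination_id, flux`; absent pairs are zero fluxes.
#' Unknown ids and negative fluxes are rejected; diagonal entries are
#' rejected (stoppping probabilities have p_ii = 0 by convention, so a
#' same-location flux cannot be represented); duplicated pairs are summed
#' with a warning.
#'
#' @param path CSV file path.
#' @param ids character vector of location ids fixing the matrix order.
#' @return L x L integer flux matrix with `ids` as dimnames.
#' @export
read_od <- function(path, ids) {
  od <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("origin_id", "destination_id", "flux")
  if (!all(need %in% names(od)))
    stop("OD file needs columns: ", paste(need, collapse = ", "))
  L <- length(ids)
  M <- matrix(0, L, L, dimnames = list(ids, ids))
  if (nrow(od) == 0) return(M)
  bad <- setdiff(c(od$origin_id, od$destination_id), ids)
  if (length(bad)) stop("unknown location id(s) in OD file: ", paste(bad, collapse = ", "))
  if (any(od$flux < 0)) stop("negative flux in OD file")
  if (any(od$origin_id == od$destination_id))
    stop("diagonal OD entries are not allowed (within-location flux is zero by convention)")
  key <- paste(od$origin_id, od$destination_id)
  if (anyDuplicated(key)) {
    warning("duplicate origin-destination pairs summed")
    od <- aggregate(flux ~ origin_id + destination_id, data = od, FUN = sum)
  }
  M[cbind(match(od$origin_id, ids), match(od$destination_id, ids))] <- od$flux
  M
}

#' @rdname read_od
#' @param od L x L flux matrix with dimnames; only nonzero cells are written.
#' @export
write_od <- function(od, path) {
  nz <- which(od != 0, arr.ind = TRUE)
  out <- data.frame(origin_id = rownames(od)[nz[, 1]],
                    destination_id = colnames(od)[nz[, 2]],
                    flux = od[nz])
  out <- out[order(out$origin_id, out$destination_id), , drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Run-metadata record
#'
#' Collects everything needed to reproduce a model run bit-for-bit: model
#' variant, deltas, metric, seed, clipping counts and the package version.
#'
#' @param model model variant tag.
#' @param scheme per-class deltas.
#' @param metric distance metric used.
#' @param seed RNG seed (or NA).
#' @param clipped number of clipped linearized probabilities.
#' @param path optional JSON output path.
#' @return The metadata list, invisibly if written.
#' @export
run_metadata <- function(model, scheme, metric, seed = NA, clipped = 0,
                         path = NULL) {
  meta <- list(model = model, delta = as.numeric(scheme), metric = metric,
               seed = seed, clipped = clipped,
               package_version = as.character(utils::packageVersion("ineqrad")),
               timestamp = format(Sys.time(), tz = "UTC"))
  if (!is.null(path)) {
    jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(meta))
  }
  meta
}
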