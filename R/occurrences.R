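# Occurrence records: loading, validation, spatial thinning, sampling-bias
# surface and background sampling.

#' Load presence records for one species from delimited text
#'
#' Accepts comma- or tab-delimited text with a header naming at least
#' `species`, `lon`, `lat`; `year` and `source` are optional.  Rows with
#' malformed or out-of-range coordinates are rejected (and reported), and
#' records sharing an identical `(lon, lat)` pair are collapsed to one,
#' keeping the most recent year among the duplicates.
#'
#' @param path file path.
#' @param species species label to extract.
#' @return An `occurrence_set`: data.frame with columns `species`, `lon`,
#'   `lat`, `year`, `source`; attributes `n_rejected` (bad coordinates) and
#'   `n_duplicates` (coordinate duplicates collapsed).
#' @export
load_occurrences <- function(path, species) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, fill = TRUE)
  names(df) <- tolower(names(df))
  if (!all(c("species", "lon", "lat") %in% names(df)))
    stop("occurrence file must have columns species, lon, lat")
  df <- df[df$species == species, , drop = FALSE]
  if (nrow(df) == 0) stop("no rows for species '", species, "' in ", path)
  df$lon <- suppressWarnings(as.numeric(df$lon))
  df$lat <- suppressWarnings(as.numeric(df$lat))
  bad <- is.na(df$lon) | is.na(df$lat) |
    df$lat < -90 | df$lat > 90 | df$lon < -180 | df$lon > 180
  if (any(bad))
    message(sum(bad), " row(s) rejected for malformed/out-of-range coordinates")
  df <- df[!bad, , drop = FALSE]
  if (nrow(df) == 0) stop("no valid records for species '", species, "'")
  if (is.null(df$year)) df$year <- NA_integer_
  df$year <- suppressWarnings(as.integer(df$year))
  if (is.null(df$source)) df$source <- NA_character_
  occurrence_set(species,
                 data.frame(lon = df$lon, lat = df$lat, year = df$year,
                            source = df$source, stringsAsFactors = FALSE),
                 n_rejected = sum(bad))
}

#' Construct an occurrence set (deduplicated by exact coordinates)
#'
#' @param species species label.
#' @param records data.frame with `lon`, `lat` and optionally `year`, `source`.
#' @param n_rejected bookkeeping count carried through from loading.
#' @return data.frame of class `occurrence_set`.
#' @export
occurrence_set <- function(species, records, n_rejected = 0L) {
  if (is.null(records$year)) records$year <- NA_integer_
  if (is.null(records$source)) records$source <- NA_character_
  # collapse coordinate duplicates, keeping the most recent year per location
  key <- paste(records$lon, records$lat)
  ord <- order(key, -xtfrm(ifelse(is.na(records$year), -Inf, records$year)))
  records <- records[ord, , drop = FALSE]
  dup <- duplicated(paste(records$lon, records$lat))
  n_dup <- sum(dup)
  records <- records[!dup, , drop = FALSE]
  out <- data.frame(species = species, lon = records$lon, lat = records$lat,
                    year = records$year, source = records$source,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_rejected") <- n_rejected
  attr(out, "n_duplicates") <- n_dup
  class(out) <- c("occurrence_set", "data.frame")
  out
}

#' Great-circle distance in kilometers
#'
#' Haversine distance on a sphere of radius 6371 km (via
#' \pkg{geosphere}).  Vectorized over both arguments.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in decimal degrees.
#' @return distance(s) in km.
#' @export
geodesic_distance_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_KM)
}

#' Spatially thin occurrence records
#'
#' Greedy thinning with recency preference: records are sorted by year
#' descending (records with unknown year last, ties kept in input order), then
#' scanned once, keeping a record iff it lies more than `min_distance_km` from
#' every record already kept.  The result is deterministic, idempotent, and
#' every retained pair is separated by more than `min_distance_km`.
#'
#' @param set an [occurrence_set()].
#' @param min_distance_km minimum pairwise separation (default 50 km).
#' @param prefer `"recent"` (default) to rank newer records first, `"first"`
#'   to keep the input order.
#' @return The thinned `occurrence_set`, in the scan order.
#' @export
thin <- function(set, min_distance_km = 50, prefer = c("recent", "first")) {
  prefer <- match.arg(prefer)
  stopifnot(min_distance_km > 0)
  n <- nrow(set)
  if (n == 0) return(set)
  ord <- if (prefer == "recent") {
    yr <- ifelse(is.na(set$year), -Inf, set$year)
    order(-yr)               # stable: ties stay in file order
  } else seq_len(n)
  s <- set[ord, , drop = FALSE]
  keep <- logical(n)
  keep[1] <- TRUE
  for (i in seq_len(n)[-1]) {
    kept <- which(keep)
    d <- geodesic_distance_km(s$lon[i], s$lat[i], s$lon[kept], s$lat[kept])
    if (all(d > min_distance_km)) keep[i] <- TRUE
  }
  out <- s[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_rejected") <- attr(set, "n_rejected")
  attr(out, "n_duplicates") <- attr(set, "n_duplicates")
  class(out) <- class(set)
  out
}

#' Sampling-bias surface from occurrence density
#'
#' Two-dimensional Gaussian kernel density estimate of collection effort,
#' evaluated at the cell centers of `grid` and renormalized to sum to one over
#' non-missing cells.  Bandwidths follow the normal-reference rule
#' `h = 4 * 1.06 * min(sd, IQR/1.34) * n^(-1/5)` per axis with kernel standard
#' deviation `h/4` (the \code{MASS::kde2d} convention); duplicated coordinates
#' are collapsed first.
#'
#' @param set an [occurrence_set()] with at least 2 distinct coordinates.
#' @param grid a [grid_spec()].
#' @param h optional length-2 bandwidth override `(h_lon, h_lat)`.
#' @param mask optional raster on the same grid; its `NA` cells are flagged
#'   missing in the bias surface.
#' @return A `bias_surface`: an [new_raster()] whose non-missing weights are
#'   `>= 0` and sum to 1.
#' @export
kde_bias_surface <- function(set, grid, h = NULL, mask = NULL) {
  pts <- unique(data.frame(lon = set$lon, lat = set$lat))
  if (nrow(pts) < 2)
    stop("need >= 2 distinct coordinates; jitter the records or use a uniform bias surface")
  if (is.null(h)) {
    h <- c(MASS::bandwidth.nrd(pts$lon), MASS::bandwidth.nrd(pts$lat))
    if (any(h <= 0)) stop("degenerate bandwidth; supply h explicitly")
  }
  lons <- cell_lons(grid)
  lats <- cell_lats(grid)       # north-first, matching the value matrix
  k <- MASS::kde2d(pts$lon, pts$lat, h = h,
                   n = c(grid$ncols, grid$nrows),
                   lims = c(range(lons), range(sort(lats))))
  # kde2d returns z[x, y] with y ascending; reorient to north-first rows
  z <- t(k$z)[grid$nrows:1, , drop = FALSE]
  if (!is.null(mask)) z[is.na(mask$values)] <- NA
  tot <- sum(z, na.rm = TRUE)
  if (!is.finite(tot) || tot <= 0) stop("kernel density vanished on the grid")
  out <- new_raster(grid, z / tot)
  class(out) <- c("bias_surface", class(out))
  out
}

#' Uniform bias surface over a grid
#' @param grid a [grid_spec()].
#' @param mask optional raster; its `NA` cells are excluded.
#' @return A `bias_surface` with equal weights.
#' @export
uniform_bias_surface <- function(grid, mask = NULL) {
  z <- matrix(1, grid$nrows, grid$ncols)
  if (!is.null(mask)) z[is.na(mask$values)] <- NA
  out <- new_raster(grid, z / sum(z, na.rm = TRUE))
  class(out) <- c("bias_surface", class(out))
  out
}

#' Sample background points from a bias surface
#'
#' Draws `n` cell centers with replacement, with probability proportional to
#' the bias weight; zero-weight and missing cells are never drawn.
#'
#' @param bias a `bias_surface` (see [kde_bias_surface()]).
#' @param n number of points (default 10000).
#' @param seed integer seed; fixed seed gives an identical point sequence.
#' @return data.frame with columns `lon`, `lat`.
#' @export
sample_background <- function(bias, n = 10000, seed = 1L) {
  stopifnot(n > 0)
  spec <- bias$spec
  w <- as.vector(bias$values)      # column-major: cell = (row, col)
  ok <- which(!is.na(w) & w > 0)
  if (length(ok) == 0) stop("no cell with positive weight")
  set.seed(as.integer(seed))
  cells <- ok[sample.int(length(ok), n, replace = TRUE, prob = w[ok])]
  row <- (cells - 1) %% spec$nrows + 1
  col <- (cells - 1) %/% spec$nrows + 1
  data.frame(lon = cell_lons(spec)[col], lat = cell_lats(spec)[row])
}
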