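#' @useDynLib enmdyn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor sd quantile aov TukeyHSD anova optim prcomp rnorm runif
#'   setNames aggregate lm as.formula var ks.test chisq.test complete.cases
#' @importFrom utils read.table write.table combn head
NULL

# Earth radius (km) used for all spherical geometry in this package.
EARTH_RADIUS_KM <- 6371

#' Grid specification for a regular lon/lat raster
#'
#' Describes a regular grid of square (in degrees) cells, ESRI-ASCII style:
#' `xll`/`yll` are the coordinates of the *corner* of the lower-left cell.
#' Cell centers are at `xll + (j - 0.5) * cellsize`, `yll + (i - 0.5) * cellsize`
#' counting from the south-west; point-in-cell assignment uses half-open
#' intervals `[west, east) x [south, north)` so every point maps to at most one
#' cell.
#'
#' @param ncols,nrows grid dimensions (>= 1).
#' @param xll,yll lower-left corner longitude/latitude in decimal degrees.
#' @param cellsize cell edge in degrees (> 0).
#' @param nodata sentinel value written for missing cells.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(ncols, nrows, xll, yll, cellsize, nodata = -9999) {
  stopifnot(ncols >= 1, nrows >= 1, cellsize > 0)
  if (xll < -180 - 1e-9 || xll + ncols * cellsize > 180 + 1e-6 ||
      yll < -90 - 1e-9 || yll + nrows * cellsize > 90 + 1e-6) {
    stop("grid extends outside [-180,180] x [-90,90]")
  }
  structure(list(ncols = as.integer(ncols), nrows = as.integer(nrows),
                 xll = xll, yll = yll, cellsize = cellsize, nodata = nodata),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells, cellsize %g deg, origin (%g, %g)\n",
              x$nrows, x$ncols, x$cellsize, x$xll, x$yll))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-9) {
  a$ncols == b$ncols && a$nrows == b$nrows &&
    abs(a$xll - b$xll) < tol && abs(a$yll - b$yll) < tol &&
    abs(a$cellsize - b$cellsize) < tol
}

# Cell-center coordinate vectors.  Rows are stored north-first (file order),
# so row i (1 = northernmost) has center latitude yll + (nrows - i + 0.5)*cs.
cell_lons <- function(spec) spec$xll + (seq_len(spec$ncols) - 0.5) * spec$cellsize
cell_lats <- function(spec) spec$yll + (spec$nrows:1 - 0.5) * spec$cellsize

#' In-memory raster: a grid_spec plus a value matrix
#'
#' @param spec a [grid_spec()].
#' @param values numeric matrix `nrows x ncols`; row 1 is the northernmost row
#'   (matching ESRI ASCII file order); `NA` marks missing cells.
#' @return An object of class `enm_raster`.
#' @export
new_raster <- function(spec, values) {
  values <- as.matrix(values)
  if (nrow(values) != spec$nrows || ncol(values) != spec$ncols)
    stop("value matrix dimensions do not match the grid spec")
  structure(list(spec = spec, values = values), class = "enm_raster")
}

#' @export
print.enm_raster <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("enm_raster %d x %d (%d missing), range [%g, %g]\n",
              x$spec$nrows, x$spec$ncols, sum(is.na(x$values)),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' Map points to cell indices
#'
#' @param spec a [grid_spec()].
#' @param lon,lat coordinate vectors (degrees).
#' @return data.frame with columns `row` (1 = north), `col`; `NA` for points
#'   outside the grid.
#' @export
point_to_cell <- function(spec, lon, lat) {
  col <- floor((lon - spec$xll) / spec$cellsize) + 1
  row_s <- floor((lat - spec$yll) / spec$cellsize) + 1   # from the south
  ok <- col >= 1 & col <= spec$ncols & row_s >= 1 & row_s <= spec$nrows
  col[!ok] <- NA_integer_
  row_s[!ok] <- NA_integer_
  data.frame(row = spec$nrows - row_s + 1L, col = as.integer(col))
}

#' Read an ESRI ASCII grid
#'
#' Parses the six-keyword header (`ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, `NODATA_value`) followed by row-major values, northern row
#' first.  `write_ascii_grid()` is its inverse; write-then-read is the identity
#' on spec and values up to text round-trip precision.
#'
#' @param path file path.
#' @return An [new_raster()] object.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+[-0-9.eE+]+\\s*$", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ESRI ASCII header in ", path, ": missing ",
         paste(setdiff(need, names(hdr)), collapse = ", "))
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               what = numeric(), quiet = TRUE)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  if (length(vals) != nc * nr)
    stop(sprintf("value count mismatch in %s: header declares %d x %d = %d values, found %d (data starting at line %d)",
                 path, nr, nc, nr * nc, length(vals), i))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA
  new_raster(grid_spec(nc, nr, hdr$xllcorner, hdr$yllcorner, hdr$cellsize,
                       nodata), m)
}

#' @rdname read_ascii_grid
#' @param raster an [new_raster()] object.
#' @export
write_ascii_grid <- function(raster, path) {
  spec <- raster$spec
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", spec$ncols),
    sprintf("nrows %d", spec$nrows),
    sprintf("xllcorner %.10g", spec$xll),
    sprintf("yllcorner %.10g", spec$yll),
    sprintf("cellsize %.10g", spec$cellsize),
    sprintf("NODATA_value %.10g", spec$nodata)), con)
  m <- raster$values
  m[is.na(m)] <- spec$nodata
  for (i in seq_len(spec$nrows))
    writeLines(paste(format(m[i, ], digits = 10, trim = TRUE,
                            scientific = FALSE), collapse = " "), con)
  invisible(path)
}

#' Bundle co-registered climate layers
#'
#' @param layers named list of [new_raster()] objects (e.g. `bio1` ... `bio19`),
#'   all sharing one grid.
#' @param period period/scenario label (e.g. `"current"`, `"LGM"`,
#'   `"2070-rcp85"`).
#' @param climate_model climate-model label (e.g. `"MPI-ESM"`).
#' @return An object of class `layer_stack`.
#' @export
layer_stack <- function(layers, period = "current", climate_model = "none") {
  if (length(layers) == 0) stop("empty layer list")
  nms <- names(layers)
  if (is.null(nms) || anyDuplicated(nms) || any(nms == ""))
    stop("layers must be uniquely named")
  spec <- layers[[1]]$spec
  for (l in layers) if (!same_grid(l$spec, spec))
    stop("all layers must share one grid")
  structure(list(layers = layers, spec = spec, period = period,
                 climate_model = climate_model), class = "layer_stack")
}

#' @export
print.layer_stack <- function(x, ...) {
  cat(sprintf("layer_stack '%s' (%s): %d layers on %d x %d grid\n",
              x$period, x$climate_model, length(x$layers),
              x$spec$nrows, x$spec$ncols))
  invisible(x)
}

#' Crop a stack to a lon/lat bounding box
#'
#' Keeps exactly the cells whose centers fall inside the (half-open)
#' box `[lon_min, lon_max) x [lat_min, lat_max)`; values are untouched.
#'
#' @param stack a [layer_stack()].
#' @param bbox numeric vector `c(lon_min, lon_max, lat_min, lat_max)`.
#' @return A cropped [layer_stack()].
#' @export
crop <- function(stack, bbox) {
  stopifnot(length(bbox) == 4)
  spec <- stack$spec
  lons <- cell_lons(spec); lats <- cell_lats(spec)
  jkeep <- which(lons >= bbox[1] & lons < bbox[2])
  ikeep <- which(lats >= bbox[3] & lats < bbox[4])
  if (length(jkeep) == 0 || length(ikeep) == 0)
    stop("bounding box does not overlap the grid")
  # new lower-left corner from the kept cell block
  new_xll <- spec$xll + (min(jkeep) - 1) * spec$cellsize
  new_yll <- spec$yll + (spec$nrows - max(ikeep)) * spec$cellsize
  nspec <- grid_spec(length(jkeep), length(ikeep), new_xll, new_yll,
                     spec$cellsize, spec$nodata)
  layers <- lapply(stack$layers, function(l)
    new_raster(nspec, l$values[ikeep, jkeep, drop = FALSE]))
  layer_stack(layers, stack$period, stack$climate_model)
}

#' Extract a samples-with-data (SWD) table at points
#'
#' Each point is mapped to its containing cell and the cell's value in every
#' layer is read off.  Points outside the grid, or falling on a cell that is
#' missing in any layer, are dropped; the counts are attached as attributes
#' `n_outside` and `n_missing`.
#'
#' @param stack a [layer_stack()].
#' @param points data.frame with columns `lon`, `lat`.
#' @param label species label for the table (or `"background"`).
#' @return data.frame with columns `species`, `lon`, `lat`, then one column per
#'   layer; class `swd_table`.
#' @export
extract_swd <- function(stack, points, label = "background") {
  cells <- point_to_cell(stack$spec, points$lon, points$lat)
  inside <- !is.na(cells$row)
  n_outside <- sum(!inside)
  idx <- cbind(cells$row[inside], cells$col[inside])
  vals <- vapply(stack$layers, function(l) l$values[idx],
                 numeric(sum(inside)))
  if (sum(inside) == 1) vals <- matrix(vals, nrow = 1,
                                       dimnames = list(NULL, names(stack$layers)))
  complete <- stats::complete.cases(vals)
  n_missing <- sum(!complete)
  out <- data.frame(species = label,
                    lon = points$lon[inside][complete],
                    lat = points$lat[inside][complete])
  out <- cbind(out, as.data.frame(vals[complete, , drop = FALSE]))
  rownames(out) <- NULL
  attr(out, "n_outside") <- n_outside
  attr(out, "n_missing") <- n_missing
  class(out) <- c("swd_table", "data.frame")
  out
}

swd_vars <- function(swd) setdiff(colnames(swd), c("species", "lon", "lat"))

swd_matrix <- function(swd) as.matrix(swd[, swd_vars(swd), drop = FALSE])

#' Write / read an SWD table as delimited text
#' @param swd an SWD data.frame.
#' @param path file path.
#' @export
write_swd <- function(swd, path) {
  utils::write.csv(as.data.frame(swd), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_swd
#' @export
read_swd <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("swd_table", "data.frame")
  out
}

#' Spherical area of the cells in one grid row
#'
#' Exact area on a sphere of radius 6371 km:
#' `A = R^2 * dlambda * (sin(phi_top) - sin(phi_bottom))`, identical for every
#' cell of a row.
#'
#' @param spec a [grid_spec()].
#' @param row_index row index, 1 = northernmost row.
#' @return Cell area in km^2.
#' @export
cell_area_km2 <- function(spec, row_index) {
  stopifnot(all(row_index >= 1), all(row_index <= spec$nrows))
  lat_top <- spec$yll + (spec$nrows - row_index + 1) * spec$cellsize
  lat_bot <- lat_top - spec$cellsize
  dlam <- spec$cellsize * pi / 180
  EARTH_RADIUS_KM^2 * dlam * (sin(lat_top * pi / 180) - sin(lat_bot * pi / 180))
}

#' Pairwise Pearson correlations of SWD variables
#'
#' @param swd an SWD table (>= 3 complete rows).
#' @param threshold absolute-correlation flag threshold (default 0.9).
#' @return list with `r` (correlation matrix, unit diagonal), `flagged`
#'   (data.frame of variable pairs with `|r| >= threshold`), and `constant`
#'   (names of zero-variance variables, whose correlations are `NA`).
#' @export
correlation_matrix <- function(swd, threshold = 0.9) {
  x <- swd_matrix(swd)
  if (nrow(x) < 3) stop("need at least 3 complete rows")
  sds <- apply(x, 2, stats::sd)
  constant <- colnames(x)[sds == 0]
  r <- suppressWarnings(stats::cor(x))
  diag(r) <- 1
  pairs <- which(upper.tri(r) & !is.na(r) & abs(r) >= threshold, arr.ind = TRUE)
  flagged <- data.frame(var1 = colnames(x)[pairs[, 1]],
                        var2 = colnames(x)[pairs[, 2]],
                        r = r[pairs])
  list(r = r, flagged = flagged, constant = constant)
}
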