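# Threshold-based suitable-area dynamics: binary maps, spherical areas split
# by region, period/scenario series, and climatic-variable ranges within the
# suitable area.

#' Threshold a suitability map
#'
#' @param suitability an [new_raster()] of cloglog suitability.
#' @param t threshold in `[0, 1]`; a cell is suitable iff its value `>= t`.
#' @param labels optional named list carried along (species, period, ...).
#' @return A `thresholded_map`: raster of `{0, 1, NA}` plus `t` and labels.
#' @export
threshold_map <- function(suitability, t, labels = list()) {
  stopifnot(t >= 0, t <= 1)
  bin <- (suitability$values >= t) + 0
  structure(list(binary = new_raster(suitability$spec, bin), t = t,
                 labels = labels), class = "thresholded_map")
}

#' Regional suitable areas in km^2
#'
#' Sums exact spherical cell areas over suitable cells.  A cell belongs to
#' Europe iff its center longitude is `< meridian` (default 60 degrees E, the
#' Ural line), else to Asia, so `europe + asia = total` exactly; it is polar
#' iff its center latitude is `>= polar_lat` (default 66.562 degrees N, the
#' Arctic Circle).
#'
#' @param map a [threshold_map()] result.
#' @param meridian Europe/Asia boundary longitude.
#' @param polar_lat polar boundary latitude.
#' @return list with `total`, `europe`, `asia`, `polar` (km^2).
#' @export
regional_areas <- function(map, meridian = 60, polar_lat = 66.562) {
  spec <- map$binary$spec
  v <- map$binary$values
  row_area <- cell_area_km2(spec, seq_len(spec$nrows))
  lons <- cell_lons(spec)
  lats <- cell_lats(spec)
  suit <- !is.na(v) & v == 1
  counts <- rowSums(suit)
  counts_eu <- rowSums(suit[, lons < meridian, drop = FALSE])
  total <- sum(counts * row_area)
  europe <- sum(counts_eu * row_area)
  polar <- sum((counts * row_area)[lats >= polar_lat])
  list(total = total, europe = europe, asia = total - europe, polar = polar)
}

#' Suitable-area series across periods and scenarios
#'
#' Projects each model onto each of its period stacks, averages nothing (one
#' suitability map per run is expected; replicate averaging happens upstream),
#' thresholds at the run's threshold, and tabulates regional areas.
#'
#' @param runs list of runs, each a list with `species`, `model` (a
#'   [fit_maxent()] model or a precomputed suitability raster per period),
#'   `stacks` (named list of [layer_stack()] per period label), and `t`
#'   (threshold for that run).
#' @param meridian,polar_lat regional boundaries (see [regional_areas()]).
#' @return data.frame of class `area_series` with one row per
#'   (species, period, scenario/climate model).
#' @export
area_series <- function(runs, meridian = 60, polar_lat = 66.562) {
  rows <- list()
  for (run in runs) {
    for (period in names(run$stacks)) {
      stack <- run$stacks[[period]]
      if (is.null(stack)) {
        warning("missing stack for period ", period, "; row skipped")
        next
      }
      suit <- if (inherits(run$model, "maxent_model"))
        project_model(run$model, stack) else run$model[[period]]
      tm <- threshold_map(suit, run$t,
                          labels = list(species = run$species,
                                        period = period,
                                        climate_model = stack$climate_model))
      a <- regional_areas(tm, meridian = meridian, polar_lat = polar_lat)
      rows[[length(rows) + 1]] <- data.frame(
        species = run$species, period = period,
        climate_model = stack$climate_model,
        total_km2 = a$total, europe_km2 = a$europe, asia_km2 = a$asia,
        polar_km2 = a$polar)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("area_series", "data.frame")
  out
}

#' Mean suitability over replicate maps
#' @param rasters list of suitability rasters on one grid.
#' @return the cellwise mean raster.
#' @export
average_suitability <- function(rasters) {
  stopifnot(length(rasters) >= 1)
  spec <- rasters[[1]]$spec
  acc <- Reduce(`+`, lapply(rasters, `[[`, "values"))
  new_raster(spec, acc / length(rasters))
}

#' Climatic-variable ranges within the suitable area
#'
#' @param map a [threshold_map()] result.
#' @param stack a [layer_stack()] on the same grid.
#' @return data.frame with `variable`, `min`, `max` over suitable,
#'   non-missing cells.
#' @export
variable_ranges <- function(map, stack) {
  if (!same_grid(map$binary$spec, stack$spec))
    stop("map and stack are on different grids")
  suit <- !is.na(map$binary$values) & map$binary$values == 1
  if (!any(suit)) stop("no suitable cells at threshold ", map$t)
  rows <- lapply(names(stack$layers), function(v) {
    vals <- stack$layers[[v]]$values[suit]
    vals <- vals[!is.na(vals)]
    data.frame(variable = v, min = min(vals), max = max(vals))
  })
  do.call(rbind, rows)
}
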