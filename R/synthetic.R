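# Synthetic study system: correlated climate raster stacks, period/scenario
# variants, virtual species with known Gaussian niches, and biased
# presence-only sampling.  Everything is a pure function of (spec, seed), so
# recovery tests have stored ground truth.

#' Specification for a synthetic climate stack
#'
#' Each variable is a planar latitudinal/longitudinal gradient plus smoothed,
#' cross-correlated Gaussian noise.  Noise fields are built by separable
#' moving-average smoothing of white noise, empirically whitened, and mixed
#' through the Cholesky factor of `target_corr`, so the noise component's
#' correlation matrix matches the target essentially exactly; nonzero
#' gradients shift the total correlations away from the target (documented
#' behavior).
#'
#' @param grid a [grid_spec()]; default 100 x 100 cells of 0.25 degrees over
#'   10-35 E, 30-55 N.
#' @param n_vars number of variables, named `bio1...` (default 19).
#' @param base per-variable offset (value at the south-west corner trend
#'   plane).
#' @param grad_lat,grad_lon per-variable change across the full grid extent.
#' @param noise_amp per-variable noise standard deviation.
#' @param corr_length noise correlation length in cells (default 5).
#' @param target_corr target noise correlation matrix (symmetric PSD, unit
#'   diagonal); default `0.5^|i-j|` between variable indices.
#' @param seed integer seed.
#' @return list of class `synthetic_climate_spec`.
#' @export
synthetic_climate_spec <- function(grid = grid_spec(100, 100, 10, 30, 0.25),
                                   n_vars = 19,
                                   base = NULL, grad_lat = NULL,
                                   grad_lon = NULL, noise_amp = NULL,
                                   corr_length = 5, target_corr = NULL,
                                   seed = 1L) {
  vars <- paste0("bio", seq_len(n_vars))
  is_temp <- seq_len(n_vars) <= min(11, n_vars)   # bio1-bio11 temperature-like
  if (is.null(base))
    base <- ifelse(is_temp, 24, 500)
  if (is.null(grad_lat))             # cooler northward, slightly wetter north
    grad_lat <- ifelse(is_temp, -23, 200)
  if (is.null(grad_lon))             # drier eastward (continentality)
    grad_lon <- ifelse(is_temp, -2, -400)
  if (is.null(noise_amp))
    noise_amp <- ifelse(is_temp, 2.5, 120)
  if (is.null(target_corr))
    target_corr <- 0.5^abs(outer(seq_len(n_vars), seq_len(n_vars), "-"))
  stopifnot(nrow(target_corr) == n_vars, isSymmetric(unname(target_corr)))
  ev <- eigen(target_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("target correlation matrix is not PSD")
  structure(list(grid = grid, vars = vars,
                 base = stats::setNames(rep_len(base, n_vars), vars),
                 grad_lat = stats::setNames(rep_len(grad_lat, n_vars), vars),
                 grad_lon = stats::setNames(rep_len(grad_lon, n_vars), vars),
                 noise_amp = stats::setNames(rep_len(noise_amp, n_vars), vars),
                 corr_length = corr_length, target_corr = target_corr,
                 seed = as.integer(seed)),
            class = "synthetic_climate_spec")
}

# separable moving-average smoothing of a matrix (reflecting borders via
# padded white noise), used to build spatially autocorrelated fields
smooth_field <- function(nr, nc, w) {
  pad <- w
  m <- matrix(stats::rnorm((nr + 2 * pad) * (nc + 2 * pad)),
              nr + 2 * pad, nc + 2 * pad)
  k <- rep(1, 2 * w + 1)
  m <- apply(m, 2, function(col) stats::filter(col, k, sides = 2))
  m <- t(apply(m, 1, function(row) stats::filter(row, k, sides = 2)))
  m[(pad + 1):(pad + nr), (pad + 1):(pad + nc)]
}

#' Generate a synthetic climate layer stack
#'
#' @param spec a [synthetic_climate_spec()].
#' @param period,climate_model labels for the produced stack.
#' @return A [layer_stack()]; bit-identical for a fixed spec (seed included).
#' @export
make_climate_stack <- function(spec, period = "current",
                               climate_model = "synthetic") {
  g <- spec$grid
  nr <- g$nrows; nc <- g$ncols
  nv <- length(spec$vars)
  set.seed(spec$seed)
  lat_norm <- matrix((cell_lats(g) - (g$yll)) / (g$nrows * g$cellsize),
                     nr, nc)
  lon_norm <- matrix(rep((cell_lons(g) - g$xll) / (g$ncols * g$cellsize),
                         each = nr), nr, nc)
  E <- vapply(seq_len(nv),
              function(k) as.vector(smooth_field(nr, nc, spec$corr_length)),
              numeric(nr * nc))
  E <- scale(E)
  # empirical whitening, then mixing: noise correlation == target exactly
  W <- E %*% solve(chol(stats::cov(E)))
  M <- W %*% chol(spec$target_corr)
  layers <- list()
  for (k in seq_len(nv)) {
    v <- spec$vars[k]
    vals <- spec$base[k] + spec$grad_lat[k] * lat_norm +
      spec$grad_lon[k] * lon_norm +
      spec$noise_amp[k] * matrix(M[, k], nr, nc)
    layers[[v]] <- new_raster(g, vals)
  }
  layer_stack(layers, period = period, climate_model = climate_model)
}

#' Perturb a stack into a period/scenario variant
#'
#' @param stack a [layer_stack()].
#' @param delta named numeric vector of per-variable offsets (e.g.
#'   `c(bio1 = 2)` for +2 degrees warming).
#' @param period new period label.
#' @return The offset [layer_stack()].
#' @export
make_scenario <- function(stack, delta, period) {
  unknown <- setdiff(names(delta), names(stack$layers))
  if (length(unknown))
    stop("unknown variable(s): ", paste(unknown, collapse = ", "))
  layers <- stack$layers
  for (v in names(delta))
    layers[[v]] <- new_raster(layers[[v]]$spec, layers[[v]]$values + delta[[v]])
  layer_stack(layers, period = period, climate_model = stack$climate_model)
}

#' Define a virtual species on a climate stack
#'
#' Bell-shaped niche with an optional optimal plateau: per driver variable the
#' response is 1 for `|z - mu| <= w` and falls off as a Gaussian shoulder
#' `exp(-(|z - mu| - w)^2 / (2 sigma^2))` beyond it; suitability is the
#' product over drivers, in (0, 1], so both "too cold" and "too hot" limits
#' exist.  `w = 0` gives the pure Gaussian bell.  The defaults place a
#' temperate species with an annual-temperature optimum around 12 degrees C
#' and a moderate-precipitation optimum, occupying roughly a tenth of the
#' default grid.  The true occupied area is the spherical area of cells with
#' suitability at or above `cutoff`.
#'
#' @param stack a [layer_stack()].
#' @param optima named vector of niche optima (variable units).
#' @param tolerances named vector of shoulder standard deviations.
#' @param plateau named vector of plateau half-widths `w` (same names;
#'   default 10 times the tolerance, i.e. a flat-topped response).
#' @param cutoff suitability cutoff defining the true occupied area
#'   (default 0.5).
#' @return list of class `virtual_species`: `optima`, `tolerances`,
#'   `plateau`, `suitability` (raster), `cutoff`, `true_area_km2`.
#' @export
virtual_species <- function(stack,
                            optima = c(bio1 = 12, bio12 = 500),
                            tolerances = c(bio1 = 0.35, bio12 = 10),
                            plateau = 10 * tolerances,
                            cutoff = 0.5) {
  stopifnot(identical(sort(names(optima)), sort(names(tolerances))),
            identical(sort(names(optima)), sort(names(plateau))))
  miss <- setdiff(names(optima), names(stack$layers))
  if (length(miss)) stop("unknown driver(s): ", paste(miss, collapse = ", "))
  sp <- structure(list(optima = optima, tolerances = tolerances,
                       plateau = plateau, cutoff = cutoff),
                  class = "virtual_species")
  sr <- true_suitability(sp, stack)
  sp$suitability <- sr
  sp$true_area_km2 <- regional_areas(threshold_map(sr, cutoff))$total
  sp
}

#' True suitability of a virtual species under a stack's conditions
#' @param species a [virtual_species()].
#' @param stack a [layer_stack()] carrying the driver variables.
#' @return suitability raster under that stack's conditions.
#' @export
true_suitability <- function(species, stack) {
  suit <- matrix(1, stack$spec$nrows, stack$spec$ncols)
  for (v in names(species$optima)) {
    z <- stack$layers[[v]]$values
    d <- pmax(0, abs(z - species$optima[[v]]) - species$plateau[[v]])
    suit <- suit * exp(-d^2 / (2 * species$tolerances[[v]]^2))
  }
  new_raster(stack$spec, suit)
}

#' Sample presence-only records of a virtual species
#'
#' Cells are drawn with replacement with probability proportional to
#' `suitability x bias`; coordinates are the cell centers plus uniform
#' sub-cell jitter.  Years are drawn uniformly from 1960-2020 so thinning's
#' recency preference is exercised.
#'
#' @param species a [virtual_species()].
#' @param n number of records.
#' @param bias a `bias_surface` on the same grid, or `NULL` for uniform
#'   sampling effort.
#' @param seed integer seed.
#' @param label species label for the records.
#' @return An [occurrence_set()]; the generating `virtual_species` is attached
#'   as attribute `truth`.
#' @export
sample_presences <- function(species, n, bias = NULL, seed = 1L,
                             label = "virtual") {
  stopifnot(n >= 1)
  spec <- species$suitability$spec
  w <- as.vector(species$suitability$values)
  if (!is.null(bias)) {
    if (!same_grid(spec, bias$spec)) stop("bias surface on a different grid")
    w <- w * as.vector(bias$values)
  }
  w[is.na(w)] <- 0
  if (sum(w) <= 0) stop("suitability x bias vanishes everywhere")
  set.seed(as.integer(seed))
  cells <- sample.int(length(w), n, replace = TRUE, prob = w)
  row <- (cells - 1) %% spec$nrows + 1
  col <- (cells - 1) %/% spec$nrows + 1
  jx <- stats::runif(n, -0.499, 0.499) * spec$cellsize
  jy <- stats::runif(n, -0.499, 0.499) * spec$cellsize
  rec <- data.frame(lon = cell_lons(spec)[col] + jx,
                    lat = cell_lats(spec)[row] + jy,
                    year = sample(1960:2020, n, replace = TRUE),
                    source = "synthetic")
  out <- occurrence_set(label, rec)
  attr(out, "truth") <- species
  out
}

#' Two virtual species differing in stated niche optima
#'
#' Builds one climate stack, defines a reference species and a second species
#' whose optimum on each named driver is shifted by `offset_sd` standard
#' deviations of the reference species' realized values of that driver (the
#' pooled within-species spread), samples `n_per_species` presences for each,
#' and extracts their climate feature table.
#'
#' @param spec a [synthetic_climate_spec()].
#' @param offset_sd niche offset in within-species-sd units (0 gives
#'   identically distributed species).
#' @param n_per_species presences per species (default 200).
#' @param seed integer seed.
#' @param drivers driver variable(s) whose optimum is shifted
#'   (default `"bio1"`).
#' @param optima,tolerances reference-species niche (defaults as in
#'   [virtual_species()]).
#' @return list with `table` (feature table with `species` labels `spA`,
#'   `spB`), `truth` (offset variables and magnitudes), `stack`, and the two
#'   `virtual_species` objects.
#' @export
two_species_scenario <- function(spec = synthetic_climate_spec(),
                                 offset_sd = 2, n_per_species = 200,
                                 seed = 1L, drivers = "bio1",
                                 optima = c(bio1 = 12, bio12 = 500),
                                 tolerances = c(bio1 = 0.35, bio12 = 10)) {
  stopifnot(offset_sd >= 0)
  stack <- make_climate_stack(spec)
  spA <- virtual_species(stack, optima, tolerances)
  occA <- sample_presences(spA, n_per_species, seed = seed, label = "spA")
  refA <- extract_swd(stack, occA, "spA")
  optB <- optima
  offsets <- numeric(0)
  for (v in drivers) {
    s <- stats::sd(refA[[v]])
    optB[[v]] <- optB[[v]] + offset_sd * s
    offsets[v] <- offset_sd * s
  }
  spB <- virtual_species(stack, optB, tolerances)
  occB <- sample_presences(spB, n_per_species, seed = as.integer(seed) + 1,
                           label = "spB")
  swdB <- extract_swd(stack, occB, "spB")
  table <- rbind(as.data.frame(refA), as.data.frame(swdB))
  list(table = table,
       truth = list(offset_vars = drivers, offsets = offsets,
                    offset_sd = offset_sd),
       stack = stack, species = list(spA = spA, spB = spB))
}
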