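# Shared fixture builders.  Everything is generated in code; no stored data.

# tiny raster from a matrix (row 1 = north)
tiny_raster <- function(values, xll = 0, yll = 0, cellsize = 1) {
  values <- as.matrix(values)
  new_raster(grid_spec(ncol(values), nrow(values), xll, yll, cellsize),
             values)
}

# small named stack from matrices
tiny_stack <- function(..., xll = 0, yll = 0, cellsize = 1,
                       period = "current") {
  mats <- list(...)
  layer_stack(lapply(mats, tiny_raster, xll = xll, yll = yll,
                     cellsize = cellsize), period = period)
}

# an SWD-like table straight from a matrix of variable values
swd_from_matrix <- function(x, species = "sp") {
  x <- as.matrix(x)
  nm <- colnames(x)
  if (is.null(nm)) nm <- rep("", ncol(x))
  nm[nm == ""] <- paste0("v", which(nm == ""))
  colnames(x) <- nm
  out <- data.frame(species = species, lon = seq_len(nrow(x)),
                    lat = seq_len(nrow(x)))
  out <- cbind(out, as.data.frame(x))
  class(out) <- c("swd_table", "data.frame")
  out
}

# occurrence set from bare coordinates
occ_from_coords <- function(lon, lat, year = NA_integer_, species = "sp") {
  occurrence_set(species, data.frame(lon = lon, lat = lat, year = year))
}

# small default synthetic world: stack + virtual species + samples
small_world <- function(seed = 1, n_vars = 6, nx = 40, ny = 40,
                        n_pres = 120, n_bg = 600) {
  spc <- synthetic_climate_spec(grid = grid_spec(nx, ny, 10, 30, 0.25),
                                n_vars = n_vars, seed = seed)
  stack <- make_climate_stack(spc)
  vs <- virtual_species(stack, optima = c(bio1 = 12),
                        tolerances = c(bio1 = 0.35),
                        plateau = c(bio1 = 3.5))
  occ <- sample_presences(vs, n_pres, seed = seed + 1, label = "vsp")
  pres <- extract_swd(stack, occ, "vsp")
  bg_pts <- sample_background(uniform_bias_surface(stack$spec), n_bg,
                              seed = seed + 2)
  bg <- extract_swd(stack, bg_pts, "background")
  list(spec = spc, stack = stack, vs = vs, occ = occ, pres = pres, bg = bg)
}

# generic convex-optimizer oracle for the maxent objective: minimizes
# -[(1/m) sum_p eta - log sum_b exp(eta) - sum beta|lambda|] by L-BFGS-B on
# the split lambda = a - b, a, b >= 0 (independent of the package's FISTA
# path)
maxent_oracle <- function(Xp, Xb, beta, reltol = 1e-14) {
  p <- ncol(Xb)
  obj <- function(ab) {
    lam <- ab[1:p] - ab[(p + 1):(2 * p)]
    eta_b <- Xb %*% lam
    m <- max(eta_b)
    -(mean(Xp %*% lam) - (m + log(sum(exp(eta_b - m)))) -
        sum(beta * (ab[1:p] + ab[(p + 1):(2 * p)])))
  }
  gr <- function(ab) {
    lam <- ab[1:p] - ab[(p + 1):(2 * p)]
    eta_b <- as.vector(Xb %*% lam)
    w <- exp(eta_b - max(eta_b)); w <- w / sum(w)
    g <- as.vector(colMeans(Xp)) - as.vector(crossprod(Xb, w))
    c(-g + beta, g + beta)
  }
  fit <- stats::optim(rep(0, 2 * p), obj, gr, method = "L-BFGS-B",
                      lower = 0, control = list(maxit = 10000,
                                                factr = reltol / 1e-15))
  fit$par[1:p] - fit$par[(p + 1):(2 * p)]
}
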