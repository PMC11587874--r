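# MaxEnt-style feature expansion.  Variables are min-max scaled to [0,1] by
# their background range; feature classes:
#   L linear, Q quadratic, H hinge (forward + reverse), P pairwise product,
#   T threshold (step indicator).

#' Build a feature map from a background SWD table
#'
#' Records the per-variable background range (for `[0,1]` scaling), the hinge
#' and threshold knots (evenly spaced strictly inside `(0,1)`), and the list of
#' derived features for the requested classes.  Variables that are constant
#' over the background keep only their linear feature (with a warning).
#'
#' @param background background SWD table (see [extract_swd()]).
#' @param classes string such as `"LQH"` or character vector of single classes;
#'   subset of `L`, `Q`, `H`, `P`, `T`.
#' @param n_knots hinge/threshold knots per variable (default 50).
#' @return An object of class `feature_map`.
#' @export
build_feature_map <- function(background, classes = "LQ", n_knots = 50) {
  classes <- unique(strsplit(toupper(paste(classes, collapse = "")), "")[[1]])
  if (length(classes) == 0 || !all(classes %in% c("L", "Q", "H", "P", "T")))
    stop("classes must be a non-empty subset of L, Q, H, P, T")
  x <- swd_matrix(background)
  if (nrow(x) == 0) stop("empty background")
  vars <- colnames(x)
  vmin <- apply(x, 2, min); vmax <- apply(x, 2, max)
  const <- vmax - vmin <= 0
  if (any(const) && length(setdiff(classes, "L")))
    warning("constant variable(s) ", paste(vars[const], collapse = ", "),
            ": nonlinear features skipped")
  knots <- seq_len(n_knots) / (n_knots + 1)

  feats <- list()
  add <- function(class, name, var1, var2 = NA, knot = NA)
    feats[[length(feats) + 1]] <<- data.frame(
      class = class, name = name, var1 = var1, var2 = var2, knot = knot,
      stringsAsFactors = FALSE)
  if ("L" %in% classes)
    for (v in vars) add("L", paste0("l.", v), v)
  if ("Q" %in% classes)
    for (v in vars[!const]) add("Q", paste0("q.", v), v)
  if ("P" %in% classes && sum(!const) >= 2) {
    prs <- utils::combn(vars[!const], 2)
    for (j in seq_len(ncol(prs)))
      add("P", paste0("p.", prs[1, j], ".", prs[2, j]), prs[1, j], prs[2, j])
  }
  if ("H" %in% classes)
    for (v in vars[!const]) for (k in knots) {
      add("H", sprintf("hf.%s.%g", v, k), v, knot = k)
      add("H", sprintf("hr.%s.%g", v, k), v, knot = -k)  # negative = reverse
    }
  if ("T" %in% classes)
    for (v in vars[!const]) for (k in knots)
      add("T", sprintf("t.%s.%g", v, k), v, knot = k)
  feats <- do.call(rbind, feats)
  structure(list(vars = vars, vmin = vmin, vmax = vmax, classes = classes,
                 n_knots = n_knots, features = feats),
            class = "feature_map")
}

#' @export
print.feature_map <- function(x, ...) {
  cat(sprintf("feature_map: %d variables, classes %s, %d features\n",
              length(x$vars), paste(x$classes, collapse = ""),
              nrow(x$features)))
  invisible(x)
}

# Scale raw variables to [0,1] by the background range; clamp if requested.
scale_vars <- function(fm, x, clamp = TRUE) {
  x <- as.matrix(x[, fm$vars, drop = FALSE])
  rng <- fm$vmax - fm$vmin
  rng[rng <= 0] <- 1
  z <- sweep(sweep(x, 2, fm$vmin), 2, rng, "/")
  if (clamp) z <- pmin(pmax(z, 0), 1)
  z
}

#' Evaluate the feature design matrix
#'
#' @param fm a [build_feature_map()] object.
#' @param data SWD table or data.frame carrying the map's variables.
#' @param clamp clamp scaled values to the training `[0,1]` range before
#'   computing features (projection default).
#' @return numeric matrix, one column per derived feature.
#' @export
design_matrix <- function(fm, data, clamp = TRUE) {
  miss <- setdiff(fm$vars, colnames(data))
  if (length(miss))
    stop("missing variable(s): ", paste(miss, collapse = ", "))
  z <- scale_vars(fm, as.data.frame(data), clamp = clamp)
  f <- fm$features
  code <- c(L = 1L, Q = 2L, P = 3L, T = 4L)[f$class]
  code[f$class == "H"] <- ifelse(f$knot[f$class == "H"] > 0, 5L, 6L)
  out <- expand_features_cpp(z, code, match(f$var1, fm$vars),
                             ifelse(is.na(f$var2), 1L,
                                    match(f$var2, fm$vars)),
                             abs(ifelse(is.na(f$knot), 0, f$knot)))
  colnames(out) <- f$name
  out
}

# Feature matrix over a stack's complete (all-layers-present) cells, clamped
# to the training range.  Rows follow column-major cell order of the kept
# cells; used to renormalize raw predictions over the study grid.
stack_design <- function(fm, stack, clamp = TRUE) {
  vals <- vapply(stack$layers[fm$vars], function(l) as.vector(l$values),
                 numeric(stack$spec$nrows * stack$spec$ncols))
  ok <- stats::complete.cases(vals)
  design_matrix(fm, as.data.frame(vals[ok, , drop = FALSE]), clamp = clamp)
}

# Published Maxent default per-class base regularization, interpolated by the
# presence sample size m (flat extrapolation beyond the table ends).
maxent_base_beta <- function(class, m) {
  tab <- switch(class,
    L = list(x = c(0, 10, 30, 100), y = c(1, 1, 0.2, 0.05)),
    Q = list(x = c(0, 10, 17, 30, 100), y = c(1.3, 1.3, 0.8, 0.5, 0.25)),
    P = list(x = c(0, 10, 17, 30, 100), y = c(2.6, 2.6, 1.6, 1, 0.43)),
    T = list(x = c(0, 100), y = c(2, 1)),
    H = list(x = c(0, 1), y = c(0.5, 0.5)),
    stop("unknown feature class ", class))
  stats::approx(tab$x, tab$y, xout = m, rule = 2)$y
}
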