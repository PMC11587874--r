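# Penalized maximum-entropy presence-background model.
#
# The model is the Gibbs distribution over background cells
#   raw(x) = exp(eta(x) - logZ),   eta(x) = sum_j lambda_j f_j(x),
# with lambda maximizing
#   (1/m) sum_presence eta(x) - log sum_background exp(eta(x))
#       - sum_j beta_j |lambda_j|.
# The cloglog output is 1 - exp(-exp(H) * raw), H the entropy of the fitted
# raw distribution over the training background.

#' Fit a maximum-entropy presence-background model
#'
#' Solves the L1-penalized maxent objective by an accelerated proximal-gradient
#' method (tolerance `1e-7` on the relative objective change, iteration cap
#' 5000).  Per-feature penalties are
#' `beta_j = rm * base(class, m) * sd_j(presence features)` with the sd floored
#' at `1e-3`, where `base` follows the published Maxent default tables and `m`
#' is the presence count.
#'
#' @param presence presence SWD table (>= 2 rows).
#' @param background background SWD table.
#' @param feature_map a [build_feature_map()] object (built on the background).
#' @param rm regularization multiplier (Maxent beta-multiplier).
#' @param tol,maxit optimizer controls.
#' @param lambda0 optional warm-start coefficient vector.
#' @return An object of class `maxent_model`.
#' @export
fit_maxent <- function(presence, background, feature_map, rm = 1,
                       tol = 1e-7, maxit = 5000, lambda0 = NULL) {
  if (nrow(presence) < 2) stop("need at least 2 presence rows")
  Xp <- design_matrix(feature_map, presence, clamp = TRUE)
  Xb <- design_matrix(feature_map, background, clamp = FALSE)
  m <- nrow(Xp)
  base <- vapply(feature_map$features$class, maxent_base_beta,
                 numeric(1), m = m)
  s <- pmax(apply(Xp, 2, stats::sd), 1e-3)
  beta <- rm * base * s
  l0 <- if (is.null(lambda0)) numeric(0) else lambda0
  res <- maxent_fit_cpp(Xp, Xb, beta, tol = tol, maxit = maxit, lambda0 = l0)
  if (!res$converged && res$iterations >= maxit)
    stop(sprintf("maxent fit did not converge in %d iterations (objective %.6g)",
                 res$iterations, res$objective))
  structure(list(feature_map = feature_map,
                 lambda = stats::setNames(as.vector(res$lambda),
                                          feature_map$features$name),
                 beta = stats::setNames(beta, feature_map$features$name),
                 rm = rm, logZ = res$logZ, entropy = res$entropy,
                 n_presence = m, n_background = nrow(Xb),
                 objective = res$objective, iterations = res$iterations,
                 converged = res$converged),
            class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(
    "maxent_model: %d features (%d nonzero), rm = %g, H = %.4f, %d iterations\n",
    length(x$lambda), sum(x$lambda != 0), x$rm, x$entropy, x$iterations))
  invisible(x)
}

model_eta <- function(model, data, clamp = TRUE) {
  X <- design_matrix(model$feature_map, data, clamp = clamp)
  as.vector(X %*% model$lambda)
}

#' Raw (Gibbs) prediction
#'
#' `raw(x) = exp(eta(x) - logZ)`; raw values sum to 1 over the training
#' background.
#'
#' @param model a fitted [fit_maxent()] model.
#' @param data SWD table or data.frame with the model's variables.
#' @param clamp clamp features to the training range.
#' @return non-negative weights.
#' @export
predict_raw <- function(model, data, clamp = TRUE) {
  exp(model_eta(model, data, clamp = clamp) - model$logZ)
}

#' Cloglog prediction
#'
#' `cloglog(x) = 1 - exp(-exp(H) * raw(x))`, a value in (0,1) strictly
#' increasing in the raw output.  The all-zero-coefficient model yields
#' `1 - exp(-1)` everywhere.
#'
#' @inheritParams predict_raw
#' @export
predict_cloglog <- function(model, data, clamp = TRUE) {
  1 - exp(-exp(model$entropy) * predict_raw(model, data, clamp = clamp))
}

#' Project a model onto a layer stack
#'
#' Evaluates the cloglog output at every cell whose variables are all
#' non-missing.  With `clamp = TRUE` (Maxent's default), scaled feature values
#' outside the training `[0,1]` range are clamped to the boundary.
#'
#' @param model a fitted [fit_maxent()] model.
#' @param stack a [layer_stack()] providing all model variables.
#' @param clamp clamp to the training range (default `TRUE`).
#' @return An [new_raster()] of cloglog suitability.
#' @export
project_model <- function(model, stack, clamp = TRUE) {
  vars <- model$feature_map$vars
  miss <- setdiff(vars, names(stack$layers))
  if (length(miss))
    stop("stack is missing layer(s): ", paste(miss, collapse = ", "))
  vals <- vapply(stack$layers[vars], function(l) as.vector(l$values),
                 numeric(stack$spec$nrows * stack$spec$ncols))
  ok <- stats::complete.cases(vals)
  out <- rep(NA_real_, nrow(vals))
  if (any(ok)) {
    df <- as.data.frame(vals[ok, , drop = FALSE])
    out[ok] <- predict_cloglog(model, df, clamp = clamp)
  }
  new_raster(stack$spec, matrix(out, stack$spec$nrows, stack$spec$ncols))
}

#' Percent contribution and permutation importance per variable
#'
#' Percent contribution allocates `|lambda_j| * sd_j(background features)`
#' to each variable (product features split evenly between their two
#' variables) and normalizes to 100.  Permutation importance permutes one
#' variable's values across the pooled presence + background rows, measures
#' the drop in training AUC, and normalizes the (non-negative) drops to 100.
#'
#' @param model a fitted [fit_maxent()] model.
#' @param presence,background the training SWD tables.
#' @param seed seed for the permutation.
#' @param highlight flag threshold in percent (default 10).
#' @return data.frame with columns `variable`, `percent_contribution`,
#'   `permutation_importance`, `high` (either measure `>= highlight`).
#' @export
variable_importance <- function(model, presence, background, seed = 1L,
                                highlight = 10) {
  fm <- model$feature_map
  Xb <- design_matrix(fm, background, clamp = FALSE)
  w <- abs(model$lambda) * apply(Xb, 2, stats::sd)
  pc <- stats::setNames(numeric(length(fm$vars)), fm$vars)
  f <- fm$features
  for (j in seq_len(nrow(f))) {
    if (w[j] == 0) next
    if (!is.na(f$var2[j])) {
      pc[f$var1[j]] <- pc[f$var1[j]] + w[j] / 2
      pc[f$var2[j]] <- pc[f$var2[j]] + w[j] / 2
    } else pc[f$var1[j]] <- pc[f$var1[j]] + w[j]
  }
  pc <- if (sum(pc) > 0) 100 * pc / sum(pc) else pc

  sp <- predict_cloglog(model, presence)
  sb <- predict_cloglog(model, background)
  auc0 <- auc(sp, sb)
  pooled <- rbind(as.data.frame(presence)[, fm$vars, drop = FALSE],
                  as.data.frame(background)[, fm$vars, drop = FALSE])
  np <- nrow(presence)
  set.seed(as.integer(seed))
  drops <- vapply(fm$vars, function(v) {
    perm <- pooled
    perm[[v]] <- perm[[v]][sample.int(nrow(perm))]
    s <- predict_cloglog(model, perm)
    max(0, auc0 - auc(s[seq_len(np)], s[-seq_len(np)]))
  }, numeric(1))
  pi_ <- if (sum(drops) > 0) 100 * drops / sum(drops) else drops
  data.frame(variable = fm$vars, percent_contribution = as.vector(pc),
             permutation_importance = as.vector(pi_),
             high = as.vector(pc >= highlight | pi_ >= highlight))
}

#' Serialize / restore a fitted model as structured text (JSON)
#' @param model a `maxent_model`.
#' @param path file path.
#' @export
write_maxent_model <- function(model, path) {
  obj <- list(vars = model$feature_map$vars,
              vmin = model$feature_map$vmin, vmax = model$feature_map$vmax,
              classes = model$feature_map$classes,
              n_knots = model$feature_map$n_knots,
              features = model$feature_map$features,
              lambda = model$lambda, beta = model$beta, rm = model$rm,
              logZ = model$logZ, entropy = model$entropy,
              n_presence = model$n_presence,
              n_background = model$n_background)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_maxent_model
#' @export
read_maxent_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fm <- structure(list(vars = obj$vars,
                       vmin = stats::setNames(obj$vmin, obj$vars),
                       vmax = stats::setNames(obj$vmax, obj$vars),
                       classes = obj$classes, n_knots = obj$n_knots,
                       features = as.data.frame(obj$features)),
                  class = "feature_map")
  structure(list(feature_map = fm,
                 lambda = stats::setNames(obj$lambda, fm$features$name),
                 beta = stats::setNames(obj$beta, fm$features$name),
                 rm = obj$rm, logZ = obj$logZ, entropy = obj$entropy,
                 n_presence = obj$n_presence,
                 n_background = obj$n_background,
                 objective = NA_real_, iterations = NA_integer_,
                 converged = TRUE),
            class = "maxent_model")
}
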