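# Species-pair niche differentiation: PCA with broken-stick retention and
# ANOVA/Tukey on scores; exhaustive condition-number/VIF subset selection;
# cross-validated L2 logistic discrimination with linear Shapley attributions
# and partial dependence.

#' Principal component analysis of a climate feature table
#'
#' Eigendecomposition of the correlation (standardized, the default since bio
#' variables mix degrees C and mm) or covariance matrix, with a deterministic
#' sign convention: each component's largest-magnitude loading is positive.
#'
#' @param table a feature table: data.frame with a `species` column and one
#'   column per climatic variable (no missing values, >= 3 rows).
#' @param standardize use the correlation matrix (default `TRUE`).
#' @return list of class `pca_result`: `eigenvalues`, `proportions`,
#'   `loadings` (columns orthonormal), `scores`, `groups`, `retained`
#'   (broken-stick count), `broken_stick` expectations.
#' @export
pca_climate <- function(table, standardize = TRUE) {
  x <- as.matrix(table[, setdiff(colnames(table), c("species", "lon", "lat")),
                       drop = FALSE])
  if (nrow(x) < 3) stop("need at least 3 rows")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("constant column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  pc <- stats::prcomp(x, center = TRUE, scale. = standardize)
  ev <- pc$sdev^2
  # sign convention: largest-|loading| entry of each component positive
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  prop <- ev / sum(ev)
  bs <- broken_stick(length(ev))
  structure(list(eigenvalues = ev, proportions = prop,
                 loadings = pc$rotation, scores = pc$x,
                 groups = table$species,
                 broken_stick = bs,
                 retained = retain_components(prop, bs)),
            class = "pca_result")
}

#' Broken-stick expected eigenvalue proportions
#'
#' `b_k = (1/p) * sum_{i=k}^{p} 1/i`; the expectations sum to one.
#'
#' @param p number of components (>= 1).
#' @return numeric vector `b_1 ... b_p`.
#' @export
broken_stick <- function(p) {
  stopifnot(p >= 1)
  inv <- 1 / seq_len(p)
  rev(cumsum(rev(inv))) / p
}

#' Broken-stick retention rule
#'
#' Retains the leading run of components whose observed variance proportion
#' exceeds the broken-stick expectation.
#'
#' @param proportions observed variance proportions.
#' @param expectations broken-stick expectations (default computed).
#' @return retained component count `k` (possibly 0).
#' @export
retain_components <- function(proportions,
                              expectations = broken_stick(length(proportions))) {
  above <- proportions > expectations
  if (!above[1]) return(0L)
  k <- which(!above)
  if (length(k) == 0) length(proportions) else as.integer(k[1] - 1)
}

#' ANOVA and Tukey HSD on PCA scores
#'
#' One-way ANOVA of each retained component's scores on the group factor,
#' followed by Tukey honest-significant-difference pairwise comparisons
#' (studentized range distribution).  Pairs with `p < alpha` are flagged as
#' significantly different.
#'
#' @param scores matrix of component scores (columns = components).
#' @param groups group label per row (>= 2 groups, each >= 2 observations).
#' @param alpha significance level (default 0.001).
#' @return list with `anova` (per-component F and p) and `tukey`
#'   (per-component, per-pair difference, p, and significance flag).
#' @export
anova_tukey <- function(scores, groups, alpha = 0.001) {
  scores <- as.matrix(scores)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs >= 2 observations")
  an <- list(); tk <- list()
  for (j in seq_len(ncol(scores))) {
    comp <- colnames(scores)[j]
    if (is.null(comp)) comp <- paste0("PC", j)
    fit <- stats::aov(scores[, j] ~ groups)
    at <- stats::anova(fit)
    an[[j]] <- data.frame(component = comp, F = at$`F value`[1],
                          p = at$`Pr(>F)`[1],
                          significant = at$`Pr(>F)`[1] < alpha)
    th <- stats::TukeyHSD(fit)$groups
    tk[[j]] <- data.frame(component = comp, pair = rownames(th),
                          diff = th[, "diff"], p = th[, "p adj"],
                          significant = th[, "p adj"] < alpha,
                          row.names = NULL)
  }
  list(anova = do.call(rbind, an), tukey = do.call(rbind, tk))
}

#' Exhaustive condition-number / VIF subset selection
#'
#' For every subset size `s` in `1..p`, enumerates all size-`s` subsets of the
#' standardized variables and keeps the one with the smallest condition number
#' (ratio of extreme singular values of the standardized column matrix,
#' computed as `sqrt(eigen_max / eigen_min)` of the subset correlation
#' matrix).  The final subset is the largest size whose per-variable VIF
#' (diagonal of the inverse subset correlation matrix) all stay `<= vif_max`.
#'
#' @param table feature table (data.frame with `species` plus variables).
#' @param vif_max VIF ceiling (default 10).
#' @param max_p guard on the exhaustive enumeration (default 19).
#' @return list of class `subset_selection`: `per_size` (best subset, kappa
#'   and max VIF per size), `variables` (final subset), `vif` (final VIFs),
#'   `kappa` (final condition number).
#' @export
subset_select_condition_vif <- function(table, vif_max = 10, max_p = 19) {
  vars <- setdiff(colnames(table), c("species", "lon", "lat"))
  p <- length(vars)
  if (p > max_p) stop("exhaustive mode limited to ", max_p, " variables")
  x <- scale(as.matrix(table[, vars, drop = FALSE]))
  R <- stats::cor(x)
  per_size <- vector("list", p)
  for (s in seq_len(p)) {
    subs <- utils::combn(p, s)
    best_kappa <- Inf; best_idx <- NULL
    for (j in seq_len(ncol(subs))) {
      idx <- subs[, j]
      ev <- eigen(R[idx, idx, drop = FALSE], symmetric = TRUE,
                  only.values = TRUE)$values
      kap <- if (min(ev) <= 1e-12) Inf else sqrt(max(ev) / min(ev))
      if (kap < best_kappa) { best_kappa <- kap; best_idx <- idx }
    }
    if (is.null(best_idx)) next
    vif <- if (is.finite(best_kappa))
      diag(solve(R[best_idx, best_idx, drop = FALSE])) else rep(Inf, s)
    per_size[[s]] <- list(size = s, variables = vars[best_idx],
                          kappa = best_kappa, vif = vif)
  }
  sizes_ok <- vapply(per_size, function(e)
    !is.null(e) && is.finite(e$kappa) && all(e$vif <= vif_max), logical(1))
  if (!any(sizes_ok)) stop("no subset satisfies the VIF rule")
  final <- per_size[[max(which(sizes_ok))]]
  per_size_df <- do.call(rbind, lapply(per_size[!vapply(per_size, is.null,
                                                        logical(1))],
    function(e) data.frame(size = e$size,
                           variables = paste(e$variables, collapse = "+"),
                           kappa = e$kappa, max_vif = max(e$vif))))
  structure(list(per_size = per_size_df, variables = final$variables,
                 vif = stats::setNames(final$vif, final$variables),
                 kappa = final$kappa),
            class = "subset_selection")
}

#' Stratified train/test split
#'
#' @param table feature table with a `species` column (>= 10 rows).
#' @param train_frac training fraction (default 0.8).
#' @param seed integer seed.
#' @return list with `train` and `test` data.frames; group proportions are
#'   preserved within one observation per group.
#' @export
split_train_test <- function(table, train_frac = 0.8, seed = 1L) {
  if (nrow(table) < 10) stop("need at least 10 rows")
  set.seed(as.integer(seed))
  idx_train <- integer(0)
  for (g in unique(table$species)) {
    rows <- which(table$species == g)
    n_tr <- round(train_frac * length(rows))
    if (n_tr == 0 || n_tr == length(rows))
      stop("group '", g, "' would be absent from one split")
    idx_train <- c(idx_train, sample(rows, n_tr))
  }
  idx_train <- sort(idx_train)
  list(train = table[idx_train, , drop = FALSE],
       test = table[-idx_train, , drop = FALSE])
}

logistic_nll <- function(theta, X, y, lambda_pen) {
  eta <- theta[1] + X %*% theta[-1]
  # mean log-loss, numerically stable
  nll <- mean((1 - y) * eta + log1p(exp(-eta)))
  nll + lambda_pen * sum(theta[-1]^2)
}

logistic_grad <- function(theta, X, y, lambda_pen) {
  eta <- as.vector(theta[1] + X %*% theta[-1])
  p <- 1 / (1 + exp(-eta))
  r <- p - y
  c(mean(r), as.vector(crossprod(X, r)) / nrow(X) + 2 * lambda_pen * theta[-1])
}

fit_ridge_logistic <- function(X, y, lambda_pen) {
  theta0 <- numeric(ncol(X) + 1)
  opt <- stats::optim(theta0, logistic_nll, logistic_grad, X = X, y = y,
                      lambda_pen = lambda_pen, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-12))
  list(intercept = opt$par[1], coef = opt$par[-1], value = opt$value)
}

#' Cross-validated L2 logistic discrimination of a species pair
#'
#' Standardizes the features on the training data only, scans a grid of L2
#' penalty strengths by 5-fold cross-validated ROC-AUC, and refits the best
#' penalty on the full training set, minimizing
#' `mean log-loss + lambda_pen * ||coefficients||^2` (intercept unpenalized)
#' by a deterministic quasi-Newton optimization.  The positive class is the
#' second species of the declared pair.
#'
#' @param train training feature table (data.frame with `species` plus
#'   variables).
#' @param pair character vector of the two species labels, in order; the
#'   second is the positive class.  Defaults to the sorted unique labels.
#' @param grid penalty grid (default 100 values from 0.001 to 0.5, linearly
#'   spaced).
#' @param folds CV folds (default 5).
#' @param seed integer seed for the fold assignment.
#' @return list of class `discrimination_model` with the standardization
#'   parameters, chosen penalty, intercept/coefficients, and the CV table.
#' @export
fit_l2_logistic_cv <- function(train, pair = NULL,
                               grid = seq(0.001, 0.5, length.out = 100),
                               folds = 5, seed = 1L) {
  if (is.null(pair)) pair <- sort(unique(train$species))
  stopifnot(length(pair) == 2)
  vars <- setdiff(colnames(train), c("species", "lon", "lat"))
  y <- as.numeric(train$species == pair[2])
  if (length(unique(y)) < 2) stop("training data contains a single class")
  X <- as.matrix(train[, vars, drop = FALSE])
  center <- colMeans(X); scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Z <- scale(X, center = center, scale = scl)
  set.seed(as.integer(seed))
  fold <- sample(rep(seq_len(folds), length.out = nrow(Z)))
  cv_auc <- vapply(grid, function(lp) {
    aucs <- vapply(seq_len(folds), function(f) {
      tr <- fold != f
      if (length(unique(y[!tr])) < 2 || length(unique(y[tr])) < 2)
        return(NA_real_)
      fit <- fit_ridge_logistic(Z[tr, , drop = FALSE], y[tr], lp)
      eta <- fit$intercept + Z[!tr, , drop = FALSE] %*% fit$coef
      auc(eta[y[!tr] == 1], eta[y[!tr] == 0])
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }, numeric(1))
  best <- which.max(cv_auc)
  fit <- fit_ridge_logistic(Z, y, grid[best])
  structure(list(pair = pair, variables = vars, center = center, scale = scl,
                 lambda_pen = grid[best], intercept = fit$intercept,
                 coef = stats::setNames(fit$coef, vars),
                 cv = data.frame(lambda_pen = grid, cv_auc = cv_auc)),
            class = "discrimination_model")
}

#' @export
print.discrimination_model <- function(x, ...) {
  cat(sprintf("discrimination_model %s vs %s: %d variables, L2 penalty %.4g\n",
              x$pair[1], x$pair[2], length(x$coef), x$lambda_pen))
  invisible(x)
}

predict_logistic <- function(model, data, type = c("prob", "link")) {
  type <- match.arg(type)
  Z <- scale(as.matrix(data[, model$variables, drop = FALSE]),
             center = model$center, scale = model$scale)
  eta <- as.vector(model$intercept + Z %*% model$coef)
  if (type == "link") eta else 1 / (1 + exp(-eta))
}

#' Test-set classification metrics
#'
#' ROC-AUC plus precision, recall and F1 at the 0.5 probability cutoff, with
#' the pair's second species as the positive class.
#'
#' @param model a [fit_l2_logistic_cv()] model.
#' @param test test feature table with both classes present.
#' @return data.frame with `roc_auc`, `precision`, `recall`, `f1`.
#' @export
classification_metrics <- function(model, test) {
  y <- as.numeric(test$species == model$pair[2])
  p <- predict_logistic(model, test)
  roc <- if (length(unique(y)) < 2) NA_real_ else auc(p[y == 1], p[y == 0])
  pred <- as.numeric(p >= 0.5)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  data.frame(roc_auc = roc, precision = precision, recall = recall, f1 = f1)
}

#' Linear Shapley attributions
#'
#' For a linear model with the reference at the training feature means, the
#' Shapley value of variable `j` for observation `i` is exactly
#' `phi_ij = coef_j * (z_ij - z_ref_j)` on the linear-predictor scale, and
#' `sum_j phi_ij + base = eta_i` (local accuracy).
#'
#' @param model a [fit_l2_logistic_cv()] model.
#' @param data feature table to explain.
#' @return list with `phi` (observations x variables), `base` (prediction at
#'   the reference on the link scale).
#' @export
linear_shap <- function(model, data) {
  miss <- setdiff(model$variables, colnames(data))
  if (length(miss)) stop("unknown variable(s): ", paste(miss, collapse = ", "))
  Z <- scale(as.matrix(data[, model$variables, drop = FALSE]),
             center = model$center, scale = model$scale)
  phi <- sweep(Z, 2, model$coef, "*")
  list(phi = phi, base = model$intercept)
}

#' Partial dependence of the predicted probability on one variable
#'
#' @param model a [fit_l2_logistic_cv()] model.
#' @param data feature table over which to average.
#' @param variable variable name.
#' @param grid values (raw scale) at which to evaluate; defaults to 25
#'   quantile-spanning points.
#' @return data.frame with `value` and mean predicted probability `pd`.
#' @export
partial_dependence <- function(model, data, variable, grid = NULL) {
  if (!variable %in% model$variables) stop("unknown variable: ", variable)
  if (is.null(grid))
    grid <- seq(min(data[[variable]]), max(data[[variable]]),
                length.out = 25)
  pd <- vapply(grid, function(v) {
    d <- data
    d[[variable]] <- v
    mean(predict_logistic(model, d))
  }, numeric(1))
  data.frame(value = grid, pd = pd)
}
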