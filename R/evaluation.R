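# Replicate-based model evaluation (AUC, omission, partial ROC), maxSSS
# thresholding, AICc, and the tuning / variable-selection loops.

#' Bootstrap replicate splits
#'
#' Per replicate, a random `test_frac` of the records is held out for testing
#' and the remaining records are resampled with replacement to their own size
#' (bootstrap training set).
#'
#' @param occ data.frame of presence records or SWD rows (>= 8 rows).
#' @param n_rep number of replicates (default 10).
#' @param test_frac held-out test fraction (default 0.25).
#' @param seed integer seed; splits are reproducible.
#' @return list of `n_rep` lists with integer `train` (bootstrap, with
#'   repeats) and `test` row indices.
#' @export
make_replicates <- function(occ, n_rep = 10, test_frac = 0.25, seed = 1L) {
  n <- nrow(occ)
  if (n < 8) stop("need at least 8 records for replicate evaluation")
  set.seed(as.integer(seed))
  lapply(seq_len(n_rep), function(r) {
    test <- sort(sample.int(n, max(1, round(test_frac * n))))
    pool <- setdiff(seq_len(n), test)
    train <- sort(sample(pool, length(pool), replace = TRUE))
    list(replicate = r, train = train, test = test)
  })
}

#' Rank-based AUC (Mann-Whitney with midranks)
#'
#' @param presence_scores,background_scores numeric score vectors.
#' @return AUC in `[0, 1]`; 0.5 when all scores tie.
#' @export
auc <- function(presence_scores, background_scores) {
  m <- length(presence_scores); n <- length(background_scores)
  stopifnot(m > 0, n > 0)
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

#' Maximum sensitivity-plus-specificity threshold
#'
#' Scans the union of observed presence and background scores as candidate
#' thresholds and returns the one maximizing
#' `sens(t) + spec(t) = P(presence >= t) + P(background < t)`;
#' ties are broken toward the smallest threshold.
#'
#' @param presence_scores training-presence scores.
#' @param background_scores background scores.
#' @return the threshold (on the scale of the scores).
#' @export
max_sss_threshold <- function(presence_scores, background_scores) {
  stopifnot(length(presence_scores) > 0, length(background_scores) > 0)
  cand <- sort(unique(c(presence_scores, background_scores)))
  sp <- sort(presence_scores); sb <- sort(background_scores)
  sens <- 1 - findInterval(cand, sp, left.open = TRUE) / length(sp)
  spec <- findInterval(cand, sb, left.open = TRUE) / length(sb)
  tot <- sens + spec
  # ties (within floating-point noise) break toward the smallest threshold
  cand[which(tot >= max(tot) - 1e-9)[1]]
}

#' Test omission rate at a threshold
#'
#' @param test_presence_scores held-out presence scores.
#' @param t threshold.
#' @param overfit_cutoff omission above which the model is flagged as likely
#'   overfitted (default 0.1).
#' @return list with `rate` (fraction of test presences scoring below `t`)
#'   and `overfit` flag.
#' @export
omission_rate <- function(test_presence_scores, t, overfit_cutoff = 0.1) {
  stopifnot(length(test_presence_scores) > 0)
  rate <- mean(test_presence_scores < t)
  list(rate = rate, overfit = rate > overfit_cutoff)
}

#' Partial ROC test
#'
#' Bootstrap AUC-ratio test restricted to the high-sensitivity region
#' (omission `<= E`).  Per iteration a fraction of the test presences is
#' resampled with replacement; the partial AUC of the sensitivity-vs-
#' proportion-of-area curve is divided by the partial AUC of the chance
#' diagonal over the same region.  The p-value is the proportion of iterations
#' with ratio `<= 1`.
#'
#' @param test_presence_scores held-out presence scores (>= 10 recommended).
#' @param background_scores background scores.
#' @param E acceptable omission (default 0.05).
#' @param iterations bootstrap iterations (default 500).
#' @param resample_frac fraction of presences resampled per iteration.
#' @param seed integer seed.
#' @return list with `mean_ratio`, `p_value`, and the per-iteration `ratios`
#'   (`NA` when the curve is degenerate, e.g. all scores equal).
#' @export
partial_roc <- function(test_presence_scores, background_scores, E = 0.05,
                        iterations = 500, resample_frac = 0.5, seed = 1L) {
  sb <- sort(background_scores)
  nb <- length(sb)
  thr <- c(-Inf, sort(unique(c(test_presence_scores, background_scores))))
  area <- 1 - findInterval(thr, sb, left.open = TRUE) / nb  # P(bg >= t)
  np <- length(test_presence_scores)
  k <- max(2, ceiling(resample_frac * np))
  set.seed(as.integer(seed))
  ratios <- vapply(seq_len(iterations), function(it) {
    ps <- sort(sample(test_presence_scores, k, replace = TRUE))
    sens <- 1 - findInterval(thr, ps, left.open = TRUE) / k
    keep <- (1 - sens) <= E
    a <- area[keep]; s <- sens[keep]
    o <- order(a)
    a <- a[o]; s <- s[o]
    da <- diff(a)
    if (length(a) < 2 || sum(da) <= 0) return(NA_real_)
    pauc_model <- sum((s[-1] + s[-length(s)]) / 2 * da)
    pauc_null <- sum((a[-1] + a[-length(a)]) / 2 * da)
    if (pauc_null <= 0) return(NA_real_)
    pauc_model / pauc_null
  }, numeric(1))
  ok <- ratios[!is.na(ratios)]
  list(mean_ratio = if (length(ok)) mean(ok) else NA_real_,
       p_value = if (length(ok)) mean(ok <= 1) else NA_real_,
       ratios = ratios)
}

#' Small-sample corrected AIC for a maxent model
#'
#' Raw predictions are renormalized to sum to one over the (cropped) study
#' grid; the log-likelihood is the sum of log normalized raw values at the
#' occurrence cells; `k` is the number of nonzero coefficients.
#' `AICc = 2k - 2 lnL + 2k(k+1)/(n-k-1)`, invalid when `k >= n - 1`.
#'
#' @param model a fitted [fit_maxent()] model.
#' @param occurrences presence SWD table (one row per occurrence).
#' @param stack the study-area [layer_stack()].
#' @param grid_design optional precomputed grid feature matrix (from
#'   `design_matrix()` on the stack's complete cells) to avoid rebuilding it
#'   across multipliers during tuning.
#' @return list with `aicc`, `k`, `n`, `lnL`, `valid`.
#' @export
aicc <- function(model, occurrences, stack, grid_design = NULL) {
  k <- sum(model$lambda != 0)
  n <- nrow(occurrences)
  if (is.null(grid_design))
    grid_design <- stack_design(model$feature_map, stack)
  eta_grid <- as.vector(grid_design %*% model$lambda)
  eta_occ <- model_eta(model, occurrences, clamp = TRUE)
  mx <- max(eta_grid)
  logS <- mx + log(sum(exp(eta_grid - mx)))
  lnL <- sum(eta_occ - logS)
  if (k >= n - 1)
    return(list(aicc = NA_real_, k = k, n = n, lnL = lnL, valid = FALSE))
  list(aicc = 2 * k - 2 * lnL + 2 * k * (k + 1) / (n - k - 1),
       k = k, n = n, lnL = lnL, valid = TRUE)
}

#' AICc tuning over feature classes and regularization multipliers
#'
#' Fits every (feature-class set, multiplier) combination on the full presence
#' and background SWD tables, computes AICc over the study grid, and marks the
#' best (minimum-AICc) valid combination per class set and overall.  Within a
#' class set the fits are warm-started across multipliers.
#'
#' @param presence,background SWD tables.
#' @param stack study-area [layer_stack()] for the AICc normalization.
#' @param class_sets character vector of feature-class combinations
#'   (default the six sets `L`, `LQ`, `LQH`, `H`, `LQHP`, `LQHPT`).
#' @param rm_range multipliers to scan (default `1:6`).
#' @param n_knots hinge/threshold knots per variable.
#' @return list of class `tuning_result`: `results` (one row per combination:
#'   `class_set`, `rm`, `aicc`, `k`, `valid`, `best_in_class`, `best`),
#'   `best` (list with `class_set`, `rm`), and `best_model`.
#' @export
tune <- function(presence, background, stack,
                 class_sets = c("L", "LQ", "LQH", "H", "LQHP", "LQHPT"),
                 rm_range = 1:6, n_knots = 50) {
  rows <- list()
  best <- NULL
  best_model <- NULL
  for (cs in class_sets) {
    fm <- build_feature_map(background, cs, n_knots = n_knots)
    gd <- stack_design(fm, stack)
    warm <- NULL
    for (rm in rm_range) {
      model <- fit_maxent(presence, background, fm, rm = rm, lambda0 = warm)
      warm <- unname(model$lambda)
      ic <- aicc(model, presence, stack, grid_design = gd)
      rows[[length(rows) + 1]] <- data.frame(
        class_set = cs, rm = rm, aicc = ic$aicc, k = ic$k, valid = ic$valid)
      if (ic$valid && (is.null(best) || ic$aicc < best$aicc)) {
        best <- list(class_set = cs, rm = rm, aicc = ic$aicc)
        best_model <- model
      }
    }
  }
  res <- do.call(rbind, rows)
  if (is.null(best)) stop("no valid (class set, rm) combination (all k >= n - 1)")
  bic <- stats::aggregate(aicc ~ class_set, data = res[res$valid, ], FUN = min)
  res$best_in_class <- res$valid &
    res$aicc == bic$aicc[match(res$class_set, bic$class_set)]
  res$best <- res$valid & res$class_set == best$class_set & res$rm == best$rm
  structure(list(results = res, best = best, best_model = best_model),
            class = "tuning_result")
}

#' @export
print.tuning_result <- function(x, ...) {
  cat(sprintf("tuning_result: %d combinations; best %s, rm = %g (AICc %.2f)\n",
              nrow(x$results), x$best$class_set, x$best$rm, x$best$aicc))
  invisible(x)
}

subset_swd <- function(swd, vars) {
  out <- swd[, c("species", "lon", "lat", vars), drop = FALSE]
  class(out) <- class(swd)
  out
}

#' Iterative contribution/correlation variable selection
#'
#' At each pass a model is fitted on the current variable subset (LQ features,
#' `rm = 1`), variables with percent contribution below `contribution_min` are
#' dropped, and for every background-correlation pair with
#' `|r| > correlation_max` the lower-contribution member is dropped; the loop
#' runs to a fixed point and the AICc tuning is then rerun on the retained
#' subset.
#'
#' @param presence,background SWD tables.
#' @param stack study-area [layer_stack()].
#' @param contribution_min minimum percent contribution (default 1).
#' @param correlation_max correlation cutoff (default 0.9).
#' @param class_sets,rm_range,n_knots passed to [tune()] for the final tuning.
#' @return list with `variables` (retained subset), `trace` (data.frame of
#'   eliminations), and `tuning` (the [tune()] result on the retained set).
#' @export
select_variables <- function(presence, background, stack,
                             contribution_min = 1, correlation_max = 0.9,
                             class_sets = c("L", "LQ", "LQH", "H", "LQHP",
                                            "LQHPT"),
                             rm_range = 1:6, n_knots = 50) {
  vars <- swd_vars(presence)
  if (length(vars) < 2) stop("need at least 2 variables")
  trace <- list()
  repeat {
    p <- subset_swd(presence, vars)
    b <- subset_swd(background, vars)
    fm <- build_feature_map(b, "LQ", n_knots = n_knots)
    model <- fit_maxent(p, b, fm, rm = 1)
    imp <- variable_importance(model, p, b)
    contrib <- stats::setNames(imp$percent_contribution, imp$variable)
    drop <- character(0)
    low <- names(contrib)[contrib < contribution_min]
    if (length(low) && length(low) < length(vars)) drop <- low
    cm <- correlation_matrix(b, threshold = correlation_max)
    if (nrow(cm$flagged)) {
      for (j in seq_len(nrow(cm$flagged))) {
        v1 <- cm$flagged$var1[j]; v2 <- cm$flagged$var2[j]
        if (abs(cm$flagged$r[j]) <= correlation_max) next
        loser <- if (contrib[v1] >= contrib[v2]) v2 else v1
        drop <- union(drop, loser)
      }
    }
    drop <- intersect(drop, vars)
    if (length(drop) >= length(vars))
      drop <- setdiff(drop, names(which.max(contrib)))
    if (length(drop) == 0) break
    trace[[length(trace) + 1]] <- data.frame(
      variable = drop, contribution = unname(contrib[drop]))
    vars <- setdiff(vars, drop)
    if (length(vars) < 2) break
  }
  if (length(vars) == 0)
    stop("all variables eliminated; trace: ",
         paste(unlist(lapply(trace, `[[`, "variable")), collapse = ", "))
  tuning <- tune(subset_swd(presence, vars), subset_swd(background, vars),
                 stack, class_sets = class_sets, rm_range = rm_range,
                 n_knots = n_knots)
  list(variables = vars,
       trace = if (length(trace)) do.call(rbind, trace)
               else data.frame(variable = character(0),
                               contribution = numeric(0)),
       tuning = tuning)
}

#' Replicate evaluation of one candidate configuration
#'
#' Runs the bootstrap replicates: per replicate the model is fitted on the
#' bootstrap training presences, scored on training and held-out test
#' presences and on the background, the maxSSS threshold is taken from the
#' training presences, and the test omission rate and partial ROC are
#' computed.
#'
#' @param presence,background SWD tables.
#' @param class_set feature-class combination (e.g. `"LQ"`).
#' @param rm regularization multiplier.
#' @param n_rep,test_frac replicate settings (defaults 10 and 0.25).
#' @param seed integer seed driving splits and the partial ROC resampling.
#' @param n_knots hinge/threshold knots.
#' @param partial_roc_E,partial_roc_iter partial ROC settings.
#' @return list of class `eval_report` with `replicates` (per-replicate
#'   data.frame), `summary` (replicate means), and the configuration.
#' @export
evaluate_candidate <- function(presence, background, class_set = "LQ", rm = 1,
                               n_rep = 10, test_frac = 0.25, seed = 1L,
                               n_knots = 50, partial_roc_E = 0.05,
                               partial_roc_iter = 500) {
  fm <- build_feature_map(background, class_set, n_knots = n_knots)
  splits <- make_replicates(presence, n_rep = n_rep, test_frac = test_frac,
                            seed = seed)
  rows <- lapply(splits, function(sp) {
    tr <- presence[sp$train, , drop = FALSE]
    te <- presence[sp$test, , drop = FALSE]
    model <- fit_maxent(tr, background, fm, rm = rm)
    s_tr <- predict_cloglog(model, tr)
    s_te <- predict_cloglog(model, te)
    s_bg <- predict_cloglog(model, background)
    t_sss <- max_sss_threshold(s_tr, s_bg)
    om <- omission_rate(s_te, t_sss)
    pr <- partial_roc(s_te, s_bg, E = partial_roc_E,
                      iterations = partial_roc_iter,
                      seed = as.integer(seed) + sp$replicate)
    data.frame(replicate = sp$replicate,
               train_auc = auc(s_tr, s_bg), test_auc = auc(s_te, s_bg),
               threshold = t_sss, omission = om$rate, overfit = om$overfit,
               proc_ratio = pr$mean_ratio, proc_p = pr$p_value)
  })
  reps <- do.call(rbind, rows)
  summary <- data.frame(
    class_set = class_set, rm = rm,
    mean_train_auc = mean(reps$train_auc),
    mean_test_auc = mean(reps$test_auc),
    mean_auc_diff = mean(abs(reps$train_auc - reps$test_auc)),
    mean_omission = mean(reps$omission),
    mean_threshold = mean(reps$threshold),
    mean_proc_ratio = mean(reps$proc_ratio, na.rm = TRUE),
    overfit = mean(reps$omission) > 0.1)
  structure(list(class_set = class_set, rm = rm, replicates = reps,
                 summary = summary), class = "eval_report")
}

#' Choose among evaluated candidates
#'
#' Lexicographic rule prioritizing low omission: lowest mean test omission,
#' then smallest mean |train - test| AUC difference, then highest mean test
#' AUC; remaining ties resolve to the first candidate in input order.
#'
#' @param reports list of [evaluate_candidate()] reports.
#' @return list with `index` of the chosen candidate and `report`.
#' @export
choose_model <- function(reports) {
  stopifnot(length(reports) >= 1)
  s <- do.call(rbind, lapply(reports, `[[`, "summary"))
  ord <- order(s$mean_omission, s$mean_auc_diff, -s$mean_test_auc)
  list(index = ord[1], report = reports[[ord[1]]], summary = s)
}
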