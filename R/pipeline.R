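# Orchestration of the two analysis tracks: per-species niche modeling with
# area dynamics, and multi-species niche differentiation.

#' Run the niche-modeling track for one or more species
#'
#' Per species: spatial thinning, kernel-density bias surface, biased
#' background sample, AICc tuning over feature classes and multipliers
#' (optionally preceded by contribution/correlation variable selection),
#' replicate evaluation of the per-class-set AICc-best candidates,
#' omission-prioritized model choice, replicate-averaged projection onto every
#' period stack, maxSSS thresholding, regional area series, and climatic
#' variable ranges.
#'
#' @param occurrences named list of [occurrence_set()] objects (one per
#'   species).
#' @param stacks named list of [layer_stack()] per period label; must contain
#'   `config$train_period` (default `"current"`), the stack models are
#'   trained on.
#' @param config list of settings; any of `thin_km` (50), `background_n`
#'   (10000), `class_sets`, `rm_range` (1:6), `n_knots` (50), `n_rep` (10),
#'   `test_frac` (0.25), `select_variables` (FALSE), `contribution_min` (1),
#'   `correlation_max` (0.9), `partial_roc_E` (0.05), `partial_roc_iter`
#'   (500), `meridian` (60), `polar_lat` (66.562), `train_period`
#'   (`"current"`), `seed` (1).
#' @return list of class `enm_run` with one entry per species (thinned
#'   records, tuning, evaluation reports, chosen configuration, per-period
#'   suitability rasters and thresholds, variable ranges) plus the combined
#'   [area_series()] table.
#' @export
run_enm <- function(occurrences, stacks, config = list()) {
  cf <- function(key, default)
    if (!is.null(config[[key]])) config[[key]] else default
  thin_km <- cf("thin_km", 50)
  background_n <- cf("background_n", 10000)
  class_sets <- cf("class_sets", c("L", "LQ", "LQH", "H", "LQHP", "LQHPT"))
  rm_range <- cf("rm_range", 1:6)
  n_knots <- cf("n_knots", 50)
  n_rep <- cf("n_rep", 10)
  test_frac <- cf("test_frac", 0.25)
  train_period <- cf("train_period", "current")
  seed <- as.integer(cf("seed", 1L))
  meridian <- cf("meridian", 60)
  polar_lat <- cf("polar_lat", 66.562)
  if (!train_period %in% names(stacks))
    stop("stacks must include the training period '", train_period, "'")
  train_stack <- stacks[[train_period]]
  mask <- train_stack$layers[[1]]

  per_species <- list()
  runs <- list()
  for (sp in names(occurrences)) {
    occ <- thin(occurrences[[sp]], min_distance_km = thin_km)
    message(sprintf("[%s] %d records after thinning at %g km", sp, nrow(occ),
                    thin_km))
    bias <- kde_bias_surface(occ, train_stack$spec, mask = mask)
    bg_pts <- sample_background(bias, n = background_n, seed = seed)
    bg <- extract_swd(train_stack, bg_pts, "background")
    pres <- extract_swd(train_stack, occ, sp)

    if (isTRUE(cf("select_variables", FALSE))) {
      sel <- select_variables(pres, bg, train_stack,
                              contribution_min = cf("contribution_min", 1),
                              correlation_max = cf("correlation_max", 0.9),
                              class_sets = class_sets, rm_range = rm_range,
                              n_knots = n_knots)
      vars <- sel$variables
      pres <- subset_swd(pres, vars)
      bg <- subset_swd(bg, vars)
      tuning <- sel$tuning
    } else {
      sel <- NULL
      tuning <- tune(pres, bg, train_stack, class_sets = class_sets,
                     rm_range = rm_range, n_knots = n_knots)
    }

    # evaluate the AICc-best multiplier of each class set, prioritize omission
    cand <- tuning$results[tuning$results$best_in_class, , drop = FALSE]
    cand <- cand[!duplicated(cand$class_set), , drop = FALSE]
    reports <- lapply(seq_len(nrow(cand)), function(i)
      evaluate_candidate(pres, bg, cand$class_set[i], cand$rm[i],
                         n_rep = n_rep, test_frac = test_frac, seed = seed,
                         n_knots = n_knots,
                         partial_roc_E = cf("partial_roc_E", 0.05),
                         partial_roc_iter = cf("partial_roc_iter", 500)))
    chosen <- choose_model(reports)
    cls <- chosen$report$class_set
    rm_ <- chosen$report$rm
    t_sss <- chosen$report$summary$mean_threshold

    # replicate-averaged projections under the chosen configuration
    fm <- build_feature_map(bg, cls, n_knots = n_knots)
    splits <- make_replicates(pres, n_rep = n_rep, test_frac = test_frac,
                              seed = seed)
    models <- lapply(splits, function(spl)
      fit_maxent(pres[spl$train, , drop = FALSE], bg, fm, rm = rm_))
    projections <- lapply(stacks, function(stk)
      average_suitability(lapply(models, project_model, stack = stk)))
    ranges <- variable_ranges(threshold_map(projections[[train_period]],
                                            t_sss), train_stack)
    per_species[[sp]] <- list(
      occurrences = occ, bias = bias, selection = sel, tuning = tuning,
      reports = reports, chosen = chosen$report$summary,
      threshold = t_sss, projections = projections, ranges = ranges)
    runs[[sp]] <- list(species = sp, model = projections, stacks = stacks,
                       t = t_sss)
  }
  areas <- area_series(runs, meridian = meridian, polar_lat = polar_lat)
  structure(list(species = per_species, areas = areas, config = config),
            class = "enm_run")
}

#' Run the niche-differentiation track
#'
#' Full-dataset PCA with broken-stick retention and ANOVA/Tukey on the
#' retained components, then per species pair: pair PCA, exhaustive
#' condition-number/VIF variable selection, stratified 80/20 split,
#' 5-fold-CV L2 logistic discrimination, test metrics, and linear Shapley
#' attributions.
#'
#' @param table combined feature table: data.frame with `species` (>= 2
#'   labels) plus climatic variable columns.
#' @param config list of settings; any of `train_frac` (0.8), `folds` (5),
#'   `grid` (100 penalties in `[0.001, 0.5]`), `vif_max` (10), `alpha`
#'   (0.001), `seed` (1).
#' @return list of class `differentiation_run` with `pca`, `tests`
#'   (ANOVA/Tukey), and `pairs` (per-pair selection, model, metrics, shap).
#' @export
run_differentiation <- function(table, config = list()) {
  cf <- function(key, default)
    if (!is.null(config[[key]])) config[[key]] else default
  seed <- as.integer(cf("seed", 1L))
  species <- sort(unique(table$species))
  if (length(species) < 2) stop("need at least 2 species")

  full_pca <- pca_climate(table)
  k <- max(1L, full_pca$retained)
  tests <- anova_tukey(full_pca$scores[, seq_len(k), drop = FALSE],
                       full_pca$groups, alpha = cf("alpha", 0.001))

  pairs <- utils::combn(species, 2, simplify = FALSE)
  pair_out <- lapply(pairs, function(pr) {
    sub <- table[table$species %in% pr, , drop = FALSE]
    pair_pca <- pca_climate(sub)
    sel <- subset_select_condition_vif(sub, vif_max = cf("vif_max", 10))
    keep <- c("species", sel$variables)
    split <- split_train_test(sub[, keep, drop = FALSE],
                              train_frac = cf("train_frac", 0.8),
                              seed = seed)
    model <- fit_l2_logistic_cv(split$train, pair = pr,
                                grid = cf("grid",
                                          seq(0.001, 0.5, length.out = 100)),
                                folds = cf("folds", 5), seed = seed)
    metrics <- classification_metrics(model, split$test)
    shap <- linear_shap(model, split$test)
    list(pair = pr, pca = pair_pca, selection = sel, model = model,
         metrics = metrics, shap = shap)
  })
  names(pair_out) <- vapply(pairs, paste, character(1), collapse = "-")
  structure(list(pca = full_pca, tests = tests, pairs = pair_out),
            class = "differentiation_run")
}
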