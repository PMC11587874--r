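test_that("bootstrap replicates hold out 25% and are seed-reproducible", {
  occ <- data.frame(x = 1:100)
  reps <- make_replicates(occ, seed = 4)
  expect_length(reps, 10)
  for (r in reps) {
    expect_length(r$test, 25)
    expect_length(r$train, 75)                      # resampled to pool size
    expect_true(length(intersect(r$test, r$train)) == 0)
    expect_true(any(duplicated(r$train)) || TRUE)   # with-replacement draw
  }
  expect_identical(reps, make_replicates(occ, seed = 4))
  expect_false(identical(reps, make_replicates(occ, seed = 5)))
  expect_error(make_replicates(data.frame(x = 1:5)), "at least 8")
})

test_that("AUC is the Mann-Whitney statistic with midranks", {
  expect_equal(auc(c(2, 3), c(0, 1)), 1)
  expect_equal(auc(c(0.9, 0.4), c(0.5, 0.1)), 0.75)  # 3 of 4 concordant pairs
  expect_equal(auc(rep(0.5, 10), rep(0.5, 7)), 0.5)
  # label permutation centers on 1/2
  set.seed(8)
  s <- rnorm(1000)
  aucs <- replicate(200, {
    lab <- sample(c(rep(TRUE, 300), rep(FALSE, 700)))
    auc(s[lab], s[!lab])
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})

test_that("maxSSS threshold maximizes sens + spec with smallest-t ties", {
  # hand enumeration: t = 0.4 and t = 0.6 tie at 1 + 2/3; smaller wins
  expect_equal(max_sss_threshold(c(0.8, 0.6, 0.4), c(0.5, 0.3, 0.1)), 0.4)
  # separable case: smallest candidate achieving sens + spec = 2
  t <- max_sss_threshold(rep(1, 5), rep(0, 5))
  expect_equal(t, 1)
  expect_equal(mean(rep(1, 5) >= t) + mean(rep(0, 5) < t), 2)
  # exchangeable scores: optimum near sens + spec = 1
  set.seed(9)
  s1 <- runif(400); s2 <- runif(400)
  tt <- max_sss_threshold(s1, s2)
  expect_lt(abs(mean(s1 >= tt) + mean(s2 < tt) - 1), 0.15)
})

test_that("maxSSS threshold maps through strictly increasing transforms", {
  set.seed(10)
  p <- runif(50); b <- runif(80)
  t0 <- max_sss_threshold(p, b)
  for (f in list(function(x) x^3, function(x) 1 - exp(-2 * x), qnorm)) {
    expect_equal(max_sss_threshold(f(p), f(b)), f(t0), tolerance = 1e-12)
  }
})

test_that("omission rate counts test presences below the threshold", {
  expect_equal(omission_rate(c(0.5, 0.6), 0.1)$rate, 0)
  om <- omission_rate(c(0.1, 0.3, 0.5, 0.05), 0.2)
  expect_equal(om$rate, 0.5)
  expect_true(om$overfit)
  expect_false(omission_rate(rep(1, 10), 0.5)$overfit)
  expect_true(omission_rate(c(rep(1, 88), rep(0, 12)), 0.5)$overfit) # 0.12 > 0.1
})

test_that("partial ROC is calibrated on null scores and powered on signal", {
  set.seed(11)
  # null: presence scores are just background draws
  bg <- runif(1000)
  pr_null <- partial_roc(sample(bg, 50), bg, seed = 1)
  expect_lt(abs(pr_null$mean_ratio - 1), 0.05)
  expect_gt(pr_null$p_value, 0.05)
  # planted signal
  pr_sig <- partial_roc(runif(50, 0.6, 1), bg, seed = 2)
  expect_gt(pr_sig$mean_ratio, 1.2)
  expect_lt(pr_sig$p_value, 0.01)
  # reproducibility under a fixed seed
  ps <- runif(40, 0.4, 1)
  expect_identical(partial_roc(ps, bg, seed = 7)$ratios,
                   partial_roc(ps, bg, seed = 7)$ratios)
  expect_false(identical(partial_roc(ps, bg, seed = 7)$ratios,
                         partial_roc(ps, bg, seed = 8)$ratios))
  # degenerate scores are reported as undefined
  deg <- partial_roc(rep(0.5, 20), rep(0.5, 100), seed = 3)
  expect_true(is.na(deg$mean_ratio))
})

test_that("AICc follows the small-sample corrected formula", {
  w <- small_world(seed = 12, n_vars = 3, n_pres = 50, n_bg = 200)
  fm <- build_feature_map(w$bg, "LQ")
  m <- fit_maxent(w$pres, w$bg, fm, rm = 1)
  ic <- aicc(m, w$pres, w$stack)
  expect_true(ic$valid)
  k <- sum(m$lambda != 0)
  expect_equal(ic$aicc, 2 * k - 2 * ic$lnL + 2 * k * (k + 1) / (50 - k - 1))
  # arithmetic check of the formula at lnL = -100, k = 5, n = 50
  expect_equal(2 * 5 - 2 * (-100) + 2 * 5 * 6 / (50 - 5 - 1), 211.364,
               tolerance = 1e-4)
  # k >= n - 1 is invalid
  ic_small <- aicc(m, w$pres[seq_len(k), ], w$stack)
  expect_false(ic_small$valid)
  expect_true(is.na(ic_small$aicc))
})

test_that("AICc ordering is invariant to duplicating background cells", {
  w <- small_world(seed = 13, n_vars = 3, n_pres = 60, n_bg = 200)
  fm <- build_feature_map(w$bg, "LQ")
  bg2 <- rbind(w$bg, w$bg); class(bg2) <- class(w$bg)
  a1 <- vapply(1:3, function(rm)
    aicc(fit_maxent(w$pres, w$bg, fm, rm = rm), w$pres, w$stack)$aicc,
    numeric(1))
  a2 <- vapply(1:3, function(rm)
    aicc(fit_maxent(w$pres, bg2, fm, rm = rm), w$pres, w$stack)$aicc,
    numeric(1))
  expect_equal(order(a1), order(a2))
  expect_equal(a1, a2, tolerance = 1e-3)
})

test_that("tuning scans all combinations and penalizes unused complexity", {
  w <- small_world(seed = 14, n_vars = 3, n_pres = 50, n_bg = 250)
  tr <- tune(w$pres, w$bg, w$stack, n_knots = 10)
  expect_equal(nrow(tr$results), 36)
  expect_equal(sum(tr$results$best), 1)
  expect_equal(min(tr$results$aicc[tr$results$valid]), tr$best$aicc)
  # single class set, single rm: that combination is best
  tr1 <- tune(w$pres, w$bg, w$stack, class_sets = "LQ", rm_range = 2)
  expect_equal(tr1$best$class_set, "LQ")
  expect_equal(tr1$best$rm, 2)
})

test_that("a linear-response species tunes to simple feature classes", {
  # presences driven by a monotone (linear) response to bio1
  spc <- synthetic_climate_spec(grid = grid_spec(40, 40, 10, 30, 0.25),
                                n_vars = 3, seed = 21)
  stack <- make_climate_stack(spc)
  g <- stack$layers$bio1$values
  prob <- (g - min(g)) / diff(range(g))
  set.seed(22)
  cells <- sample.int(length(prob), 30, replace = TRUE, prob = as.vector(prob))
  row <- (cells - 1) %% 40 + 1; col <- (cells - 1) %/% 40 + 1
  pts <- data.frame(lon = 10 + (col - 0.5) * 0.25,
                    lat = 30 + (40 - row + 0.5) * 0.25)
  pres <- extract_swd(stack, pts, "lin")
  bg <- extract_swd(stack, sample_background(
    uniform_bias_surface(stack$spec), 400, seed = 23), "background")
  tr <- tune(pres, bg, stack, n_knots = 10)
  expect_true(tr$best$class_set %in% c("L", "LQ"))
})

test_that("model choice prioritizes low omission lexicographically", {
  mk <- function(om, auc_diff, test_auc, cs) {
    r <- list(class_set = cs, rm = 1,
              summary = data.frame(class_set = cs, rm = 1,
                                   mean_train_auc = test_auc + auc_diff,
                                   mean_test_auc = test_auc,
                                   mean_auc_diff = auc_diff,
                                   mean_omission = om,
                                   mean_threshold = 0.5,
                                   mean_proc_ratio = 1.5, overfit = om > 0.1))
    class(r) <- "eval_report"
    r
  }
  a <- mk(0.05, 0.02, 0.80, "A"); b <- mk(0.15, 0.01, 0.95, "B")
  expect_equal(choose_model(list(a, b))$index, 1)   # omission beats AUC
  c_ <- mk(0.05, 0.01, 0.85, "C")
  expect_equal(choose_model(list(a, c_))$index, 2)  # then AUC difference
  d <- mk(0.05, 0.02, 0.90, "D")
  expect_equal(choose_model(list(a, d))$index, 2)   # then test AUC
  expect_equal(choose_model(list(a, mk(0.05, 0.02, 0.80, "E")))$index, 1) # tie
  expect_equal(choose_model(list(b))$index, 1)
})

test_that("candidate evaluation produces coherent replicate reports", {
  w <- small_world(seed = 15, n_vars = 3, n_pres = 80, n_bg = 400)
  rep_ <- evaluate_candidate(w$pres, w$bg, "LQ", rm = 1, n_rep = 3,
                             seed = 2, partial_roc_iter = 50)
  expect_equal(nrow(rep_$replicates), 3)
  expect_true(all(rep_$replicates$train_auc >= 0 &
                    rep_$replicates$train_auc <= 1))
  expect_true(all(rep_$replicates$omission >= 0 &
                    rep_$replicates$omission <= 1))
  expect_equal(rep_$summary$mean_omission, mean(rep_$replicates$omission))
  # reproducible under the same seed
  rep2 <- evaluate_candidate(w$pres, w$bg, "LQ", rm = 1, n_rep = 3,
                             seed = 2, partial_roc_iter = 50)
  expect_equal(rep_$replicates, rep2$replicates)
})

test_that("variable selection removes duplicates and keeps clean sets", {
  w <- small_world(seed = 16, n_vars = 3, n_pres = 60, n_bg = 300)
  # plant an exact duplicate of bio1
  pres <- w$pres; bg <- w$bg
  pres$dupl <- pres$bio1; bg$dupl <- bg$bio1
  class(pres) <- class(w$pres); class(bg) <- class(w$bg)
  stack2 <- layer_stack(c(w$stack$layers,
                          list(dupl = w$stack$layers$bio1)),
                        period = "current")
  sel <- select_variables(pres, bg, stack2, contribution_min = 0,
                          class_sets = "LQ", rm_range = 1, n_knots = 10)
  # the exact duplicate pair never survives together
  expect_false(all(c("bio1", "dupl") %in% sel$variables))
  expect_true(length(sel$variables) >= 1)

  # independent layers, all contributing: the set is already a fixed point
  spc <- synthetic_climate_spec(grid = grid_spec(30, 30, 10, 30, 0.25),
                                n_vars = 3, seed = 31,
                                grad_lat = c(-20, 0, 5), grad_lon = c(0, 15, -10),
                                target_corr = diag(3))
  stack3 <- make_climate_stack(spc)
  vs3 <- virtual_species(stack3, optima = c(bio1 = 12, bio2 = 8),
                         tolerances = c(bio1 = 0.5, bio2 = 0.5),
                         plateau = c(bio1 = 3, bio2 = 3))
  occ3 <- sample_presences(vs3, 80, seed = 32)
  pres3 <- extract_swd(stack3, occ3, "v")
  bg3 <- extract_swd(stack3, sample_background(
    uniform_bias_surface(stack3$spec), 400, seed = 33), "background")
  sel2 <- select_variables(pres3, bg3, stack3, contribution_min = 0,
                           class_sets = "LQ", rm_range = 1, n_knots = 10)
  expect_setequal(sel2$variables, c("bio1", "bio2", "bio3"))
  expect_equal(nrow(sel2$trace), 0)
})
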