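test_that("PCA recovers degenerate and isotropic structure", {
  # rank-1 data: all variance on PC1
  set.seed(1)
  t1 <- rnorm(50)
  tab1 <- data.frame(species = "a", x = t1, y = 2 * t1, z = -t1)
  p1 <- pca_climate(tab1, standardize = FALSE)
  expect_equal(p1$proportions[1], 1, tolerance = 1e-10, ignore_attr = TRUE)
  # loadings orthonormality
  L <- p1$loadings
  expect_equal(t(L) %*% L, diag(3), tolerance = 1e-10, ignore_attr = TRUE)
  # two uncorrelated unit-variance variables split evenly
  tab2 <- data.frame(species = "a", x = rnorm(2000), y = rnorm(2000))
  p2 <- pca_climate(tab2)
  expect_equal(unname(p2$proportions), c(0.5, 0.5), tolerance = 0.05)
  # per-component score variance equals the eigenvalue
  w <- two_species_scenario(
    synthetic_climate_spec(grid = grid_spec(30, 30, 10, 30, 0.25),
                           n_vars = 12, seed = 2),
    offset_sd = 2, n_per_species = 60, seed = 3)
  p3 <- pca_climate(w$table)
  expect_equal(unname(apply(p3$scores, 2, stats::var)),
               unname(p3$eigenvalues), tolerance = 1e-8)
  # deterministic sign convention
  for (j in seq_len(ncol(p3$loadings)))
    expect_gt(p3$loadings[which.max(abs(p3$loadings[, j])), j], 0)
  expect_error(pca_climate(data.frame(species = "a", x = 1:5, y = 1)),
               "constant")
})

test_that("broken-stick expectations and retention follow the closed form", {
  b3 <- broken_stick(3)
  expect_equal(b3, c(11 / 18, 5 / 18, 2 / 18), tolerance = 1e-12)
  expect_equal(round(b3, 4), c(0.6111, 0.2778, 0.1111))
  for (p in c(1, 5, 19)) expect_equal(sum(broken_stick(p)), 1)
  # retention: leading run above expectation
  expect_equal(retain_components(c(0.7, 0.2, 0.1)), 1)   # 0.2 < 0.2778
  expect_equal(retain_components(c(0.65, 0.30, 0.05)), 2)
  expect_equal(retain_components(c(0.3, 0.4, 0.3)), 0)   # PC1 below stick
  # scale invariance under standardization
  w <- two_species_scenario(
    synthetic_climate_spec(grid = grid_spec(30, 30, 10, 30, 0.25),
                           n_vars = 8, seed = 4),
    offset_sd = 1, n_per_species = 50, seed = 5,
    optima = c(bio1 = 12), tolerances = c(bio1 = 0.35))
  tab <- w$table
  tab2 <- tab
  tab2$bio3 <- tab2$bio3 * 1000 + 5
  expect_equal(pca_climate(tab)$retained, pca_climate(tab2)$retained)
})

test_that("ANOVA/Tukey flags planted group shifts and matches the t-test at k = 2", {
  set.seed(6)
  # identical distributions relabeled: no significance
  x <- rnorm(90)
  null <- anova_tukey(matrix(x, ncol = 1), rep(c("a", "b", "c"), each = 30))
  expect_gt(null$anova$p[1], 0.001)
  expect_true(all(!null$tukey$significant))
  # two groups: Tukey p equals the equal-variance two-sample p
  g2 <- rep(c("a", "b"), each = 25)
  y <- c(rnorm(25), rnorm(25, 0.8))
  tk <- anova_tukey(matrix(y, ncol = 1), g2)
  tt <- stats::t.test(y ~ g2, var.equal = TRUE)
  expect_equal(tk$tukey$p[1], tt$p.value, tolerance = 1e-6)
  # three groups, one shifted by 3 pooled sds: that pair is significant
  z <- c(rnorm(50), rnorm(50), rnorm(50, 3))
  g3 <- rep(c("a", "b", "c"), each = 50)
  tk3 <- anova_tukey(matrix(z, ncol = 1), g3)
  expect_true(all(tk3$tukey$significant[tk3$tukey$pair %in%
                                          c("c-a", "c-b")]))
  expect_false(tk3$tukey$significant[tk3$tukey$pair == "b-a"])
  expect_error(anova_tukey(matrix(z, ncol = 1), c("a", rep("b", 149))),
               ">= 2 observations")
})

test_that("condition-number/VIF selection matches a brute-force oracle", {
  oracle_select <- function(x, vif_max = 10) {
    # independent enumeration via svd of the standardized data matrix
    p <- ncol(x)
    z <- scale(x)
    best <- vector("list", p)
    for (s in seq_len(p)) {
      for (idx in utils::combn(p, s, simplify = FALSE)) {
        sv <- svd(z[, idx, drop = FALSE])$d
        kap <- if (min(sv) < 1e-8) Inf else max(sv) / min(sv)
        if (is.null(best[[s]]) || kap < best[[s]]$kappa)
          best[[s]] <- list(idx = idx, kappa = kap)
      }
    }
    ok <- vapply(seq_len(p), function(s) {
      idx <- best[[s]]$idx
      if (!is.finite(best[[s]]$kappa)) return(FALSE)
      vif <- diag(solve(stats::cor(z[, idx, drop = FALSE])))
      all(vif <= vif_max)
    }, logical(1))
    best[[max(which(ok))]]$idx
  }
  set.seed(7)
  for (trial in 1:3) {
    p <- sample(4:6, 1)
    n <- 80
    base <- matrix(rnorm(n * p), n, p)
    # plant correlation structure
    base[, 2] <- base[, 1] * 0.95 + rnorm(n, sd = 0.3)
    x <- base
    colnames(x) <- paste0("b", seq_len(p))
    tab <- cbind(data.frame(species = "s"), as.data.frame(x))
    res <- subset_select_condition_vif(tab)
    expect_setequal(res$variables, colnames(x)[oracle_select(x)])
    expect_gte(res$kappa, 1)
    expect_true(all(res$vif >= 1 - 1e-9))
  }
})

test_that("orthonormal columns select in full; duplicated columns never co-survive", {
  q <- qr.Q(qr(matrix(rnorm(100 * 4), 100, 4)))
  colnames(q) <- paste0("b", 1:4)
  tab <- cbind(data.frame(species = "s"), as.data.frame(q))
  res <- subset_select_condition_vif(tab)
  expect_setequal(res$variables, colnames(q))
  expect_equal(res$kappa, 1, tolerance = 0.35)   # sample correlation noise
  expect_true(all(res$vif < 1.5))

  tab$b5 <- tab$b1
  res2 <- subset_select_condition_vif(tab)
  expect_false(all(c("b1", "b5") %in% res2$variables))
})

test_that("train/test splitting is stratified and reproducible", {
  tab <- data.frame(species = rep(c("a", "b"), c(60, 40)), x = rnorm(100))
  sp <- split_train_test(tab, seed = 8)
  expect_equal(nrow(sp$train), 80)
  expect_equal(nrow(sp$test), 20)
  expect_equal(sum(sp$train$species == "a"), 48)
  expect_equal(sum(sp$test$species == "b"), 8)
  expect_identical(split_train_test(tab, seed = 8)$train, sp$train)
  expect_error(split_train_test(tab[1:8, ]), "at least 10")
})

test_that("ridge logistic CV selects on the declared grid and shrinks monotonically", {
  set.seed(9)
  n <- 120
  x1 <- c(rnorm(n / 2), rnorm(n / 2, 1.5))
  x2 <- rnorm(n)
  tab <- data.frame(species = rep(c("a", "b"), each = n / 2),
                    v1 = x1, v2 = x2)
  grid_default <- seq(0.001, 0.5, length.out = 100)
  expect_length(grid_default, 100)
  expect_equal(range(grid_default), c(0.001, 0.5))
  m <- fit_l2_logistic_cv(tab, grid = seq(0.001, 0.5, length.out = 10),
                          seed = 1)
  expect_true(m$lambda_pen %in% m$cv$lambda_pen)
  # positive class is the second species; v1 is larger there
  expect_gt(m$coef[["v1"]], 0)
  # coefficient norm non-increasing in the penalty on fixed data
  Z <- scale(as.matrix(tab[, c("v1", "v2")]))
  y <- as.numeric(tab$species == "b")
  norms <- vapply(c(0.001, 0.01, 0.05, 0.2, 0.5), function(lp)
    sqrt(sum(enmdyn:::fit_ridge_logistic(Z, y, lp)$coef^2)), numeric(1))
  expect_true(all(diff(norms) < 1e-8))
  expect_error(fit_l2_logistic_cv(tab[tab$species == "a", ], pair = c("a", "b")),
               "single class")
})

test_that("the authored ridge logistic fit agrees with glmnet", {
  skip_if_not_installed("glmnet")
  set.seed(10)
  n <- 200
  X <- matrix(rnorm(n * 3), n, 3)
  y <- rbinom(n, 1, plogis(X %*% c(1, -0.5, 0)))
  Z <- scale(X)
  lp <- 0.05
  ours <- enmdyn:::fit_ridge_logistic(Z, y, lp)
  # glmnet ridge: (1/n) logloss + lambda/2 * ||beta||^2  =>  lambda = 2 lp
  gl <- glmnet::glmnet(Z, y, family = "binomial", alpha = 0,
                       lambda = 2 * lp, standardize = FALSE,
                       thresh = 1e-14)
  expect_equal(ours$coef, as.vector(gl$beta), tolerance = 1e-4)
  expect_equal(ours$intercept, as.vector(gl$a0), tolerance = 1e-4)
})

test_that("classification metrics follow their standard definitions", {
  mk_model <- function(coef, intercept, vars) {
    structure(list(pair = c("a", "b"), variables = vars,
                   center = rep(0, length(vars)),
                   scale = rep(1, length(vars)),
                   lambda_pen = 0.1, intercept = intercept,
                   coef = stats::setNames(coef, vars),
                   cv = data.frame()), class = "discrimination_model")
  }
  # perfect classifier
  test1 <- data.frame(species = rep(c("a", "b"), each = 5),
                      x = rep(c(-2, 2), each = 5))
  m1 <- mk_model(5, 0, "x")
  expect_equal(unlist(classification_metrics(m1, test1)),
               c(roc_auc = 1, precision = 1, recall = 1, f1 = 1))
  # all-positive predictions at prevalence 0.4
  test2 <- data.frame(species = rep(c("a", "b"), c(6, 4)), x = rep(1, 10))
  m2 <- mk_model(0, 10, "x")
  met2 <- classification_metrics(m2, test2)
  expect_equal(met2$precision, 0.4)
  expect_equal(met2$recall, 1)
  expect_equal(met2$f1, 2 * 0.4 / 1.4, tolerance = 1e-6)
  # confusion TP=3 FP=1 FN=1 TN=5
  test3 <- data.frame(species = rep(c("b", "a"), c(4, 6)),
                      x = c(1, 1, 1, -1, 1, -1, -1, -1, -1, -1))
  m3 <- mk_model(5, 0, "x")
  met3 <- classification_metrics(m3, test3)
  expect_equal(met3$precision, 0.75)
  expect_equal(met3$recall, 0.75)
  expect_equal(met3$f1, 0.75)
})

test_that("linear Shapley values are exact and match coalition enumeration", {
  set.seed(11)
  tab <- data.frame(species = rep(c("a", "b"), each = 30),
                    u = rnorm(60), v = rnorm(60), w = rnorm(60))
  tab$u <- tab$u + 2 * (tab$species == "b")
  m <- fit_l2_logistic_cv(tab, grid = c(0.01, 0.1), seed = 2)
  sh <- linear_shap(m, tab)
  eta <- enmdyn:::predict_logistic(m, tab, type = "link")
  # exact local accuracy
  expect_equal(rowSums(sh$phi) + sh$base, eta, tolerance = 1e-12,
               ignore_attr = TRUE)
  # brute-force Shapley with mean-imputation value function over 2^3 coalitions
  Z <- scale(as.matrix(tab[, m$variables]), center = m$center,
             scale = m$scale)
  vfun <- function(S, i) {
    zz <- rep(0, 3)                 # reference = train means = 0 after scaling
    zz[S] <- Z[i, S]
    m$intercept + sum(m$coef * zz)
  }
  for (i in c(1, 17, 60)) {
    for (j in 1:3) {
      others <- setdiff(1:3, j)
      phi <- 0
      for (k in 0:2) {
        for (S in utils::combn(others, k, simplify = FALSE)) {
          wgt <- factorial(k) * factorial(3 - k - 1) / factorial(3)
          phi <- phi + wgt * (vfun(c(S, j), i) - vfun(S, i))
        }
      }
      expect_equal(unname(sh$phi[i, j]), phi, tolerance = 1e-10)
    }
  }
  # zero-coefficient variables get zero attribution
  m0 <- m
  m0$coef[["w"]] <- 0
  sh0 <- linear_shap(m0, tab)
  expect_true(all(sh0$phi[, "w"] == 0))
  expect_error(linear_shap(m, tab[, 1:3]), "unknown variable")
})

test_that("partial dependence averages the prediction over the overwritten variable", {
  set.seed(12)
  tab <- data.frame(species = rep(c("a", "b"), each = 40),
                    u = rnorm(80), v = rnorm(80))
  tab$u <- tab$u + 2 * (tab$species == "b")
  m <- fit_l2_logistic_cv(tab, grid = c(0.01, 0.1), seed = 3)
  pd <- partial_dependence(m, tab, "u", grid = c(-2, 0, 2))
  expect_equal(nrow(pd), 3)
  expect_true(all(diff(pd$pd) > 0))   # positive-coefficient variable
  d0 <- tab; d0$u <- 0
  expect_equal(pd$pd[2], mean(enmdyn:::predict_logistic(m, d0)),
               tolerance = 1e-12)
  expect_error(partial_dependence(m, tab, "zz"), "unknown variable")
})

test_that("planted two-species differences are recovered end to end", {
  w <- two_species_scenario(
    synthetic_climate_spec(grid = grid_spec(40, 40, 10, 30, 0.25),
                           n_vars = 12, seed = 13),
    offset_sd = 3, n_per_species = 200, seed = 14)
  sp <- split_train_test(w$table, seed = 15)
  keep <- c("species", subset_select_condition_vif(sp$train, max_p = 12)$variables)
  m <- fit_l2_logistic_cv(sp$train[, keep],
                          grid = seq(0.001, 0.5, length.out = 25), seed = 16)
  met <- classification_metrics(m, sp$test[, keep])
  expect_gt(met$roc_auc, 0.9)
  # the planted driver (or a close correlate) carries the attribution signal
  sh <- linear_shap(m, sp$test[, keep])
  top <- names(which.max(colMeans(abs(sh$phi))))
  expect_true(top %in% c("bio1", "bio2", "bio3"))
  # and its mean attribution sign tracks the planted direction (spB warmer)
  mean_phi_b <- mean(sh$phi[sp$test$species == "spB", top])
  mean_phi_a <- mean(sh$phi[sp$test$species == "spA", top])
  expect_gt(mean_phi_b, mean_phi_a)
})

test_that("null two-species scenarios show no discrimination signal", {
  w <- two_species_scenario(
    synthetic_climate_spec(grid = grid_spec(40, 40, 10, 30, 0.25),
                           n_vars = 6, seed = 17),
    offset_sd = 0, n_per_species = 150, seed = 18,
    optima = c(bio1 = 12), tolerances = c(bio1 = 0.35))
  sp <- split_train_test(w$table, seed = 19)
  m <- fit_l2_logistic_cv(sp$train, grid = seq(0.001, 0.5, length.out = 10),
                          seed = 20)
  met <- classification_metrics(m, sp$test)
  expect_lt(abs(met$roc_auc - 0.5), 0.25)   # small-test-set noise around 1/2
})
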