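test_that("tree attributions satisfy local accuracy and the stump identity", {
  set.seed(61)
  n <- 80
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(paste0("i", 1:n),
                                                  paste0("f", 1:4)))
  y <- 1.5 * X[, 2] + rnorm(n, 0, 0.1)
  rf <- raw_forest(X, y, max_depth = 4, n_estimators = 40, seed = 61)
  sh <- compute_shap(rf, X)
  expect_equal(sh$base + rowSums(sh$phi), predict(rf, X),
               tolerance = 1e-6, ignore_attr = TRUE)
  # a depth-1 single-feature stump: the split feature carries everything
  stump <- raw_forest(X[, 2, drop = FALSE], y, max_depth = 1,
                      max_features = "none", n_estimators = 1, seed = 62)
  sh1 <- compute_shap(stump, X[, 2, drop = FALSE])
  expect_equal(sh1$phi[, 1], predict(stump, X[, 2, drop = FALSE]) - sh1$base,
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(compute_shap(structure(list(), class = "weird"), X),
               "tree-ensemble or linear")
})

test_that("attributions equal brute-force Shapley on small trees", {
  set.seed(63)
  X <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1, 0.4, 0.7), 5, 2, byrow = TRUE,
              dimnames = list(NULL, c("a", "b")))
  y <- c(0, 1, 2, 5, 0.3)
  rf <- raw_forest(X, y, max_depth = 2, max_features = "none",
                   n_estimators = 5, seed = 63)
  sh <- compute_shap(rf, X)
  for (i in 1:5)
    expect_equal(unname(sh$phi[i, ]), brute_force_shapley(rf, X[i, ], 2),
                 tolerance = 1e-10)
  # three features, depth 2, with feature re-use along paths
  X3 <- matrix(runif(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  y3 <- X3[, 1] * (X3[, 2] > 0.5) + 0.3 * X3[, 3]
  rf3 <- raw_forest(X3, y3, max_depth = 2, max_features = "none",
                    n_estimators = 7, seed = 64)
  sh3 <- compute_shap(rf3, X3)
  for (i in c(1, 4, 8))
    expect_equal(unname(sh3$phi[i, ]), brute_force_shapley(rf3, X3[i, ], 3),
                 tolerance = 1e-10)
})

test_that("linear models get exact linear attributions", {
  set.seed(65)
  X <- matrix(rnorm(200), 40, 5, dimnames = list(NULL, paste0("m", 1:5)))
  y <- drop(X %*% c(1, -2, 0, 0.5, 0)) + rnorm(40, 0, 0.1)
  fit <- rrblup_fit(X, y)
  sh <- compute_shap(fit, X)
  expect_equal(sh$base + rowSums(sh$phi), predict(fit, X), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(unname(sh$phi[, 2]),
               unname(fit$u[2] * (X[, 2] - mean(X[, 2]))), tolerance = 1e-10)
})

test_that("global importance drops unused features and ties duplicates", {
  set.seed(66)
  n <- 100
  x <- rnorm(n)
  X <- cbind(a = x, b = x, noise = rnorm(n))   # duplicated column
  y <- 2 * x + rnorm(n, 0, 0.1)
  rf <- raw_forest(X, y, max_depth = 3, max_features = "none",
                   n_estimators = 200, seed = 66)
  sh <- compute_shap(rf, X)
  tab <- global_importance_rank(sh)
  ab <- tab[tab$feature %in% c("a", "b"), ]
  expect_equal(diff(range(ab$importance)) / max(ab$importance), 0,
               tolerance = 0.15)   # shared splits divide the credit evenly-ish
  expect_true(all(c("a", "b") == tab$feature[1:2]))
  # a feature never split on is absent from the table
  rf1 <- raw_forest(X[, 1, drop = FALSE], y, max_depth = 2,
                    max_features = "none", n_estimators = 5, seed = 67)
  sh1 <- compute_shap(rf1, X[, 1, drop = FALSE])
  expect_equal(global_importance_rank(sh1)$feature, "a")
})

test_that("rank correlation joins on features or genes and matches by hand", {
  ta <- data.frame(feature = c("f1", "f2", "f3", "f4", "f5"),
                   importance = c(5, 4, 3, 2, 1))
  expect_equal(rank_correlation(ta, ta)$rho, 1)
  tb <- ta; tb$importance <- rev(tb$importance)
  expect_equal(rank_correlation(ta, tb)$rho, -1)
  tc <- data.frame(feature = ta$feature, importance = c(2, 5, 1, 4, 3))
  oracle <- cor(ta$importance, tc$importance, method = "spearman")
  expect_equal(rank_correlation(ta, tc)$rho, oracle, tolerance = 1e-12)
  # gene-level join takes per-gene maxima first
  gm <- data.frame(feature = c("f1", "f2", "f3", "f4", "f5"),
                   gene = c("g1", "g1", "g2", "g3", "g4"))
  rc <- rank_correlation(ta, tc, join_on = "gene", gene_map = gm)
  a_gene <- c(g1 = 5, g2 = 3, g3 = 2, g4 = 1)
  c_gene <- c(g1 = 5, g2 = 1, g3 = 4, g4 = 3)
  expect_equal(rc$rho, cor(a_gene, c_gene, method = "spearman"),
               tolerance = 1e-12)
  expect_equal(rc$n_shared, 4)
  few <- data.frame(feature = c("f1", "f2"), importance = 1:2)
  expect_true(is.na(rank_correlation(few, few)$rho))
})

test_that("SHAP clustering separates opposite genetic backgrounds", {
  set.seed(68)
  n <- 120
  bg <- rep(c(0, 1), each = n / 2)
  X <- cbind(drv = bg * 2, other = rnorm(n))
  colnames(X) <- c("drv", "other")
  y <- ifelse(bg == 1, 2, -2) + rnorm(n, 0, 0.2)
  rf <- raw_forest(X, y, max_depth = 3, max_features = "none",
                   n_estimators = 40, seed = 68)
  rownames(X) <- paste0("i", 1:n)
  sh <- compute_shap(rf, X)
  cl <- cluster_isolates_by_shap(sh, k = 2, n_clusters = 2)
  tab <- table(cl$labels, bg)
  agreement <- max(sum(diag(tab)), sum(tab[1, 2], tab[2, 1])) / n
  expect_gt(agreement, 0.95)
  expect_true(all(sort(unique(cl$labels)) == seq_along(unique(cl$labels))))
  expect_warning(cluster_isolates_by_shap(sh, k = 50, n_clusters = 2), "capped")
  # threshold 0 separates every distinct profile
  cl0 <- cluster_isolates_by_shap(sh, k = 2, threshold = 0)
  expect_equal(length(unique(cl0$labels)),
               nrow(unique(round(sh$phi[, cl0$features], 12))))
})

test_that("cluster-fitness trend matches the two-point OLS oracle", {
  phi <- rbind(matrix(0.1, 10, 3), matrix(2, 10, 3))
  rownames(phi) <- paste0("i", 1:20)
  colnames(phi) <- paste0("f", 1:3)
  sh <- structure(list(phi = phi, base = 0, model_id = "toy"),
                  class = "fs_shap")
  cl <- cluster_isolates_by_shap(sh, k = 3, n_clusters = 2)
  fitness <- setNames(c(rep(0, 10), rep(1, 10)), rownames(phi))
  tr <- cluster_fitness_trend(cl, sh, fitness)
  expect_equal(tr$slope, (1 - 0) / (2 - 0.1), tolerance = 1e-10)
  expect_equal(tr$r, 1, tolerance = 1e-10)
  # equal cluster medians: zero slope
  tr0 <- cluster_fitness_trend(cl, sh, setNames(rep(1, 20), rownames(phi)))
  expect_equal(tr0$slope, 0)
  one_cl <- cl; one_cl$labels[] <- 1L
  expect_error(cluster_fitness_trend(one_cl, sh, fitness), "single cluster")
})

test_that("Gini and mean-absolute-SHAP rankings agree on synthetic cohorts", {
  coh <- small_cohort(n = 200, snps = 120, envs = 1, h2 = 0.7, qtl = 10,
                      seed = 69, missing_rate = 0)
  X <- coh$geno$dosages
  y <- coh$fitness$values[, 1]
  rf <- raw_forest(X, y, max_depth = 6, max_features = "0.5",
                   n_estimators = 80, seed = 69)
  gini <- rank_by_gini(rf)
  shap_tab <- global_importance_rank(compute_shap(rf, X))
  rc <- rank_correlation(gini, shap_tab)
  expect_gt(rc$rho, 0.5)
  expect_lt(rc$p, 0.01)
})
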