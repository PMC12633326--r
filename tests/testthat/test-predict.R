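test_that("holdout split has the documented sizes and is deterministic", {
  ids <- sprintf("iso_%04d", 1:750)
  sp <- split_holdout(ids, split_scheme(seed = 3))
  expect_length(sp$test, 125)
  expect_length(sp$train, 625)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), ids)
  expect_identical(sp, split_holdout(ids, split_scheme(seed = 3)))
  expect_length(split_holdout(sprintf("i%02d", 1:12), split_scheme(seed = 1))$test, 2)
  expect_error(split_holdout(ids[1:5], split_scheme()), "too few")
})

test_that("rrBLUP at fixed lambda equals the explicit ridge solution", {
  set.seed(31)
  X <- matrix(rnorm(60), 6, 10)
  y <- rnorm(6)
  for (lam in c(0.1, 1, 10)) {
    fit <- rrblup_fit(X, y, lambda = lam)
    oracle <- solve(crossprod(X) + lam * diag(10), crossprod(X, y - fit$mu))
    expect_equal(unname(fit$u), drop(oracle), tolerance = 1e-8)
  }
})

test_that("rrBLUP REML recovers simulated marker effects", {
  set.seed(32)
  X <- matrix(rnorm(200 * 50), 200, 50)
  u_true <- rnorm(50, 0, 0.5)
  y <- drop(X %*% u_true) + rnorm(200, 0, 0.1)
  fit <- rrblup_fit(X, y)
  expect_gt(cor(fit$u, u_true), 0.95)
  # constant response degenerates gracefully
  expect_warning(fit0 <- rrblup_fit(X, rep(2, 200)), "zero-variance")
  expect_true(all(fit0$u == 0))
  expect_equal(fit0$mu, 2)
})

test_that("Bayesian samplers shrink noise and find sparse signal", {
  set.seed(33)
  n <- 120; p <- 200
  X <- matrix(rbinom(n * p, 2, 0.3), n, p,
              dimnames = list(NULL, sprintf("m%03d", 1:p)))
  # pure noise: posterior means shrink far below per-marker OLS
  y_noise <- rnorm(n)
  fit <- bayes_fit(X, y_noise, "BayesC", n_iter = 1500, burn_in = 300, seed = 1)
  ols <- abs(apply(X, 2, function(x)
    if (var(x) > 0) cov(x, y_noise) / var(x) else 0))
  expect_lt(mean(abs(fit$beta)), 0.1 * mean(ols))
  # sparse truth: the 5 large effects rank at the top in most seeded chains
  hits <- vapply(1:10, function(s) {
    idx <- fitscape:::with_seed(s, sample(p, 5))
    b <- numeric(p); b[idx] <- c(2, -2, 1.5, -1.5, 1.8)
    y <- drop(X %*% b) + fitscape:::with_seed(100 + s, rnorm(n))
    f <- bayes_fit(X, y, "BayesC", n_iter = 1500, burn_in = 300, seed = s)
    sum(idx %in% order(-abs(f$beta))[1:10]) == 5
  }, TRUE)
  expect_gte(sum(hits), 8)
  # Bayesian LASSO predicts the same sparse signal
  idx <- 1:5; b <- numeric(p); b[idx] <- 2
  y <- drop(X %*% b) + rnorm(n)
  fl <- bayes_fit(X, y, "BayesianLASSO", n_iter = 1500, burn_in = 300, seed = 2)
  expect_gt(r_sq <- 1 - sum((y - predict(fl, X))^2) / sum((y - mean(y))^2), 0.8)
  expect_error(bayes_fit(X, y, "BayesC", n_iter = 100, burn_in = 100), "burn-in")
  expect_error(bayes_fit(X, c(y[-1], Inf), "BayesC", n_iter = 200, burn_in = 10),
               "non-finite")
})

test_that("tree learners tune over the grid and learn structure", {
  # the default RF grid enumerates 3 x 5 x 3 = 45 combinations
  expect_equal(nrow(default_rf_grid()), 45)
  set.seed(34)
  n <- 150
  X <- matrix(runif(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y_step <- ifelse(X[, 3] > 0.5, 2, -1)        # deterministic step function
  fit <- tree_fit(X, y_step, "RF",
                  grid = data.frame(max_depth = c(2, 4), max_features = "none",
                                    n_estimators = 50),
                  scheme = split_scheme(n_repeats = 1, seed = 5))
  expect_gt(fit$validation_r2, 0.9)
  expect_equal(nrow(fit$tuning), 2)
  expect_equal(which.max(fit$importance), 3, ignore_attr = TRUE)
  # depth-limited trees on pure noise generalize near zero
  y_noise <- rnorm(n)
  fit0 <- tree_fit(X, y_noise, "RF",
                   grid = data.frame(max_depth = 3, max_features = "sqrt",
                                     n_estimators = 50),
                   scheme = split_scheme(n_repeats = 1, seed = 6))
  expect_lt(fit0$validation_r2, 0.1)
  expect_error(tree_fit(X, y_noise, "RF", grid = data.frame()[0, ],
                        scheme = split_scheme(seed = 1)), "empty")
  # GBM randomized search stays within the documented ranges
  gb <- tree_fit(X, y_step, "GBM", scheme = split_scheme(n_repeats = 1, seed = 7),
                 n_search = 6)
  expect_true(all(gb$tuning$learning_rate >= 0.01 & gb$tuning$learning_rate <= 0.4))
  expect_true(all(gb$tuning$max_depth %in% 2:10))
  expect_true(all(gb$tuning$n_estimators %% 5 == 0))
  expect_gt(gb$validation_r2, 0.8)
})

test_that("repeated cross-validation is deterministic and scores sensibly", {
  set.seed(35)
  n <- 90
  X <- matrix(rnorm(n * 20), n, 20, dimnames = list(paste0("i", 1:n), NULL))
  y <- drop(X[, 1:3] %*% c(1, 1, 1)) + rnorm(n, 0, 0.2)
  sch <- split_scheme(n_repeats = 2, seed = 9)
  cv <- cross_validate(X, y, "rrBLUP", sch, environment = "e1",
                       feature_type = "SNP")
  cv2 <- cross_validate(X, y, "rrBLUP", sch, environment = "e1",
                        feature_type = "SNP")
  expect_identical(cv$record, cv2$record)
  expect_gt(cv$record$validation_r2, 0.5)
  # a perfect predictor reaches R2 = 1 on validation and test
  y_perfect <- X[, 1]
  cvp <- cross_validate(X[, 1, drop = FALSE], y_perfect, "rrBLUP",
                        split_scheme(n_repeats = 1, seed = 2),
                        X_test = X[1:10, 1, drop = FALSE],
                        y_test = y_perfect[1:10])
  expect_gt(cvp$record$validation_r2, 0.999)
  expect_gt(cvp$record$test_r2, 0.999)
  # out-of-fold R2 of a mean-only predictor is <= 0 by construction
  oof_mean <- vapply(1:30, function(i) {
    r_squared(y[1:30], rep(mean(y[-(1:30)]), 30))
  }, 0)
  expect_true(all(oof_mean <= 0))
  # the holdout is never part of the training audit trail
  sp <- split_holdout(rownames(X), sch)
  cvh <- cross_validate(X[sp$train, ], y[match(sp$train, rownames(X))],
                        "rrBLUP", sch, X_test = X[sp$test, ],
                        y_test = y[match(sp$test, rownames(X))])
  expect_length(intersect(cvh$train_ids, sp$test), 0)
})

test_that("marker-based rrBLUP beats the PC-only baseline on additive traits", {
  diffs <- vapply(1:2, function(s) {
    coh <- small_cohort(n = 250, snps = 300, envs = 1, h2 = 0.5, qtl = 20,
                        seed = 700 + s, missing_rate = 0)
    geno <- coh$geno
    y <- coh$fitness$values[, 1]
    pcs <- principal_components(geno, 5)
    sch <- split_scheme(n_repeats = 1, seed = s)
    sp <- split_holdout(geno$isolates, sch)
    t_r2 <- function(X) cross_validate(X[sp$train, ], y[sp$train], "rrBLUP",
                                       sch, X[sp$test, ], y[sp$test]
                                       )$record$test_r2
    t_r2(geno$dosages) - t_r2(pcs$scores)
  }, 0)
  expect_gt(mean(diffs), 0)
})
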