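#' Holdout / cross-validation split scheme
#'
#' One-sixth of the isolates are held out as a test set used exclusively for
#' final evaluation; the training remainder is split into `n_folds` folds,
#' re-randomized for each of `n_repeats` repeats.
#'
#' @param test_fraction fraction held out (default 1/6).
#' @param n_folds folds of the inner cross-validation (default 5).
#' @param n_repeats number of repeated CV rounds.
#' @param seed integer seed governing all randomization of the scheme.
#' @export
split_scheme <- function(test_fraction = 1 / 6, n_folds = 5, n_repeats = 5,
                         seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1, n_folds >= 2, n_repeats >= 1)
  structure(list(test_fraction = test_fraction, n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed)),
            class = "split_scheme")
}

#' Split isolates into training and holdout test sets
#' @param isolates character vector of ids.
#' @param scheme a [split_scheme()].
#' @return list with `train` and `test` id vectors (disjoint, exhaustive).
#' @export
split_holdout <- function(isolates, scheme = split_scheme()) {
  n <- length(isolates)
  if (n < 2 * scheme$n_folds) stop("too few isolates for the scheme")
  n_test <- round(n * scheme$test_fraction)
  test <- with_seed(derive_seed(scheme$seed, "holdout"),
                    sort(sample(isolates, n_test)))
  list(train = setdiff(isolates, test), test = test)
}

fold_assignment <- function(n, n_folds) {
  sample(rep_len(seq_len(n_folds), n))
}

#' Ridge-regression BLUP via spectral REML
#'
#' Fits y = 1*mu + X u + e with i.i.d. Gaussian marker effects
#' u ~ N(0, I sigma2_u). The variance ratio lambda = sigma2_e / sigma2_u is
#' estimated by REML through a single eigendecomposition of X X' and a 1-D
#' likelihood optimization; marker effects are then the BLUP
#' u = X' (X X' + lambda I)^-1 (y - 1 mu), equal (push-through identity) to
#' the explicit ridge solution (X'X + lambda I)^-1 X' (y - 1 mu).
#'
#' @param X feature matrix (no missing values).
#' @param y response vector.
#' @param lambda optional fixed variance ratio; `NULL` (default) = REML.
#' @return an `fs_rrblup` model with `mu`, `u`, `lambda`, variance components.
#' @export
rrblup_fit <- function(X, y, lambda = NULL) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), !anyNA(X), !anyNA(y))
  n <- nrow(X)
  if (var(y) == 0) {
    warning("zero-variance response: all marker effects set to 0")
    return(structure(list(mu = mean(y), u = setNames(numeric(ncol(X)), colnames(X)),
                          lambda = Inf, sigma2_u = 0, sigma2_e = 0,
                          feature_means = colMeans(X), features = colnames(X)),
                     class = "fs_rrblup"))
  }
  K <- tcrossprod(X)
  eig <- eigen(K, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  yt <- crossprod(eig$vectors, y)
  ot <- crossprod(eig$vectors, rep(1, n))

  reml_ll <- function(log_lambda) {
    lam <- exp(log_lambda)
    w <- 1 / (d + lam)
    denom <- sum(ot^2 * w)
    mu <- sum(ot * yt * w) / denom
    r <- yt - ot * mu
    s2u <- sum(r^2 * w) / (n - 1)
    -0.5 * ((n - 1) * (log(2 * pi * s2u) + 1) + sum(log(d + lam)) + log(denom))
  }
  if (is.null(lambda)) {
    opt <- optimize(reml_ll, c(-12, 12), maximum = TRUE, tol = 1e-8)
    lambda <- exp(opt$maximum)
  }
  w <- 1 / (d + lambda)
  denom <- sum(ot^2 * w)
  mu <- sum(ot * yt * w) / denom
  r <- yt - ot * mu
  sigma2_u <- sum(r^2 * w) / (n - 1)
  u <- drop(crossprod(X, eig$vectors %*% (w * r)))
  names(u) <- colnames(X)
  structure(list(mu = mu, u = u, lambda = lambda, sigma2_u = sigma2_u,
                 sigma2_e = lambda * sigma2_u, feature_means = colMeans(X),
                 features = colnames(X)),
            class = "fs_rrblup")
}

#' @export
predict.fs_rrblup <- function(object, newdata, ...) {
  drop(as.matrix(newdata) %*% object$u) + object$mu
}

#' @export
coef.fs_rrblup <- function(object, ...) c(`(Intercept)` = object$mu, object$u)

#' @export
print.fs_rrblup <- function(x, ...) {
  cat(sprintf("<fs_rrblup> %d markers, lambda = %.4g (h2_markers = %.3f)\n",
              length(x$u), x$lambda, 1 / (1 + x$lambda / max(1e-12, sum(x$u^2)))))
  invisible(x)
}

#' Bayesian whole-genome regression (BayesC / Bayesian LASSO)
#'
#' Gibbs samplers for marker effect models. BayesC places a spike-slab prior
#' on effects: zero with probability 1 - `pi_in`, otherwise Gaussian with a
#' common variance carrying a scaled-inverse-chi-square prior. Bayesian LASSO
#' uses the double-exponential prior via its normal-exponential mixture with
#' a Gamma-updated lambda^2. Prior scales follow the common whole-genome
#' regression convention of an assumed genomic R2 (default 0.5) split over
#' markers.
#'
#' @param X feature matrix.
#' @param y response.
#' @param model `"BayesC"` or `"BayesianLASSO"`.
#' @param n_iter,burn_in chain length and burn-in (paper-scale defaults
#'   32000 / 3200; reduce for small problems).
#' @param pi_in BayesC prior inclusion probability (default 0.01).
#' @param df_b,df_e prior degrees of freedom (default 5).
#' @param R2 assumed genomic R2 used to set prior scales.
#' @param seed chain seed.
#' @return an `fs_bayes` model (posterior-mean effects; `pip` for BayesC).
#' @export
bayes_fit <- function(X, y, model = c("BayesC", "BayesianLASSO"),
                      n_iter = 32000, burn_in = 3200, pi_in = 0.01,
                      df_b = 5, df_e = 5, R2 = 0.5, seed = 1L) {
  model <- match.arg(model)
  X <- as.matrix(X)
  if (any(!is.finite(y))) stop("non-finite response values")
  if (burn_in >= n_iter) stop("burn-in must be smaller than the iteration count")
  vy <- var(y)
  msx <- sum(apply(X, 2, var))
  if (msx == 0) msx <- 1
  scale_e <- (1 - R2) * vy * (df_e + 2) / df_e
  res <- with_seed(derive_seed(seed, paste0("gibbs_", model)), {
    if (model == "BayesC") {
      scale_b <- R2 * vy * (df_b + 2) / (df_b * pi_in * msx)
      cpp_bayesc(X, y, as.integer(n_iter), as.integer(burn_in), pi_in,
                 df_b, scale_b, df_e, scale_e)
    } else {
      lambda2 <- 2 * (1 - R2) / R2 * msx
      cpp_blasso(X, y, as.integer(n_iter), as.integer(burn_in), lambda2,
                 1.1, 1.1 / lambda2, df_e, scale_e)
    }
  })
  structure(list(model = model, beta = setNames(res$beta, colnames(X)),
                 mu = res$mu, pip = if (model == "BayesC") res$pip,
                 sigma2_e = res$sigma2_e,
                 feature_means = colMeans(X), features = colnames(X),
                 n_iter = n_iter, burn_in = burn_in, seed = seed),
            class = "fs_bayes")
}

#' @export
predict.fs_bayes <- function(object, newdata, ...) {
  drop(as.matrix(newdata) %*% object$beta) + object$mu
}

#' @export
coef.fs_bayes <- function(object, ...) c(`(Intercept)` = object$mu, object$beta)

#' @export
print.fs_bayes <- function(x, ...) {
  cat(sprintf("<fs_bayes:%s> %d markers, %d iterations (burn-in %d)\n",
              x$model, length(x$beta), x$n_iter, x$burn_in))
  invisible(x)
}

#' Default random-forest hyperparameter grid
#'
#' max_depth {3, 5, 10} x max_features {0.1, 0.5, sqrt, log2, none} x
#' n_estimators {100, 500, 1000}: 45 combinations, searched exhaustively.
#' @export
default_rf_grid <- function() {
  expand.grid(max_depth = c(3, 5, 10),
              max_features = c("0.1", "0.5", "sqrt", "log2", "none"),
              n_estimators = c(100, 500, 1000),
              stringsAsFactors = FALSE)
}

resolve_mtry <- function(max_features, p) {
  if (is.numeric(max_features)) return(max(1L, min(p, floor(max_features * p))))
  switch(as.character(max_features),
         sqrt = max(1L, floor(sqrt(p))),
         log2 = max(1L, floor(log2(p))),
         none = , `NULL` = p,
         max(1L, min(p, floor(as.numeric(max_features) * p))))
}

fit_rf_once <- function(X, y, max_depth, max_features, n_estimators,
                        min_split = 2L, min_leaf = 1L) {
  mtry <- resolve_mtry(max_features, ncol(X))
  ens <- cpp_forest_fit(X, y, as.integer(n_estimators), as.integer(mtry),
                        as.integer(max_depth), as.integer(min_split),
                        as.integer(min_leaf), TRUE)
  ens
}

fit_gbm_once <- function(X, y, max_depth, n_estimators, learning_rate,
                         subsample, colsample) {
  cpp_gbm_fit(X, y, as.integer(n_estimators), learning_rate,
              as.integer(max_depth), 2L, 1L, subsample, colsample)
}

#' Fit a tree-ensemble learner with hyperparameter search
#'
#' RF: exhaustive grid search scored by negative mean squared error under an
#' inner k-fold cross-validation; GBM: randomized search over the standard
#' continuous/integer ranges (learning_rate 0.01-0.4, max_depth 2-10,
#' subsample 0.5-1, colsample 0.7-1, n_estimators 5-500 step 5) scored by
#' mean R2. The winning combination is refit on all supplied rows.
#'
#' @param X,y training features and response.
#' @param algorithm `"RF"` or `"GBM"`.
#' @param grid data.frame of hyperparameter combinations (RF; default
#'   [default_rf_grid()]).
#' @param scheme a [split_scheme()] supplying fold count and seed.
#' @param n_search randomized-search draws for GBM (default 100).
#' @return an `fs_forest` fitted ensemble with `$tuning` (all evaluated
#'   combinations and scores), `$best_params`, `$validation_r2`,
#'   `$importance` (impurity-decrease, per-tree normalized, averaged).
#' @export
tree_fit <- function(X, y, algorithm = c("RF", "GBM"), grid = NULL,
                     scheme = split_scheme(), n_search = 100) {
  algorithm <- match.arg(algorithm)
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  n <- nrow(X)
  if (algorithm == "RF" && is.null(grid)) grid <- default_rf_grid()
  with_seed(derive_seed(scheme$seed, paste0("tree_", algorithm)), {
    folds <- fold_assignment(n, scheme$n_folds)
    if (min(table(folds)) < 2) stop("fold with fewer than 2 isolates")
    if (algorithm == "GBM") {
      grid <- data.frame(
        learning_rate = runif(n_search, 0.01, 0.4),
        max_depth = sample(2:10, n_search, replace = TRUE),
        subsample = runif(n_search, 0.5, 1.0),
        colsample = runif(n_search, 0.7, 1.0),
        n_estimators = 5L * sample.int(100L, n_search, replace = TRUE))
    }
    if (is.null(grid) || nrow(grid) == 0) stop("empty hyperparameter grid")

    scores <- numeric(nrow(grid))
    oof_best <- NULL
    for (g in seq_len(nrow(grid))) {
      oof <- rep(NA_real_, n)
      for (k in seq_len(scheme$n_folds)) {
        tr <- folds != k
        ens <- if (algorithm == "RF")
          fit_rf_once(X[tr, , drop = FALSE], y[tr], grid$max_depth[g],
                      grid$max_features[g], grid$n_estimators[g])
        else
          fit_gbm_once(X[tr, , drop = FALSE], y[tr], grid$max_depth[g],
                       grid$n_estimators[g], grid$learning_rate[g],
                       grid$subsample[g], grid$colsample[g])
        oof[!tr] <- cpp_ensemble_predict(ens$trees, X[!tr, , drop = FALSE],
                                         ens$tree_weight, ens$init)
      }
      scores[g] <- if (algorithm == "RF") -mean((y - oof)^2)
                   else r_squared(y, oof)
      if (g == 1 || scores[g] > max(scores[seq_len(g - 1)])) oof_best <- oof
    }
    best <- which.max(scores)
    ens <- if (algorithm == "RF")
      fit_rf_once(X, y, grid$max_depth[best], grid$max_features[best],
                  grid$n_estimators[best])
    else
      fit_gbm_once(X, y, grid$max_depth[best], grid$n_estimators[best],
                   grid$learning_rate[best], grid$subsample[best],
                   grid$colsample[best])
    structure(list(algorithm = algorithm, trees = ens$trees,
                   tree_weight = ens$tree_weight, init = ens$init,
                   importance = setNames(as.numeric(ens$importance), colnames(X)),
                   tuning = cbind(grid, score = scores),
                   best_params = grid[best, , drop = FALSE],
                   validation_r2 = r_squared(y, oof_best),
                   features = colnames(X), n_train = n),
              class = "fs_forest")
  })
}

#' @export
predict.fs_forest <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$features) && !is.null(colnames(newdata)))
    newdata <- newdata[, object$features, drop = FALSE]
  drop(cpp_ensemble_predict(object$trees, newdata, object$tree_weight,
                            object$init))
}

#' @export
print.fs_forest <- function(x, ...) {
  cat(sprintf("<fs_forest:%s> %d trees, %d features, validation R2 = %.3f\n",
              x$algorithm, length(x$trees), length(x$features),
              x$validation_r2))
  invisible(x)
}

#' Repeated cross-validation of one learner on one feature set
#'
#' The paper's evaluation design: with the holdout already removed, each
#' repeat re-randomizes the folds, fits the learner (tuning tree learners
#' inside the repeat's folds), and scores out-of-fold predictions against the
#' observed values; the validation R2 is the mean over repeats. The final
#' model is refit on the full training set using the best-validation repeat's
#' hyperparameters and, when a holdout is supplied, scored once on it.
#'
#' @param X,y training features and response (holdout excluded).
#' @param algorithm one of `"rrBLUP"`, `"BayesC"`, `"BayesianLASSO"`,
#'   `"RF"`, `"GBM"`.
#' @param scheme a [split_scheme()]; `n_repeats` follows the scheme.
#' @param X_test,y_test optional holdout for the single test-set evaluation.
#' @param environment,feature_type labels carried into the record.
#' @param ... passed to the underlying fitter ([tree_fit()] grid,
#'   [bayes_fit()] chain settings, ...).
#' @return an `fs_cv` object: `$record` (one-row performance data.frame),
#'   `$model` (final fitted model), `$per_repeat`, `$repeat_models` (for tree
#'   learners), `$train_ids` audit trail.
#' @export
cross_validate <- function(X, y, algorithm, scheme = split_scheme(),
                           X_test = NULL, y_test = NULL,
                           environment = NA_character_,
                           feature_type = NA_character_, ...) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(y) == n)
  is_tree <- algorithm %in% c("RF", "GBM")
  per_repeat <- numeric(scheme$n_repeats)
  repeat_models <- vector("list", scheme$n_repeats)

  for (r in seq_len(scheme$n_repeats)) {
    rep_seed <- derive_seed(scheme$seed, paste0("cv_repeat_", r))
    if (is_tree) {
      rep_scheme <- scheme
      rep_scheme$seed <- rep_seed
      fit <- tree_fit(X, y, algorithm, scheme = rep_scheme, ...)
      per_repeat[r] <- fit$validation_r2
      repeat_models[[r]] <- fit
    } else {
      oof <- rep(NA_real_, n)
      folds <- with_seed(rep_seed, fold_assignment(n, scheme$n_folds))
      if (min(table(folds)) < 2) stop("fold with fewer than 2 isolates")
      for (k in seq_len(scheme$n_folds)) {
        tr <- folds != k
        m <- switch(algorithm,
                    rrBLUP = rrblup_fit(X[tr, , drop = FALSE], y[tr]),
                    BayesC = bayes_fit(X[tr, , drop = FALSE], y[tr], "BayesC",
                                       seed = rep_seed + k, ...),
                    BayesianLASSO = bayes_fit(X[tr, , drop = FALSE], y[tr],
                                              "BayesianLASSO",
                                              seed = rep_seed + k, ...),
                    stop("unknown algorithm: ", algorithm))
        oof[!tr] <- predict(m, X[!tr, , drop = FALSE])
      }
      per_repeat[r] <- r_squared(y, oof)
    }
  }

  final <- if (is_tree) {
    best_rep <- which.max(per_repeat)
    fit <- repeat_models[[best_rep]]
    fit
  } else {
    switch(algorithm,
           rrBLUP = rrblup_fit(X, y),
           BayesC = bayes_fit(X, y, "BayesC",
                              seed = derive_seed(scheme$seed, "final"), ...),
           BayesianLASSO = bayes_fit(X, y, "BayesianLASSO",
                                     seed = derive_seed(scheme$seed, "final"), ...))
  }
  test_r2 <- if (!is.null(X_test))
    r_squared(y_test, predict(final, as.matrix(X_test))) else NA_real_

  record <- data.frame(environment = environment, feature_type = feature_type,
                       algorithm = algorithm,
                       validation_r2 = mean(per_repeat), test_r2 = test_r2,
                       n_features = ncol(X), stringsAsFactors = FALSE)
  structure(list(record = record, model = final, per_repeat = per_repeat,
                 repeat_models = if (is_tree) repeat_models,
                 train_ids = rownames(X), test_ids = rownames(X_test)),
            class = "fs_cv")
}

#' @export
print.fs_cv <- function(x, ...) {
  r <- x$record
  cat(sprintf("<fs_cv> %s on %s: validation R2 = %.3f (%d repeats), test R2 = %s\n",
              r$algorithm, r$feature_type, r$validation_r2,
              length(x$per_repeat),
              ifelse(is.na(r$test_r2), "-", sprintf("%.3f", r$test_r2))))
  invisible(x)
}
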