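#' Per-isolate Shapley attributions from a fitted model
#'
#' Tree ensembles use the exact polynomial-time tree-path Shapley algorithm
#' (attributions over the tree's cover-weighted conditional expectations);
#' linear models (rrBLUP, Bayesian regressions) use exact linear
#' attributions, weight x (feature - training mean). Local accuracy — base
#' value plus the attribution row equals the model prediction — is asserted
#' for every row at tolerance 1e-6.
#'
#' @param model an `fs_forest`, `fs_rrblup` or `fs_bayes` fit (or an `fs_cv`
#'   wrapper, in which case its final model is used).
#' @param X isolate x feature matrix on the model's features.
#' @return `fs_shap`: `phi` (isolate x feature attributions), `base`,
#'   `model_id`.
#' @export
compute_shap <- function(model, X) {
  if (inherits(model, "fs_cv")) model <- model$model
  X <- as.matrix(X)
  if (!is.null(model$features) && !is.null(colnames(X)))
    X <- X[, model$features, drop = FALSE]
  if (inherits(model, "fs_forest")) {
    res <- cpp_tree_shap_matrix(model$trees, X, model$tree_weight, model$init)
    phi <- res$phi
    base <- res$base
  } else if (inherits(model, c("fs_rrblup", "fs_bayes"))) {
    w <- if (inherits(model, "fs_rrblup")) model$u else model$beta
    phi <- sweep(X, 2, model$feature_means) * rep(w, each = nrow(X))
    base <- model$mu + sum(w * model$feature_means)
  } else stop("SHAP attributions require a tree-ensemble or linear model fit")
  dimnames(phi) <- dimnames(X)
  pred <- predict(model, X)
  gap <- max(abs(base + rowSums(phi) - pred))
  if (is.na(gap) || gap > 1e-6)
    stop("local accuracy violated: max |base + sum(phi) - prediction| = ", gap)
  structure(list(phi = phi, base = base,
                 model_id = class(model)[1]), class = "fs_shap")
}

#' @export
print.fs_shap <- function(x, ...) {
  cat(sprintf("<fs_shap> %d isolates x %d features, base = %.4g\n",
              nrow(x$phi), ncol(x$phi), x$base))
  invisible(x)
}

#' Global feature importance from mean absolute SHAP values
#'
#' Mean |phi| per feature across isolates; features never used (zero
#' importance) are dropped before ranking; ties receive average ranks.
#' @param shap an `fs_shap`.
#' @return data.frame(feature, importance, rank).
#' @export
global_importance_rank <- function(shap) {
  imp <- colMeans(abs(shap$phi))
  imp <- imp[imp > 0]
  if (!length(imp))
    return(data.frame(feature = character(), importance = numeric(),
                      rank = numeric(), stringsAsFactors = FALSE))
  out <- data.frame(feature = names(imp), importance = unname(imp),
                    rank = rank(-imp, ties.method = "average"),
                    stringsAsFactors = FALSE)
  out[order(-out$importance, out$feature), , drop = FALSE]
}

#' Spearman rank correlation between two importance tables
#'
#' Joins two importance tables on their shared keys (features, or genes
#' after taking per-gene maxima through a feature-to-gene map) and reports
#' Spearman's rho with a two-sided p. Zero-importance entries are expected
#' to have been dropped upstream.
#'
#' @param table_a,table_b data.frames with `feature` and `importance`.
#' @param join_on `"feature"` or `"gene"`.
#' @param gene_map optional data.frame(feature, gene) required for gene-level
#'   joins.
#' @return list(rho, p, n_shared).
#' @export
rank_correlation <- function(table_a, table_b, join_on = c("feature", "gene"),
                             gene_map = NULL) {
  join_on <- match.arg(join_on)
  to_keyed <- function(tab) {
    if (join_on == "feature")
      return(setNames(tab$importance, tab$feature))
    stopifnot(!is.null(gene_map))
    m <- merge(tab, gene_map[, c("feature", "gene")], by = "feature")
    agg <- tapply(m$importance, m$gene, max)
    setNames(as.numeric(agg), names(agg))
  }
  a <- to_keyed(table_a)
  b <- to_keyed(table_b)
  shared <- intersect(names(a), names(b))
  if (length(shared) < 3)
    return(list(rho = NA_real_, p = NA_real_, n_shared = length(shared)))
  ct <- suppressWarnings(cor.test(a[shared], b[shared], method = "spearman",
                                  exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n_shared = length(shared))
}

#' Hierarchical clustering of isolates by their SHAP profiles
#'
#' Restricts the attribution matrix to the top `k` features by mean |phi|,
#' then clusters isolates with Ward linkage on Euclidean distances
#' (ward.D2, the squared-increment Ward variant used by scipy). Clusters are
#' labeled by cutting the tree at `threshold` (tree height) or into
#' `n_clusters` groups (default 8 when neither is given). Features are also
#' clustered for display.
#'
#' @param shap an `fs_shap`.
#' @param k number of top features to keep (default 20, capped with a
#'   warning when fewer are available).
#' @param threshold distance threshold at which to cut the tree.
#' @param n_clusters alternative: number of clusters.
#' @return `fs_clustering`: linkage (hclust), labels (contiguous from 1),
#'   threshold, features used, feature linkage.
#' @export
cluster_isolates_by_shap <- function(shap, k = 20, threshold = NULL,
                                     n_clusters = NULL) {
  imp <- colMeans(abs(shap$phi))
  if (k > length(imp)) {
    warning("k exceeds available features; capped at ", length(imp))
    k <- length(imp)
  }
  top <- names(sort(imp, decreasing = TRUE))[seq_len(k)]
  m <- shap$phi[, top, drop = FALSE]
  hc <- hclust(dist(m, method = "euclidean"), method = "ward.D2")
  if (is.null(threshold) && is.null(n_clusters)) n_clusters <- 8L
  labels <- if (!is.null(threshold)) cutree(hc, h = threshold)
            else cutree(hc, k = min(n_clusters, nrow(m)))
  labels <- as.integer(factor(labels, levels = unique(labels[hc$order])))
  names(labels) <- rownames(m)
  feat_hc <- if (ncol(m) >= 2)
    hclust(dist(t(m), method = "euclidean"), method = "ward.D2")
  structure(list(linkage = hc, labels = labels, threshold = threshold,
                 method = "ward", metric = "euclidean", features = top,
                 feature_linkage = feat_hc),
            class = "fs_clustering")
}

#' @export
print.fs_clustering <- function(x, ...) {
  cat(sprintf("<fs_clustering> %d isolates in %d clusters (%s/%s)\n",
              length(x$labels), length(unique(x$labels)), x$method, x$metric))
  invisible(x)
}

#' @export
plot.fs_clustering <- function(x, ...) {
  graphics::plot(x$linkage, labels = FALSE, hang = -1,
                 main = "isolates by SHAP profile", ...)
  if (!is.null(x$threshold)) graphics::abline(h = x$threshold, lty = 2)
  invisible(x)
}

#' Relationship between SHAP magnitude and fitness across clusters
#'
#' For each isolate, x is the median |phi| over the clustering's top
#' features and y is the median fitness of the isolate's cluster (the
#' cluster median is replicated to every member so the regression is
#' well-posed); an ordinary least-squares line is fit and the p-value for
#' zero slope comes from the Wald t-test.
#'
#' @param clustering an `fs_clustering`.
#' @param shap the `fs_shap` the clustering was built from.
#' @param fitness numeric vector of fitness values named by isolate, or an
#'   `fs_fitness` plus `environment`.
#' @param environment environment name when `fitness` is a table.
#' @return list(slope, intercept, r, p, n_clusters).
#' @export
cluster_fitness_trend <- function(clustering, shap, fitness,
                                  environment = NULL) {
  if (inherits(fitness, "fs_fitness")) {
    stopifnot(!is.null(environment))
    fitness <- setNames(fitness$values[, environment], fitness$isolates)
  }
  labels <- clustering$labels
  if (length(unique(labels)) < 2)
    stop("cluster-fitness trend is undefined with a single cluster")
  m <- abs(shap$phi[names(labels), clustering$features, drop = FALSE])
  x <- apply(m, 1, median)
  cluster_median <- tapply(fitness[names(labels)], labels, median)
  y <- as.numeric(cluster_median[as.character(labels)])
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))
  slope <- unname(coef(fit)[2])
  p <- if (nrow(sm$coefficients) > 1 && !is.na(slope) &&
           sm$coefficients[2, 2] > 0) sm$coefficients[2, 4] else NA_real_
  if (!is.na(slope) && sd(y) == 0) { slope <- 0; p <- 1 }
  list(slope = if (is.na(slope)) 0 else slope,
       intercept = unname(coef(fit)[1]),
       r = if (sd(x) > 0 && sd(y) > 0) cor(x, y) else 0,
       p = p, n_clusters = length(unique(labels)))
}
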