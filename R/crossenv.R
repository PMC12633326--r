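#' Cluster environments by fitness correlation
#'
#' Pairwise Pearson correlations between environments (pairwise-complete
#' isolates), hierarchical clustering on Euclidean distances between the
#' correlation-profile rows, and the coarsest partition in which every
#' within-cluster pair correlates above `r_threshold`.
#'
#' @param fitness an `fs_fitness` (or plain isolate x environment matrix).
#' @param r_threshold minimum within-cluster pairwise correlation (default
#'   0.51).
#' @return `fs_envclust`: `r` matrix, `linkage`, `clusters` (named integer
#'   labels), `threshold`.
#' @export
environment_clusters <- function(fitness, r_threshold = 0.51) {
  m <- if (inherits(fitness, "fs_fitness")) fitness$values else as.matrix(fitness)
  if (ncol(m) < 2) stop("need at least 2 environments")
  constant <- apply(m, 2, function(x) sd(x, na.rm = TRUE) == 0)
  if (any(constant))
    warning("constant environment column(s): ",
            paste(colnames(m)[constant], collapse = ", "),
            " (correlations undefined)")
  r <- suppressWarnings(cor(m, use = "pairwise.complete.obs"))
  r_dist <- r
  r_dist[is.na(r_dist)] <- 0     # undefined correlations carry no affinity
  hc <- hclust(dist(r_dist, method = "euclidean"), method = "average")
  n_env <- ncol(m)
  labels <- NULL
  for (k in seq_len(n_env)) {
    cand <- cutree(hc, k = k)
    ok <- all(vapply(unique(cand), function(cl) {
      idx <- which(cand == cl)
      if (length(idx) < 2) return(TRUE)
      pairs <- r[idx, idx][lower.tri(diag(length(idx)))]
      all(!is.na(pairs) & pairs > r_threshold)
    }, TRUE))
    if (ok) { labels <- cand; break }
  }
  if (is.null(labels)) labels <- setNames(seq_len(n_env), colnames(m))
  structure(list(r = r, linkage = hc, clusters = labels,
                 threshold = r_threshold), class = "fs_envclust")
}

#' @export
print.fs_envclust <- function(x, ...) {
  cat(sprintf("<fs_envclust> %d environments, %d clusters (min within r > %.2f)\n",
              ncol(x$r), length(unique(x$clusters)), x$threshold))
  invisible(x)
}

#' Permutation test for cross-environment gene sharing
#'
#' The observed statistic is, per gene, the number of environments sharing it
#' (row sums of the binary gene x environment presence matrix). The null
#' shuffles each environment column independently; per-permutation median
#' row-sums are recorded, and the observed count distribution is compared to
#' the pooled permuted count distribution with a one-sided two-sample
#' Kolmogorov-Smirnov test whose alternative ("greater", the default) is
#' that observed sharing is stochastically greater than the null. (Testing
#' against the null *medians* alone degenerates to a spread-versus-point-mass
#' comparison that rejects regardless of sharing; the pooled exchangeable
#' null keeps the test calibrated — see the methods vignette.)
#'
#' @param presence binary gene x environment matrix.
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed.
#' @param alternative `"greater"` (observed sharing exceeds null) or
#'   `"two.sided"`.
#' @param max_pooled cap on the pooled null sample size used by the KS test.
#' @return `fs_permtest`: observed counts, null medians, KS statistic, p.
#' @export
gene_presence_permutation_test <- function(presence, n_perm = 10000, seed = 1L,
                                           alternative = c("greater", "two.sided"),
                                           max_pooled = 2e6) {
  alternative <- match.arg(alternative)
  m <- as.matrix(presence)
  if (!all(m %in% c(0, 1))) stop("presence matrix must be binary")
  observed <- rowSums(m)
  n_pool <- max(1L, min(n_perm, floor(max_pooled / nrow(m))))
  res <- with_seed(derive_seed(seed, "presence_perm"), {
    null_medians <- numeric(n_perm)
    pooled <- vector("list", n_pool)
    for (b in seq_len(n_perm)) {
      rs <- rowSums(apply(m, 2, sample))
      null_medians[b] <- median(rs)
      if (b <= n_pool) pooled[[b]] <- rs
    }
    list(null_medians = null_medians, pooled = unlist(pooled))
  })
  # R parameterization: "less" = CDF of x below y = x stochastically greater
  ks_alt <- if (alternative == "greater") "less" else "two.sided"
  ks <- suppressWarnings(ks.test(observed, res$pooled, alternative = ks_alt))
  structure(list(observed = observed, null_medians = res$null_medians,
                 statistic = unname(ks$statistic), p = ks$p.value,
                 n_perm = n_perm),
            class = "fs_permtest")
}

#' @export
print.fs_permtest <- function(x, ...) {
  cat(sprintf("<fs_permtest> D = %.3f, p = %.3g (%d permutations)\n",
              x$statistic, x$p, x$n_perm))
  invisible(x)
}

#' Rank correlation of features shared between two environments
#'
#' Features present in both importance vectors and non-zero in at least one
#' are ranked per environment; Spearman's rho is reported on that shared set.
#'
#' @param rank_a,rank_b named numeric importance vectors (or importance
#'   tables with `feature` and `importance`).
#' @return list(rho, p, n_shared).
#' @export
shared_feature_correlation <- function(rank_a, rank_b) {
  as_vec <- function(x) {
    if (is.data.frame(x)) setNames(x$importance, x$feature) else x
  }
  a <- as_vec(rank_a); b <- as_vec(rank_b)
  shared <- intersect(names(a), names(b))
  shared <- shared[a[shared] != 0 | b[shared] != 0]
  if (length(shared) < 3)
    return(list(rho = NA_real_, p = NA_real_, n_shared = length(shared)))
  ct <- suppressWarnings(cor.test(a[shared], b[shared], method = "spearman",
                                  exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n_shared = length(shared))
}

#' Meta-regression of model performance on heritability and fitness moments
#'
#' OLS with the full three-way factorial design
#' y = b0 + b1 xh + b2 xm + b3 xv + b4 xh xm + b5 xh xv + b6 xm xv
#' + b7 xh xm xv + e, where xh is heritability, xm median fitness and xv
#' fitness variance per environment. Per-observation linear attributions are
#' coefficient x (term - term mean), which sum (plus the intercept-at-means)
#' to the fitted value.
#'
#' @param performance per-environment model performance (the response y).
#' @param h2,med_fitness,var_fitness per-environment predictors.
#' @return `fs_metareg`: coefficients, adjusted R2, attributions matrix,
#'   fitted lm.
#' @export
performance_meta_regression <- function(performance, h2, med_fitness,
                                        var_fitness) {
  n <- length(performance)
  stopifnot(length(h2) == n, length(med_fitness) == n, length(var_fitness) == n)
  if (n < 9) stop("need at least 9 environments to fit 8 coefficients")
  df <- data.frame(y = performance, xh = h2, xm = med_fitness, xv = var_fitness)
  fit <- lm(y ~ xh * xm * xv, data = df)
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("rank-deficient design; collinear term(s): ",
         paste(bad, collapse = ", "))
  }
  mm <- stats::model.matrix(fit)[, -1, drop = FALSE]
  centered <- sweep(mm, 2, colMeans(mm))
  attributions <- sweep(centered, 2, coef(fit)[-1], `*`)
  sm <- suppressWarnings(summary(fit))
  structure(list(coefficients = coef(fit),
                 adj_r2 = sm$adj.r.squared,
                 r2 = sm$r.squared,
                 attributions = attributions,
                 base = mean(fitted(fit)), fit = fit),
            class = "fs_metareg")
}

#' @export
print.fs_metareg <- function(x, ...) {
  cat(sprintf("<fs_metareg> adj R2 = %.3f\n", x$adj_r2))
  print(round(x$coefficients, 4))
  invisible(x)
}
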