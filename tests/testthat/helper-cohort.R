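# Shared fixtures: everything is generated in code at test time.

small_cohort <- function(n = 120, snps = 200, orfs = 50, envs = 2, h2 = 0.6,
                         qtl = 8, seed = 11, missing_rate = 0.01, fst = 0.15) {
  simulate_cohort(
    population_config(n_isolates = n, n_snps = snps, n_orfs = orfs,
                      fst = fst, missing_rate = missing_rate, seed = seed),
    trait_architecture(n_environments = envs, n_additive_qtl = qtl,
                       n_dominance_qtl = 2, target_h2 = h2))
}

toy_geno <- function(dosages, chrom = "chr01") {
  m <- as.matrix(dosages)
  snps <- data.frame(id = sprintf("snp_%05d", seq_len(ncol(m))),
                     chrom = chrom, pos = seq_len(ncol(m)) * 100L,
                     ref = "A", alt = "G", stringsAsFactors = FALSE)
  new_genotype_matrix(m, sprintf("iso_%04d", seq_len(nrow(m))), snps, "raw012")
}

# fit a small forest directly (test-only shortcut around tree_fit's CV)
raw_forest <- function(X, y, max_depth = 6, max_features = "0.5",
                       n_estimators = 60, seed = 1) {
  fit <- fitscape:::with_seed(seed, fitscape:::fit_rf_once(
    as.matrix(X), y, max_depth, max_features, n_estimators))
  structure(list(algorithm = "RF", trees = fit$trees,
                 tree_weight = fit$tree_weight, init = fit$init,
                 importance = stats::setNames(as.numeric(fit$importance),
                                              colnames(X)),
                 features = colnames(X)),
            class = "fs_forest")
}

# Conditional expectation of a tree given a feature subset S (1-based), by
# cover-weighted descent -- the oracle primitive for brute-force Shapley.
tree_expvalue <- function(tree, x, S) {
  rec <- function(node) {
    f <- tree[node, 1]
    if (f < 0) return(tree[node, 5])
    l <- tree[node, 3] + 1; r <- tree[node, 4] + 1
    if ((f + 1) %in% S) {
      if (x[f + 1] <= tree[node, 2]) rec(l) else rec(r)
    } else {
      (tree[l, 6] * rec(l) + tree[r, 6] * rec(r)) / tree[node, 6]
    }
  }
  rec(1)
}

# Exact Shapley values by enumeration over all feature orderings.
brute_force_shapley <- function(model, x, p) {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (rest in perms(v[-i]))
      out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  all_orders <- perms(seq_len(p))
  phi <- numeric(p)
  for (tr in model$trees) for (ord in all_orders) {
    S <- integer(0)
    for (j in ord) {
      phi[j] <- phi[j] + model$tree_weight *
        (tree_expvalue(tr, x, c(S, j)) - tree_expvalue(tr, x, S)) /
        length(all_orders)
      S <- c(S, j)
    }
  }
  phi
}

expect_psd <- function(m, tol = 1e-8) {
  ev <- eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -tol)
}
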