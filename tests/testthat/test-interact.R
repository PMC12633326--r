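test_that("reduced feature sets follow the three-set arithmetic", {
  reps <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                     feature = c("f1", "f2", "f3", "f4"),
                     importance = c(4, 3, 2, 1))
  sets <- build_reduced_feature_sets(reps, benchmark = "g1",
                                     important_genes = c("g2", "g3"))
  expect_setequal(sets$combined, c("f1", "f2", "f3"))
  expect_setequal(sets$non_benchmark, c("f2", "f3"))
  expect_setequal(sets$benchmark, "f1")
  # a gene that is both benchmark and important appears once
  sets2 <- build_reduced_feature_sets(reps, benchmark = c("g1", "g2"),
                                      important_genes = c("g2", "g3"))
  expect_setequal(sets2$combined, c("f1", "f2", "f3"))
  expect_setequal(sets2$non_benchmark, "f3")
  expect_error(build_reduced_feature_sets(reps, "gX", "g2"),
               "no benchmark gene")
})

test_that("interaction tensors satisfy symmetry, row sums, and additivity", {
  set.seed(81)
  n <- 60
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(paste0("i", 1:n),
                                                  paste0("f", 1:5)))
  # additive ground truth: off-diagonal mass is a small fraction of diagonal
  y_add <- X[, 1] + 2 * X[, 2] + rnorm(n, 0, 0.02)
  rf <- raw_forest(X, y_add, max_depth = 3, max_features = "none",
                   n_estimators = 100, seed = 81)
  it <- shap_interaction_tensor(rf, X)
  s <- apply(abs(it$tensor), c(2, 3), mean)
  expect_lt(mean(s[upper.tri(s)]) , 0.05 * mean(diag(s)))
  # hard identities (also asserted internally)
  expect_equal(it$tensor, aperm(it$tensor, c(1, 3, 2)), tolerance = 1e-12)
  expect_equal(apply(it$tensor, c(1, 2), sum), it$phi$phi, tolerance = 1e-8)
  # a planted product term ranks first among feature pairs
  y_int <- 2 * X[, 3] * X[, 4] + rnorm(n, 0, 0.05)
  rf2 <- raw_forest(X, y_int, max_depth = 3, max_features = "none",
                    n_estimators = 100, seed = 82)
  ps <- interaction_pair_scores(shap_interaction_tensor(rf2, X))
  expect_setequal(c(ps$feature_a[1], ps$feature_b[1]), c("f3", "f4"))
  expect_error(shap_interaction_tensor(rf2, X, max_features = 3), "cap")
  expect_error(shap_interaction_tensor(rrblup_fit(X, y_add), X),
               "tree-ensemble")
})

test_that("feature-pair interactions aggregate to unordered gene pairs", {
  tensor <- array(0, c(2, 4, 4), dimnames = list(
    c("i1", "i2"), paste0("f", 1:4), paste0("f", 1:4)))
  tensor[, 1, 2] <- tensor[, 2, 1] <- 0.5
  tensor[, 3, 4] <- tensor[, 4, 3] <- 0.2
  tensor[, 1, 3] <- tensor[, 3, 1] <- 0.1
  phi <- structure(list(phi = apply(tensor, c(1, 2), sum), base = 0),
                   class = "fs_shap")
  it <- structure(list(tensor = tensor, phi = phi, features = paste0("f", 1:4)),
                  class = "fs_interaction")
  gm <- data.frame(feature = paste0("f", 1:4),
                   gene = c("gA", "gB", "gA", "gC"),
                   unmapped = FALSE, multi = FALSE)
  pairs <- interactions_to_gene_pairs(list(`SNP-SNP` = it), gm)
  # f1-f2 -> gA-gB (0.5); f3-f4 -> gA-gC (0.2); f1-f3 same gene -> dropped
  expect_equal(nrow(pairs), 2)
  expect_equal(pairs$score[pairs$gene_a == "gA" & pairs$gene_b == "gB"], 0.5)
  expect_equal(pairs$rank, rank(-pairs$score))
  # two variant kinds mapping to one gene pair: one row per kind
  pairs2 <- interactions_to_gene_pairs(list(`SNP-SNP` = it, `CNV-CNV` = it), gm)
  gAgB <- pairs2[pairs2$gene_a == "gA" & pairs2$gene_b == "gB", ]
  expect_setequal(gAgB$kind, c("SNP-SNP", "CNV-CNV"))
  # unmapped features are skipped and counted
  gm2 <- gm; gm2$unmapped[4] <- TRUE
  pairs3 <- interactions_to_gene_pairs(list(k = it), gm2)
  expect_equal(nrow(pairs3), 1)
  expect_gt(attr(pairs3, "n_skipped"), 0)
})

test_that("validated-network overlap applies the confidence filter and enriches", {
  net <- data.frame(gene_a = c("g1", "g2", "g3"),
                    gene_b = c("g2", "g3", "g4"),
                    eps = c(0.3, 0.10, -0.4), p = c(0.01, 0.04, 0.02))
  kept <- filter_network_edges(net)
  expect_equal(nrow(kept), 2)              # |eps| = 0.10 fails the 0.12 rule
  expect_false(any(kept$eps == 0.10))
  pairs <- data.frame(gene_a = c("g1", "g3", "g5", "g6"),
                      gene_b = c("g2", "g4", "g6", "g7"),
                      score = c(4, 3, 2, 1))
  ov <- validated_overlap_enrichment(pairs, kept, percentiles = 50)
  expect_equal(ov$overlap, 2)
  expect_equal(ov$n_pairs, 4)
  # network covering every predicted pair: trivial enrichment at any cut
  ov2 <- validated_overlap_enrichment(pairs, pairs[, 1:2], percentiles = c(25, 50))
  expect_equal(ov2$overlap, 4)
  expect_error(validated_overlap_enrichment(pairs, net[0, ]), "empty")
})

test_that("genotype-stratified summaries match hand-computed percentiles", {
  phi <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12), 12, 1,
                dimnames = list(paste0("i", 1:12), "fA"))
  sh <- structure(list(phi = phi, base = 0), class = "fs_shap")
  geno <- matrix(c(rep(0, 6), rep(2, 6)), 12, 1,
                 dimnames = list(rownames(phi), "fA"))
  tab <- genotype_stratified_summary(sh, "fA", genotypes = geno)
  expect_equal(tab$median, c(3.5, 9.5))
  expect_equal(tab$q25, unname(c(quantile(1:6, 0.25), quantile(7:12, 0.25))))
  expect_equal(tab$q75, unname(c(quantile(1:6, 0.75), quantile(7:12, 0.75))))
  # single isolate per stratum: degenerate quartiles
  solo <- genotype_stratified_summary(sh, "fA",
                                      genotypes = matrix(1:12, 12, 1,
                                                         dimnames = dimnames(geno)))
  expect_equal(solo$median, 1:12)
  expect_true(all(solo$q75 - solo$q25 == 0))
})

test_that("distance clustering contrasts benchmark SHAP against the reference", {
  set.seed(83)
  n <- 90
  # two well-separated genetic backgrounds; reference sits in background 1
  bg <- rep(c(0, 1), c(45, 45))
  prof <- matrix(rnorm(n * 30, mean = bg * 6), n, 30,
                 dimnames = list(paste0("i", 1:n), NULL))
  prof[1:45, ] <- prof[1:45, ] * 0.2
  dm <- distance_matrix(rbind(prof, S288C = rep(0, 30)))
  phi <- matrix(rnorm(n * 4, sd = 0.05), n, 4,
                dimnames = list(paste0("i", 1:n), paste0("b", 1:4)))
  phi[bg == 0, ] <- phi[bg == 0, ] + 1     # benchmark effects near reference
  sh <- structure(list(phi = phi, base = 0), class = "fs_shap")
  res <- distance_cluster_benchmark_test(dm, sh, paste0("b", 1:4), "S288C",
                                         k_range = 2:6, seed = 3)
  expect_equal(res$k, 2)
  expect_equal(unname(res$labels["S288C"]), unname(res$reference_cluster))
  expect_lt(res$p, 0.05)
  # identical SHAP distributions: p is not small
  phi0 <- matrix(0.3, n, 4, dimnames = dimnames(phi))
  sh0 <- structure(list(phi = phi0, base = 0), class = "fs_shap")
  res0 <- distance_cluster_benchmark_test(dm, sh0, paste0("b", 1:4), "S288C",
                                          k_range = 2:6, seed = 3)
  expect_gt(res0$p, 0.2)
  expect_error(distance_cluster_benchmark_test(dm, sh, "missing_feat", "S288C"),
               "absent from attributions")
  expect_error(distance_cluster_benchmark_test(dm, sh, "b1", "nope"),
               "absent from the distance matrix")
})

test_that("benchmark ablation ordering holds when benchmarks are causal", {
  r2s <- sapply(1:3, function(s) {
    coh <- small_cohort(n = 160, snps = 120, envs = 1, h2 = 0.7, qtl = 6,
                        seed = 200 + s, missing_rate = 0)
    X <- coh$geno$dosages
    y <- coh$fitness$values[, 1]
    causal <- vapply(coh$truth$environments[[1]]$additive, `[[`, "", "feature")
    noncausal <- setdiff(colnames(X), causal)
    sch <- split_scheme(n_repeats = 1, seed = s)
    sp <- split_holdout(rownames(X), sch)
    grid <- data.frame(max_depth = 6, max_features = "0.5", n_estimators = 50)
    fit_on <- function(feats) {
      cv <- cross_validate(X[sp$train, feats, drop = FALSE], y[sp$train], "RF",
                           sch, X[sp$test, feats, drop = FALSE], y[sp$test],
                           grid = grid)
      cv$record$test_r2
    }
    combined <- fit_on(c(causal, noncausal[1:20]))
    bench_only <- fit_on(causal)
    random_set <- fit_on(fitscape:::with_seed(s, sample(noncausal, length(causal))))
    c(combined = combined, bench = bench_only, random = random_set)
  })
  # benchmark-only (causal) beats random equal-size sets on average
  expect_gt(mean(r2s["bench", ] - r2s["random", ]), 0)
  # combined does not fall materially below benchmark-only
  expect_gt(mean(r2s["combined", ] - r2s["bench", ]), -0.1)
})
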