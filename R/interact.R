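#' Benchmark-ablation feature sets
#'
#' Builds the three reduced gene-level feature sets used to probe what
#' benchmark genes contribute to prediction: (1) important non-benchmark
#' genes plus benchmark genes, (2) important non-benchmark genes only,
#' (3) benchmark genes only. Each gene is represented by a single feature
#' (see [gene_representative_feature()]); a gene that is both benchmark and
#' important appears once in the combined set.
#'
#' @param representatives data.frame(gene, feature, importance) over all
#'   mapped genes (from the complete-model representatives).
#' @param benchmark an `fs_benchmark` or character vector of benchmark genes.
#' @param important_genes genes selected by the optimized models.
#' @return list of three character feature-id vectors: `combined`,
#'   `non_benchmark`, `benchmark` (plus matching `$genes`).
#' @export
build_reduced_feature_sets <- function(representatives, benchmark,
                                       important_genes) {
  bench_genes <- if (inherits(benchmark, "fs_benchmark")) benchmark$genes else benchmark
  bench_avail <- intersect(bench_genes, representatives$gene)
  if (!length(bench_avail))
    stop("no benchmark gene has a mapped representative feature")
  nonbench <- setdiff(intersect(important_genes, representatives$gene),
                      bench_genes)
  combined_genes <- union(nonbench, bench_avail)
  feat_of <- function(genes)
    representatives$feature[match(genes, representatives$gene)]
  list(combined = feat_of(combined_genes),
       non_benchmark = feat_of(nonbench),
       benchmark = feat_of(bench_avail),
       genes = list(combined = combined_genes, non_benchmark = nonbench,
                    benchmark = bench_avail))
}

#' Pairwise Shapley interaction values for a tree ensemble
#'
#' Decomposes each isolate's attribution vector into main (diagonal) and
#' pairwise interaction (off-diagonal) effects via conditioned re-runs of the
#' tree-path Shapley algorithm. The tensor is symmetric in its feature axes
#' and each row sums back to the plain attribution (both identities are
#' asserted at 1e-6).
#'
#' @param model an `fs_forest` (tree ensembles only).
#' @param X isolate x feature matrix.
#' @param max_features guard against the quadratic cost (default 500).
#' @return `fs_interaction`: `tensor` (isolate x feature x feature),
#'   `phi` (the matching `fs_shap`), feature ids.
#' @export
shap_interaction_tensor <- function(model, X, max_features = 500) {
  if (inherits(model, "fs_cv")) model <- model$model
  if (!inherits(model, "fs_forest"))
    stop("interaction values require a tree-ensemble model")
  X <- as.matrix(X)
  if (!is.null(model$features) && !is.null(colnames(X)))
    X <- X[, model$features, drop = FALSE]
  if (ncol(X) > max_features)
    stop("feature count ", ncol(X), " exceeds the interaction cap (",
         max_features, "); use a reduced feature set")
  tensor <- cpp_shap_interaction_tensor(model$trees, X, model$tree_weight,
                                        model$init)
  dimnames(tensor) <- list(rownames(X), colnames(X), colnames(X))
  shap <- compute_shap(model, X)
  # hard identities: symmetry and row-sum reconciliation
  sym_gap <- max(abs(tensor - aperm(tensor, c(1, 3, 2))))
  row_gap <- max(abs(apply(tensor, c(1, 2), sum) - shap$phi))
  if (sym_gap > 1e-6 || row_gap > 1e-6)
    stop(sprintf("interaction identities violated (symmetry %g, row sums %g)",
                 sym_gap, row_gap))
  structure(list(tensor = tensor, phi = shap, features = colnames(X)),
            class = "fs_interaction")
}

#' @export
print.fs_interaction <- function(x, ...) {
  d <- dim(x$tensor)
  cat(sprintf("<fs_interaction> %d isolates x %d x %d features\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' Mean absolute interaction score per feature pair
#' @param interaction an `fs_interaction`.
#' @return data.frame(feature_a, feature_b, score) for all unordered pairs,
#'   sorted by descending score.
#' @export
interaction_pair_scores <- function(interaction) {
  s <- apply(abs(interaction$tensor), c(2, 3), mean)
  feats <- interaction$features
  idx <- which(upper.tri(s) & s > 0, arr.ind = TRUE)
  out <- data.frame(feature_a = feats[idx[, 1]], feature_b = feats[idx[, 2]],
                    score = s[idx], stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$feature_a, out$feature_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate feature-pair interactions to gene pairs
#'
#' Maps each scored feature pair to its gene pair (dropping pairs with an
#' unmapped feature or with both features in the same gene), annotates the
#' variant-pair kind, and ranks by score within each source model; pairs
#' supported by several variant-kind combinations are reported once per kind.
#'
#' @param interactions named list of `fs_interaction` (name = variant-pair
#'   kind, e.g. `"SNP-SNP"`, `"SNP-CNV"`), or a single `fs_interaction`.
#' @param gene_map data.frame(feature, gene, unmapped, multi) covering the
#'   features.
#' @return data.frame(gene_a, gene_b, kind, score, rank, n_skipped attr).
#' @export
interactions_to_gene_pairs <- function(interactions, gene_map) {
  if (inherits(interactions, "fs_interaction"))
    interactions <- list(pair = interactions)
  mapped <- gene_map[!gene_map$unmapped & !gene_map$multi &
                       !is.na(gene_map$gene), , drop = FALSE]
  lookup <- setNames(mapped$gene, mapped$feature)
  n_skipped <- 0L
  rows <- list()
  for (kind in names(interactions)) {
    ps <- interaction_pair_scores(interactions[[kind]])
    ga <- lookup[ps$feature_a]
    gb <- lookup[ps$feature_b]
    bad <- is.na(ga) | is.na(gb)
    n_skipped <- n_skipped + sum(bad)
    ps <- ps[!bad, , drop = FALSE]; ga <- ga[!bad]; gb <- gb[!bad]
    same <- ga == gb
    ps <- ps[!same, , drop = FALSE]; ga <- ga[!same]; gb <- gb[!same]
    if (!nrow(ps)) next
    lo <- pmin(ga, gb); hi <- pmax(ga, gb)
    df <- data.frame(gene_a = lo, gene_b = hi, kind = kind,
                     score = ps$score, stringsAsFactors = FALSE)
    # one row per gene pair per kind: keep the strongest supporting pair
    df <- df[order(-df$score), , drop = FALSE]
    df <- df[!duplicated(paste(df$gene_a, df$gene_b)), , drop = FALSE]
    df$rank <- rank(-df$score, ties.method = "average")
    rows[[kind]] <- df
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_a = character(), gene_b = character(),
                      kind = character(), score = numeric(), rank = numeric(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Filter a validated genetic-interaction edge list by confidence
#'
#' Applies the stringent screen threshold: interaction p below `max_p` and
#' absolute interaction score epsilon above `min_eps`. Edges without
#' epsilon/p columns pass unfiltered.
#' @param network data.frame(gene_a, gene_b, and optionally eps, p).
#' @param max_p,min_eps thresholds (defaults 0.05 and 0.12).
#' @export
filter_network_edges <- function(network, max_p = 0.05, min_eps = 0.12) {
  if (!all(c("eps", "p") %in% names(network))) return(network)
  network[network$p < max_p & abs(network$eps) > min_eps, , drop = FALSE]
}

normalize_edges <- function(network) {
  lo <- pmin(network$gene_a, network$gene_b)
  hi <- pmax(network$gene_a, network$gene_b)
  unique(paste(lo, hi, sep = "\r"))
}

#' Overlap and enrichment of predicted gene pairs in a validated network
#'
#' Counts predicted pairs present in the validated edge list and tests, at
#' each rank percentile of the predicted-pair ranking, whether validated
#' edges are enriched among the top pairs (Fisher 2x2 over the scored-pair
#' universe, BH-after-dropping-p=1 across percentiles).
#'
#' @param pairs data.frame from [interactions_to_gene_pairs()] (or any table
#'   with gene_a, gene_b, score).
#' @param network validated edge list data.frame(gene_a, gene_b, ...).
#' @param percentiles percent thresholds (default 1, 5, 10, 15, 20, 25).
#' @return list(overlap = count, results = per-percentile data.frame).
#' @export
validated_overlap_enrichment <- function(pairs, network,
                                         percentiles = c(1, 5, 10, 15, 20, 25)) {
  if (!nrow(network)) stop("empty validated network")
  edges <- normalize_edges(network)
  key <- paste(pmin(pairs$gene_a, pairs$gene_b),
               pmax(pairs$gene_a, pairs$gene_b), sep = "\r")
  dup <- duplicated(key)
  key <- key[!dup]
  score <- pairs$score[!dup]
  ord <- order(-score)
  key <- key[ord]
  in_net <- key %in% edges
  n <- length(key)
  overlap <- sum(in_net)
  rows <- lapply(percentiles, function(tau) {
    k <- ceiling(tau / 100 * n)
    a <- sum(in_net[seq_len(k)])
    b <- overlap - a
    cc <- k - a
    d <- n - k - b
    cbind(percentile = tau, fisher_2x2(a, b, cc, d))
  })
  res <- do.call(rbind, rows)
  res$q <- bh_adjust_drop_p1(res$p)
  rownames(res) <- NULL
  list(overlap = overlap, n_pairs = n, results = res)
}

#' Median and interquartile range of attributions by genotype stratum
#'
#' Groups isolates by their genotype combination at one or two features and
#' summarizes the chosen attribution (the SHAP value of `feature_a`, or the
#' pairwise interaction value when an interaction tensor is supplied) with
#' the median and the 25th/75th percentiles (linear-interpolation quantiles,
#' R type 7).
#'
#' @param x an `fs_shap` or `fs_interaction`.
#' @param feature_a,feature_b feature ids (`feature_b` optional for SHAP).
#' @param genotypes isolate x feature matrix of genotype values to stratify
#'   on (e.g. dosages).
#' @return data.frame(genotype_a, genotype_b, n, median, q25, q75).
#' @export
genotype_stratified_summary <- function(x, feature_a, feature_b = NULL,
                                        genotypes) {
  genotypes <- as.matrix(genotypes)
  vals <- if (inherits(x, "fs_interaction")) {
    stopifnot(!is.null(feature_b))
    x$tensor[, feature_a, feature_b]
  } else if (inherits(x, "fs_shap")) {
    x$phi[, feature_a]
  } else stop("x must be an fs_shap or fs_interaction")
  ga <- genotypes[, feature_a]
  gb <- if (!is.null(feature_b)) genotypes[, feature_b] else rep(NA, length(ga))
  strata <- split(seq_along(vals), paste(ga, gb, sep = "|"))
  rows <- lapply(strata, function(idx) {
    v <- vals[idx]
    data.frame(genotype_a = ga[idx[1]], genotype_b = gb[idx[1]],
               n = length(idx), median = median(v),
               q25 = unname(quantile(v, 0.25)), q75 = unname(quantile(v, 0.75)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$genotype_a, out$genotype_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genetic-distance clustering and benchmark-SHAP contrast
#'
#' K-means on the rows of a genetic distance matrix (k chosen from `k_range`
#' by the maximum-curvature elbow rule on total within-cluster inertia: the
#' largest discrete second difference), identification of the cluster
#' containing the reference isolate, and a one-sided ("greater")
#' Mann-Whitney U test comparing per-isolate median absolute SHAP values of
#' benchmark-gene features between the reference cluster and the remaining
#' isolates.
#'
#' @param distance an `fs_relmat` of kind `"distance"` (reference row
#'   included; see [distance_matrix()]).
#' @param shap an `fs_shap` over the non-reference isolates.
#' @param benchmark_features features mapped to benchmark genes.
#' @param reference_id id of the reference row in the distance matrix.
#' @param k_range candidate cluster counts (default 2:10).
#' @param seed RNG seed for k-means restarts.
#' @return list(labels, k, statistic, p, per_cluster).
#' @export
distance_cluster_benchmark_test <- function(distance, shap, benchmark_features,
                                            reference_id, k_range = 2:10,
                                            seed = 1L) {
  m <- if (inherits(distance, "fs_relmat")) distance$values else as.matrix(distance)
  if (!reference_id %in% rownames(m))
    stop("reference isolate ", reference_id, " absent from the distance matrix")
  missing_feats <- setdiff(benchmark_features, colnames(shap$phi))
  if (length(missing_feats))
    stop("benchmark features absent from attributions: ",
         paste(head(missing_feats, 5), collapse = ", "))
  k_range <- k_range[k_range < nrow(m)]
  fits <- with_seed(derive_seed(seed, "distance_kmeans"), {
    lapply(k_range, function(k) kmeans(m, centers = k, nstart = 10, iter.max = 50))
  })
  inertia <- vapply(fits, function(f) f$tot.withinss, 0)
  # elbow: largest discrete second difference of inertia over k, with the
  # trivial k = 1 solution (total sum of squares) prepended so the first
  # candidate k can itself be the elbow
  tss <- sum(scale(m, scale = FALSE)^2)
  k_idx <- if (length(k_range) >= 2) {
    curv <- diff(diff(c(tss, inertia)))
    which.max(curv)
  } else 1L
  fit <- fits[[k_idx]]
  labels <- fit$cluster
  ref_cluster <- labels[reference_id]
  iso <- setdiff(rownames(m), reference_id)
  x <- apply(abs(shap$phi[iso, benchmark_features, drop = FALSE]), 1, median)
  in_ref <- labels[iso] == ref_cluster
  if (!any(in_ref) || all(in_ref))
    stop("reference cluster covers none or all isolates; cannot contrast")
  wt <- suppressWarnings(wilcox.test(x[in_ref], x[!in_ref],
                                     alternative = "greater"))
  per_cluster <- do.call(rbind, lapply(sort(unique(labels[iso])), function(cl) {
    if (cl == ref_cluster) return(NULL)
    other <- labels[iso] == cl
    w <- suppressWarnings(wilcox.test(x[in_ref], x[other],
                                      alternative = "greater"))
    data.frame(cluster = cl, n = sum(other), statistic = unname(w$statistic),
               p = w$p.value)
  }))
  list(labels = labels, k = k_range[k_idx], reference_cluster = ref_cluster,
       statistic = unname(wt$statistic), p = wt$p.value,
       per_cluster = per_cluster)
}
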