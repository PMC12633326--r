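#' Rank features by average Gini importance
#'
#' Averages the impurity-decrease (Gini) importance of each feature across
#' fitted tree-ensemble repeats, drops features with zero importance, and
#' ranks the remainder in descending order with average ties. Display order
#' breaks exact ties lexicographically by feature id for reproducibility.
#'
#' @param fits a single `fs_forest`/`fs_cv`, or a list of them (the CV
#'   repeats).
#' @return an importance table: data.frame(feature, importance, rank).
#' @export
rank_by_gini <- function(fits) {
  if (inherits(fits, c("fs_forest", "fs_cv"))) fits <- list(fits)
  imps <- lapply(fits, function(f) {
    if (inherits(f, "fs_cv")) {
      if (is.null(f$repeat_models))
        stop("Gini ranking requires tree-ensemble models")
      return(rowMeans(vapply(f$repeat_models, function(m) m$importance,
                             numeric(length(f$model$importance)))))
    }
    if (!inherits(f, "fs_forest"))
      stop("Gini ranking requires tree-ensemble models")
    f$importance
  })
  imp <- rowMeans(do.call(cbind, imps))
  imp <- imp[imp > 0]
  if (!length(imp))
    return(data.frame(feature = character(), importance = numeric(),
                      rank = numeric(), stringsAsFactors = FALSE))
  out <- data.frame(feature = names(imp), importance = unname(imp),
                    rank = rank(-imp, ties.method = "average"),
                    stringsAsFactors = FALSE)
  out[order(-out$importance, out$feature), , drop = FALSE]
}

#' Nested subset sizes for feature selection
#'
#' SNPs use the powers-of-two series joined with an arithmetic series in
#' steps of 1000; PAV/CNV (and PCs) use steps of 250. Sizes are truncated to
#' the available feature count, sorted and deduplicated.
#'
#' @param variant_type `"SNP"`, `"PAV"`, `"CNV"` or `"PC"`.
#' @param n_available total number of features.
#' @export
subset_grid <- function(variant_type, n_available) {
  stopifnot(n_available >= 2)
  step <- if (toupper(variant_type) == "SNP") 1000L else 250L
  sizes <- sort(unique(c(2L^(1:10), step * (1:30))))
  sizes[sizes <= n_available]
}

#' Choose the optimized feature-set size from a selection curve
#'
#' Operationalizes the "inflection point" of a feature selection curve
#' (x: subset size, y: mean validation R2) as the smallest size whose score
#' is within `delta` of the curve maximum; the chosen features are the
#' top-k of the importance table (ties broken lexicographically).
#'
#' @param sizes ascending subset sizes evaluated.
#' @param scores mean validation R2 per size.
#' @param importance importance table from [rank_by_gini()] (or the
#'   SHAP-based analogue).
#' @param delta plateau tolerance (default 0.01).
#' @return `fs_selection`: sizes, scores, chosen size, chosen feature ids.
#' @export
select_optimized <- function(sizes, scores, importance = NULL, delta = 0.01) {
  stopifnot(length(sizes) == length(scores))
  if (length(sizes) < 3) stop("need at least 3 curve points")
  ord <- order(sizes)
  sizes <- sizes[ord]; scores <- scores[ord]
  chosen <- sizes[which(scores >= max(scores) - delta)[1]]
  chosen_features <- NULL
  if (!is.null(importance)) {
    tab <- importance[order(-importance$importance, importance$feature), ]
    chosen_features <- head(tab$feature, chosen)
  }
  structure(list(sizes = sizes, scores = scores, chosen_size = chosen,
                 chosen_features = chosen_features, delta = delta),
            class = "fs_selection")
}

#' @export
print.fs_selection <- function(x, ...) {
  cat(sprintf("<fs_selection> %d sizes evaluated, chosen %d (max R2 %.3f)\n",
              length(x$sizes), x$chosen_size, max(x$scores)))
  invisible(x)
}

#' @export
plot.fs_selection <- function(x, ...) {
  graphics::plot(x$sizes, x$scores, type = "b", log = "x",
                 xlab = "number of features", ylab = "validation R2", ...)
  graphics::abline(v = x$chosen_size, lty = 2)
  invisible(x)
}

#' Run the nested-subset feature selection curve
#'
#' Builds new ensembles on the top-k features for each size of
#' [subset_grid()] (capped by `max_size` to keep desk-scale runs fast),
#' scores each by repeated-CV validation R2, and picks the optimized set via
#' [select_optimized()].
#'
#' @param X,y training data.
#' @param importance importance table over the columns of `X`.
#' @param variant_type passed to [subset_grid()].
#' @param scheme a [split_scheme()] (repeats typically reduced here).
#' @param algorithm tree learner to use (default RF).
#' @param grid hyperparameter grid for the subset models (small by default).
#' @param delta plateau tolerance.
#' @param max_size optional cap on evaluated sizes.
#' @export
feature_selection_curve <- function(X, y, importance, variant_type = "SNP",
                                    scheme = split_scheme(n_repeats = 3),
                                    algorithm = "RF", grid = NULL,
                                    delta = 0.01, max_size = NULL) {
  sizes <- subset_grid(variant_type, min(ncol(X), nrow(importance)))
  if (!is.null(max_size)) sizes <- sizes[sizes <= max_size]
  if (length(sizes) < 3) stop("not enough feature-subset sizes to form a curve")
  tab <- importance[order(-importance$importance, importance$feature), ]
  if (is.null(grid))
    grid <- data.frame(max_depth = 5, max_features = "0.5", n_estimators = 100,
                       stringsAsFactors = FALSE)
  scores <- vapply(sizes, function(k) {
    feats <- head(tab$feature, k)
    cv <- cross_validate(X[, feats, drop = FALSE], y, algorithm,
                         scheme = scheme, grid = grid)
    cv$record$validation_r2
  }, 0)
  select_optimized(sizes, scores, importance, delta)
}
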