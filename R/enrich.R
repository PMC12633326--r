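#' Mutant and phenotype filters defining benchmark fitness genes
#'
#' A gene qualifies as a benchmark fitness gene for a condition when at least
#' one of its phenotype annotations combines a loss-of-function mutant class
#' with a decreased-fitness phenotype class.
#' @export
benchmark_mutant_filters <- c("null Allele", "reduction of function",
                              "reduction of function Allele")

#' @rdname benchmark_mutant_filters
#' @export
benchmark_phenotype_filters <- c("resistance to chemicals: decreased",
                                 "viability: decreased",
                                 "metal resistance: decreased",
                                 "oxidative stress resistance: decreased",
                                 "respiratory growth: decreased",
                                 "stress resistance: decreased")

norm_ws <- function(x) gsub("\\s+", " ", trimws(x))

#' Curate a benchmark fitness gene set from a phenotype annotation table
#'
#' Keeps genes having at least one row whose mutant-information value matches
#' the loss-of-function filters AND whose phenotype value matches the
#' decreased-fitness filters (exact string match after whitespace
#' normalization); the gene list is deduplicated.
#'
#' @param table data.frame of phenotype annotations.
#' @param condition condition name recorded on the set.
#' @param gene_col,mutant_col,phenotype_col column names.
#' @return `fs_benchmark`: condition, source, genes.
#' @export
curate_benchmarks <- function(table, condition = "condition",
                              gene_col = "gene",
                              mutant_col = "mutant_information",
                              phenotype_col = "phenotype") {
  missing_cols <- setdiff(c(gene_col, mutant_col, phenotype_col), names(table))
  if (length(missing_cols))
    stop("schema error: missing column(s) ", paste(missing_cols, collapse = ", "))
  keep <- norm_ws(table[[mutant_col]]) %in% benchmark_mutant_filters &
    norm_ws(table[[phenotype_col]]) %in% benchmark_phenotype_filters
  genes <- unique(table[[gene_col]][keep])
  if (!length(genes)) stop("empty benchmark set for ", condition)
  structure(list(condition = condition, source = "SGD-derived", genes = genes),
            class = "fs_benchmark")
}

#' @export
print.fs_benchmark <- function(x, ...) {
  cat(sprintf("<fs_benchmark> %s: %d genes (%s)\n", x$condition,
              length(x$genes), x$source))
  invisible(x)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric p (two-sided by the probability-mass rule) with the
#' sample cross-ratio odds ratio (a d)/(b c): zero numerator gives 0, zero
#' denominator with positive numerator gives Inf, 0/0 is undefined (NA).
#'
#' @param a,b,c,d cell counts: a = important genes with the annotation,
#'   b = background genes with it, c = important without, d = background
#'   without.
#' @param alternative passed to the exact test (default two-sided).
#' @return data.frame(a, b, c, d, odds_ratio, p, q) — `q` is filled by
#'   [bh_adjust_drop_p1()] across a test family.
#' @export
fisher_2x2 <- function(a, b, c, d, alternative = "two.sided") {
  counts <- c(a, b, c, d)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (all(counts == 0)) stop("undefined test: all-zero contingency table")
  p <- fisher.test(matrix(counts, 2, 2, byrow = TRUE),
                   alternative = alternative)$p.value
  p <- min(max(p, 0), 1)    # guard the tiny >1 overshoot of summed tails
  or <- if (a * d == 0 && b * c == 0) NA_real_ else (a * d) / (b * c)
  data.frame(a = a, b = b, c = c, d = d, odds_ratio = or, p = p,
             q = NA_real_)
}

#' Benjamini-Hochberg correction after removing p = 1 tests
#'
#' Tests with p exactly 1 are removed before the step-up correction and
#' reported with an undefined (NA) q; the remainder get standard BH q-values.
#' @param p vector of p-values in `[0, 1]`.
#' @return q-values aligned with `p` (NA where p = 1).
#' @export
bh_adjust_drop_p1 <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  q <- rep(NA_real_, length(p))
  keep <- !is.na(p) & p < 1
  q[keep] <- p.adjust(p[keep], method = "BH")
  q
}

#' Benchmark enrichment at rank-percentile thresholds
#'
#' For each percentile tau, the top ceiling(tau/100 * N) genes of the ranking
#' are the "important" set and the rest the background; enrichment of the
#' benchmark set is a two-sided Fisher test, corrected across the percentile
#' family with [bh_adjust_drop_p1()].
#'
#' @param ranking character vector of genes, best first (or a data.frame
#'   with `gene` ordered by rank).
#' @param benchmark an `fs_benchmark` or character vector of genes.
#' @param percentiles percent thresholds (default 1, 5, 10, 15, 20, 25).
#' @return data.frame with one row per percentile: percentile, threshold
#'   rank, a, b, c, d, odds_ratio, p, q.
#' @export
percentile_benchmark_enrichment <- function(ranking, benchmark,
                                            percentiles = c(1, 5, 10, 15, 20, 25)) {
  if (is.data.frame(ranking)) ranking <- ranking$gene
  genes <- if (inherits(benchmark, "fs_benchmark")) benchmark$genes else benchmark
  universe <- unique(ranking)
  bench <- intersect(genes, universe)
  if (!length(bench)) stop("benchmark set does not intersect the gene universe")
  n <- length(universe)
  rows <- lapply(percentiles, function(tau) {
    k <- ceiling(tau / 100 * n)
    top <- universe[seq_len(k)]
    a <- sum(top %in% bench)
    b <- length(bench) - a
    cc <- k - a
    d <- n - k - b
    cbind(percentile = tau, threshold_rank = k,
          fisher_2x2(a, b, cc, d))
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust_drop_p1(out$p)
  rownames(out) <- NULL
  out
}

#' Annotation-term enrichment (GO terms, pathways, or any gene-set family)
#'
#' Runs the 2x2 Fisher design over a list of annotation terms: a = important
#' genes with the term, b = background genes with it, c/d the complements,
#' with the family-wise BH-after-dropping-p=1 correction.
#'
#' @param important character vector of important genes.
#' @param background character vector of background genes (disjoint from
#'   `important`).
#' @param term_genes named list: term -> character vector of genes.
#' @return data.frame(term, a, b, c, d, odds_ratio, p, q).
#' @export
term_enrichment <- function(important, background, term_genes) {
  stopifnot(length(term_genes) > 0)
  rows <- lapply(names(term_genes), function(term) {
    g <- term_genes[[term]]
    a <- sum(important %in% g)
    b <- sum(background %in% g)
    cc <- length(important) - a
    d <- length(background) - b
    cbind(term = term, fisher_2x2(a, b, cc, d))
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust_drop_p1(out$p)
  rownames(out) <- NULL
  out
}

#' Read GO annotations from a GAF 2.2 file, keeping experimental evidence
#'
#' Returns a term -> genes list filtered to the experimental and
#' high-throughput evidence codes (IDA, IPI, IMP, IGI, IEP, HDA, HMP, HGI,
#' HEP). Direct annotations only; no propagation up the ontology graph.
#' @param path GAF file (may be plain text or gzip).
#' @param evidence evidence codes kept.
#' @export
read_gaf <- function(path, evidence = c("IDA", "IPI", "IMP", "IGI", "IEP",
                                        "HDA", "HMP", "HGI", "HEP")) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "!")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  parts <- parts[vapply(parts, length, 0L) >= 15]
  keep <- vapply(parts, function(p) p[7] %in% evidence, TRUE)
  parts <- parts[keep]
  if (!length(parts)) return(list())
  df <- data.frame(gene = vapply(parts, `[`, "", 3),
                   term = vapply(parts, `[`, "", 5), stringsAsFactors = FALSE)
  lapply(split(df$gene, df$term), unique)
}
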