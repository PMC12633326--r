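#' @title Genotype, ORF and fitness containers
#' @description Lightweight S3 containers used throughout the package.
#'   A genotype matrix (`fs_geno`) holds isolate x SNP dosages plus SNP
#'   metadata (chrom, 1-based pos, ref/alt) and an encoding tag: `"raw012"`
#'   counts the alternative allele (0 = homozygous reference), `"signed"`
#'   maps major-homozygote/het/minor-homozygote to -1/0/1.
#' @param dosages numeric isolate x SNP matrix (`NA` = missing).
#' @param isolates character ids (rows).
#' @param snps data.frame with columns id, chrom, pos, ref, alt.
#' @param encoding `"raw012"` or `"signed"`.
#' @return an `fs_geno` object.
#' @export
new_genotype_matrix <- function(dosages, isolates, snps, encoding = "raw012") {
  stopifnot(nrow(dosages) == length(isolates), ncol(dosages) == nrow(snps),
            encoding %in% c("raw012", "signed"))
  mode(dosages) <- "numeric"
  dimnames(dosages) <- list(isolates, snps$id)
  structure(list(dosages = dosages, isolates = isolates, snps = snps,
                 encoding = encoding, imputed = FALSE),
            class = "fs_geno")
}

#' @export
print.fs_geno <- function(x, ...) {
  cat(sprintf("<fs_geno> %d isolates x %d SNPs, encoding %s, %.2f%% missing%s\n",
              length(x$isolates), nrow(x$snps), x$encoding,
              100 * mean(is.na(x$dosages)),
              if (isTRUE(x$imputed)) " (imputed)" else ""))
  invisible(x)
}

#' ORF matrix container (PAV or CNV)
#' @param values isolate x ORF matrix; PAV must be 0/1, CNV non-negative.
#' @param isolates,orfs ids.
#' @param kind `"PAV"` or `"CNV"`.
#' @export
new_orf_matrix <- function(values, isolates, orfs, kind = c("PAV", "CNV")) {
  kind <- match.arg(kind)
  stopifnot(nrow(values) == length(isolates), ncol(values) == length(orfs))
  if (kind == "PAV" && !all(values %in% c(0, 1) | is.na(values)))
    stop("PAV values must be binary")
  if (kind == "CNV" && any(values < 0, na.rm = TRUE))
    stop("CNV values must be non-negative")
  if (any(colSums(!is.na(values)) == 0))
    stop("ORF columns missing in all isolates must be excluded")
  values <- matrix(as.numeric(values), nrow(values), ncol(values),
                   dimnames = list(isolates, orfs))
  structure(list(values = values, isolates = isolates, orfs = orfs, kind = kind),
            class = "fs_orf")
}

#' @export
print.fs_orf <- function(x, ...) {
  cat(sprintf("<fs_orf:%s> %d isolates x %d ORFs\n", x$kind,
              length(x$isolates), length(x$orfs)))
  invisible(x)
}

#' Fitness table container
#' @param values isolate x environment matrix of positive colony-size ratios.
#' @param isolates,environments ids.
#' @export
new_fitness_table <- function(values, isolates, environments) {
  stopifnot(nrow(values) == length(isolates), ncol(values) == length(environments),
            all(is.finite(values)))
  dimnames(values) <- list(isolates, environments)
  structure(list(values = values, isolates = isolates,
                 environments = environments), class = "fs_fitness")
}

#' @export
print.fs_fitness <- function(x, ...) {
  cat(sprintf("<fs_fitness> %d isolates x %d environments\n",
              length(x$isolates), length(x$environments)))
  invisible(x)
}

new_relationship_matrix <- function(values, isolates,
                                    kind = c("kinship", "additive", "dominance",
                                             "distance")) {
  kind <- match.arg(kind)
  dimnames(values) <- list(isolates, isolates)
  structure(list(values = values, isolates = isolates, kind = kind),
            class = "fs_relmat")
}

#' @export
print.fs_relmat <- function(x, ...) {
  cat(sprintf("<fs_relmat:%s> %d x %d\n", x$kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# I/O
# ---------------------------------------------------------------------------

#' Write / read a matrix as TSV with an id column
#' @param values matrix; `ids` row names; `cols` column names.
#' @param path file path.
#' @param id_col name of the first column.
#' @export
write_matrix_tsv <- function(values, ids, cols, path, id_col = "id") {
  df <- data.frame(ids, values, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(id_col, cols)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write genotypes as VCF 4.2 (GT field, diploid, `./.` for missing)
#' @param geno an `fs_geno` in raw012 encoding.
#' @param path output path.
#' @export
write_genotypes_vcf <- function(geno, path) {
  stopifnot(geno$encoding == "raw012")
  gt_codes <- c("0/0", "0/1", "1/1")
  dos <- geno$dosages
  gt <- matrix("./.", nrow(dos), ncol(dos))
  ok <- !is.na(dos)
  gt[ok] <- gt_codes[dos[ok] + 1L]
  header <- c("##fileformat=VCFv4.2",
              "##source=fitscape",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", geno$isolates), collapse = "\t"))
  body <- data.table::data.table(geno$snps$chrom, geno$snps$pos, geno$snps$id,
                                 geno$snps$ref, geno$snps$alt, ".", "PASS",
                                 ".", "GT")
  body <- cbind(body, data.table::as.data.table(t(gt)))
  writeLines(header, path)
  data.table::fwrite(body, path, sep = "\t", quote = FALSE, append = TRUE,
                     col.names = FALSE)
  invisible(path)
}

#' Read diploid genotypes from a VCF file
#'
#' Parses the GT field of a VCF 4.x file into a raw012 genotype matrix
#' (alternative-allele dosage; `./.` or `.` become `NA`). Multi-allelic
#' records and indels are retained with their ALT string so that
#' [filter_snps()] can enforce the biallelic-SNP rules; their dosages count
#' any non-reference allele. The default reader is a fast tabular parser;
#' `method = "VariantAnnotation"` routes through Bioconductor instead and is
#' used as an independent cross-check in the test suite.
#'
#' @param path VCF path.
#' @param method `"light"` or `"VariantAnnotation"`.
#' @return an `fs_geno` (raw012).
#' @export
read_genotypes_vcf <- function(path, method = c("light", "VariantAnnotation")) {
  method <- match.arg(method)
  if (method == "VariantAnnotation") {
    if (!requireNamespace("VariantAnnotation", quietly = TRUE))
      stop("VariantAnnotation not installed")
    vcf <- VariantAnnotation::readVcf(path)
    gt <- VariantAnnotation::geno(vcf)$GT
    rr <- SummarizedExperiment::rowRanges(vcf)
    alt <- vapply(as.list(rr$ALT), function(a) paste(as.character(a), collapse = ","), "")
    snps <- data.frame(id = rownames(gt),
                       chrom = as.character(GenomeInfoDb::seqnames(rr)),
                       pos = BiocGenerics::start(rr),
                       ref = as.character(rr$REF), alt = alt,
                       stringsAsFactors = FALSE)
    dos <- t(apply(gt, c(1, 2), gt_to_dosage))
    return(new_genotype_matrix(dos, colnames(gt), snps, "raw012"))
  }
  lines <- readLines(path, n = 2000L)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop("parse error: no #CHROM header line found")
  cols <- strsplit(lines[hdr[1]], "\t", fixed = TRUE)[[1]]
  samples <- cols[-(1:9)]
  df <- data.table::fread(path, sep = "\t", skip = hdr[1], header = FALSE,
                          data.table = FALSE,
                          colClasses = list(character = c(1, 3:9)))
  if (ncol(df) != length(cols))
    stop("parse error: inconsistent column count in VCF body")
  snps <- data.frame(id = df[[3]], chrom = df[[1]], pos = as.integer(df[[2]]),
                     ref = df[[4]], alt = df[[5]], stringsAsFactors = FALSE)
  noid <- snps$id == "."
  if (any(noid)) snps$id[noid] <- paste0(snps$chrom[noid], ":", snps$pos[noid])
  gt_idx <- vapply(strsplit(df[[9]], ":", fixed = TRUE),
                   function(f) match("GT", f), 0L)
  if (anyNA(gt_idx)) stop("parse error: record without GT field")
  dos <- matrix(NA_real_, length(samples), nrow(df))
  for (j in seq_along(samples)) {
    field <- df[[9 + j]]
    gt <- vapply(seq_along(field), function(i) {
      strsplit(field[i], ":", fixed = TRUE)[[1]][gt_idx[i]]
    }, "")
    dos[j, ] <- gt_vec_to_dosage(gt)
  }
  new_genotype_matrix(dos, samples, snps, "raw012")
}

gt_to_dosage <- function(gt) {
  gt_vec_to_dosage(gt)
}

gt_vec_to_dosage <- function(gt) {
  gt <- sub(":.*$", "", gt)
  alleles1 <- sub("[/|].*$", "", gt)
  alleles2 <- sub("^[^/|]*[/|]", "", gt)
  a1 <- suppressWarnings(as.integer(alleles1))
  a2 <- suppressWarnings(as.integer(ifelse(alleles2 == gt, alleles1, alleles2)))
  out <- (a1 > 0) + (a2 > 0)
  as.numeric(out)
}

# ---------------------------------------------------------------------------
# Operations
# ---------------------------------------------------------------------------

#' Filter to biallelic SNPs by MAF and missingness
#'
#' Retains variants that are single-base biallelic substitutions with minor
#' allele frequency strictly greater than `maf` (computed on non-missing
#' calls) and missing fraction strictly below `max_missing`. Boundary cases
#' are enforced as printed: MAF exactly at the threshold is removed, as is a
#' missing fraction exactly at the cap. Idempotent; order preserved.
#'
#' @param geno an `fs_geno` in raw012 encoding.
#' @param maf minor-allele-frequency threshold (default 0.05).
#' @param max_missing missing-fraction cap (default 0.20).
#' @export
filter_snps <- function(geno, maf = 0.05, max_missing = 0.20) {
  stopifnot(inherits(geno, "fs_geno"), geno$encoding == "raw012")
  snps <- geno$snps
  biallelic <- nchar(snps$ref) == 1 & nchar(snps$alt) == 1 &
    snps$ref %in% c("A", "C", "G", "T") & snps$alt %in% c("A", "C", "G", "T")
  miss <- colMeans(is.na(geno$dosages))
  p_alt <- colMeans(geno$dosages, na.rm = TRUE) / 2
  maf_obs <- pmin(p_alt, 1 - p_alt)
  maf_obs[is.nan(maf_obs)] <- 0
  keep <- biallelic & maf_obs > maf & miss < max_missing
  out <- new_genotype_matrix(geno$dosages[, keep, drop = FALSE],
                             geno$isolates, snps[keep, , drop = FALSE],
                             "raw012")
  out$subpop <- geno$subpop
  out$imputed <- geno$imputed
  out
}

#' Encode dosages as signed {-1, 0, 1} or raw {0, 1, 2}
#'
#' Signed encoding maps major-allele homozygotes to -1, heterozygotes to 0
#' and minor-allele homozygotes to +1, with the major allele determined from
#' non-missing calls (frequency ties at exactly 0.5 treat the reference
#' allele as major). Raw012 counts copies of the alternative allele, 0 being
#' homozygous reference.
#'
#' @param geno an `fs_geno`.
#' @param encoding target encoding.
#' @export
encode_dosage <- function(geno, encoding = c("signed", "raw012")) {
  encoding <- match.arg(encoding)
  if (geno$encoding == encoding) return(geno)
  if (geno$encoding == "raw012") {
    p_alt <- colMeans(geno$dosages, na.rm = TRUE) / 2
    alt_major <- p_alt > 0.5           # tie -> ref treated as major
    # raw -> signed: ref-major columns: d - 1 ; alt-major columns: 1 - d
    d <- geno$dosages
    d <- sweep(d, 2, ifelse(alt_major, -1, 1), `*`) +
      rep(ifelse(alt_major, 1, -1), each = nrow(d))
    out <- new_genotype_matrix(d, geno$isolates, geno$snps, "signed")
    out$alt_major <- alt_major
  } else {
    alt_major <- geno$alt_major %||% rep(FALSE, nrow(geno$snps))
    d <- geno$dosages
    d <- sweep(d, 2, ifelse(alt_major, -1, 1), `*`) + 1
    out <- new_genotype_matrix(d, geno$isolates, geno$snps, "raw012")
  }
  out$subpop <- geno$subpop
  out$imputed <- geno$imputed
  out
}

#' Impute missing genotype calls with the per-SNP mode
#'
#' Deterministic stand-in for haplotype-model imputation: each missing call
#' is replaced by the most frequent non-missing dosage of its SNP, ties going
#' to the lower dosage. Output is flagged `imputed`.
#' @param geno an `fs_geno`.
#' @export
impute_missing <- function(geno) {
  d <- geno$dosages
  for (j in which(colSums(is.na(d)) > 0)) {
    x <- d[, j]
    obs <- x[!is.na(x)]
    if (!length(obs)) stop("SNP ", geno$snps$id[j], " has no observed calls")
    tab <- table(obs)
    mode_val <- as.numeric(names(tab)[tab == max(tab)])
    d[is.na(x), j] <- min(mode_val)
  }
  out <- new_genotype_matrix(d, geno$isolates, geno$snps, geno$encoding)
  out$subpop <- geno$subpop
  out$alt_major <- geno$alt_major
  out$imputed <- TRUE
  out
}

allele_freq <- function(geno) {
  if (geno$encoding == "raw012") colMeans(geno$dosages) / 2
  else (colMeans(geno$dosages) + 1) / 2
}

#' Centered identity-by-state kinship
#'
#' K = W W' / c with W the column-centered dosage matrix and
#' c = sum_j 2 p_j (1 - p_j) the total expected heterozygosity — the
#' normalization of the centered-IBS genomic relationship estimator.
#' @param geno complete (no missing) `fs_geno`.
#' @return `fs_relmat` of kind `"kinship"`.
#' @export
kinship_centered_ibs <- function(geno) {
  d <- geno$dosages
  if (anyNA(d)) stop("kinship requires complete genotypes; impute first")
  p <- allele_freq(geno)
  c0 <- sum(2 * p * (1 - p))
  W <- sweep(d, 2, colMeans(d))
  if (c0 <= 0 || max(abs(W)) == 0)
    stop("degenerate input: zero-variance genotype matrix")
  K <- tcrossprod(W) / c0
  new_relationship_matrix((K + t(K)) / 2, geno$isolates, "kinship")
}

#' Principal components of the SNP genotypes
#' @param geno complete `fs_geno`.
#' @param n number of components (default 5).
#' @return `fs_pcs`: scores (isolate x n), explained variance fractions.
#' @export
principal_components <- function(geno, n = 5) {
  d <- geno$dosages
  if (anyNA(d)) stop("PCA requires complete genotypes")
  W <- sweep(d, 2, colMeans(d))
  sv <- svd(W, nu = 0, nv = 0)
  rank <- sum(sv$d > max(sv$d) * 1e-10)
  if (n > rank) stop("n exceeds the rank (", rank, ") of the genotype matrix")
  sv <- svd(W, nu = n, nv = n)
  scores <- sv$u %*% diag(sv$d[seq_len(n)], n)
  dimnames(scores) <- list(geno$isolates, paste0("PC", seq_len(n)))
  structure(list(scores = scores,
                 explained = sv$d[seq_len(n)]^2 / sum(svd(W, nu = 0, nv = 0)$d^2),
                 loadings = sv$v),
            class = "fs_pcs")
}

#' @export
print.fs_pcs <- function(x, ...) {
  cat(sprintf("<fs_pcs> %d components, explained: %s\n", ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * x$explained), collapse = " ")))
  invisible(x)
}

#' Additive (VanRaden) and dominance genomic relationship matrices
#'
#' A is the centered dosage cross-product scaled by total expected
#' heterozygosity (identical to [kinship_centered_ibs()]); D uses the
#' classical dominance parameterization: heterozygosity indicators centered
#' by 2pq, normalized by sum (2pq)^2.
#' @param geno complete `fs_geno` in raw012 encoding.
#' @return list with `A` and `D` (`fs_relmat`).
#' @export
relationship_matrices <- function(geno) {
  if (geno$encoding != "raw012") geno <- encode_dosage(geno, "raw012")
  d <- geno$dosages
  if (anyNA(d)) stop("relationship matrices require complete genotypes")
  p <- allele_freq(geno)
  tpq <- 2 * p * (1 - p)
  if (sum(tpq) <= 0) stop("degenerate input: monomorphic-only genotype matrix")
  A <- tcrossprod(sweep(d, 2, 2 * p)) / sum(tpq)
  H <- (abs(d - 1) < .Machine$double.eps^0.5) * 1
  M <- sweep(H, 2, tpq)
  denom <- sum(tpq^2)
  D <- if (denom > 0) tcrossprod(M) / denom else matrix(0, nrow(d), nrow(d))
  if (all(H == 0)) D <- matrix(0, nrow(d), nrow(d))
  list(A = new_relationship_matrix((A + t(A)) / 2, geno$isolates, "additive"),
       D = new_relationship_matrix((D + t(D)) / 2, geno$isolates, "dominance"))
}

#' Euclidean genetic distance matrix
#'
#' Pairwise Euclidean distances between isolate profiles, unscaled. For SNPs
#' the raw012 encoding is required (so the reference genome is the all-zero
#' profile); an optional reference row of zeros can be appended, emulating
#' the distance of every isolate to the reference background.
#'
#' @param x an `fs_geno` (raw012), `fs_orf` or plain matrix.
#' @param reference_id if non-NULL, name of an appended all-zero reference
#'   profile.
#' @return `fs_relmat` of kind `"distance"`.
#' @export
distance_matrix <- function(x, reference_id = NULL) {
  if (inherits(x, "fs_geno")) {
    if (x$encoding != "raw012")
      stop("distances are defined on the raw012 encoding")
    m <- x$dosages
  } else if (inherits(x, "fs_orf")) m <- x$values
  else m <- as.matrix(x)
  if (anyNA(m)) stop("distance matrix requires complete data")
  if (!is.null(reference_id)) {
    m <- rbind(m, matrix(0, 1, ncol(m), dimnames = list(reference_id, NULL)))
  }
  dm <- as.matrix(dist(m, method = "euclidean"))
  new_relationship_matrix(dm, rownames(m), "distance")
}
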