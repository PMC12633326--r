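#' Read gene annotation from a GFF3 file
#'
#' Keeps gene-type records only and returns 1-based inclusive coordinates.
#' Uses rtracklayer when installed; otherwise falls back on a minimal
#' tab-parser of the gene lines (ID= or Name= attribute as the gene id).
#'
#' @param path GFF3 file.
#' @return data.frame(gene, chrom, start, end, strand).
#' @export
read_gene_annotation <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[gr$type == "gene"]
    id <- if (!is.null(gr$ID)) gr$ID else gr$Name
    return(data.frame(gene = as.character(id),
                      chrom = as.character(GenomeInfoDb::seqnames(gr)),
                      start = BiocGenerics::start(gr),
                      end = BiocGenerics::end(gr),
                      strand = as.character(BiocGenerics::strand(gr)),
                      stringsAsFactors = FALSE))
  }
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  parts <- parts[vapply(parts, length, 0L) >= 9]
  parts <- parts[vapply(parts, function(p) p[3] == "gene", TRUE)]
  if (!length(parts)) stop("no gene records in ", path)
  attr_field <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0("(^|;)", key, "=([^;]+)"), attrs))[[1]]
    if (length(m) >= 3) m[3] else NA_character_
  }
  do.call(rbind, lapply(parts, function(p) {
    id <- attr_field(p[9], "ID")
    if (is.na(id)) id <- attr_field(p[9], "Name")
    data.frame(gene = id, chrom = p[1], start = as.integer(p[4]),
               end = as.integer(p[5]), strand = p[7], stringsAsFactors = FALSE)
  }))
}

#' Assign SNPs to genes by genic interval
#'
#' A SNP maps to the gene whose `[start, end]` interval (1-based inclusive,
#' strand-agnostic) contains its position. Intergenic SNPs are flagged
#' unmapped; SNPs inside overlapping genes are flagged multi-mapped and
#' excluded from gene-level analyses.
#'
#' @param snps data.frame with id, chrom, pos (an `fs_geno$snps` works).
#' @param annotation data.frame from [read_gene_annotation()].
#' @return `gene map` data.frame(feature, gene, kind, unmapped, multi).
#' @export
snp_to_gene <- function(snps, annotation) {
  if (inherits(snps, "fs_geno")) snps <- snps$snps
  unknown <- setdiff(unique(snps$chrom), unique(annotation$chrom))
  if (length(unknown))
    stop("unknown chromosome(s) in SNP table: ", paste(unknown, collapse = ", "))
  out <- data.frame(feature = snps$id, gene = NA_character_, kind = "SNP",
                    unmapped = TRUE, multi = FALSE, stringsAsFactors = FALSE)
  for (ch in unique(snps$chrom)) {
    genes <- annotation[annotation$chrom == ch, , drop = FALSE]
    rows <- which(snps$chrom == ch)
    for (i in rows) {
      hit <- which(genes$start <= snps$pos[i] & genes$end >= snps$pos[i])
      if (length(hit) == 1) {
        out$gene[i] <- genes$gene[hit]
        out$unmapped[i] <- FALSE
      } else if (length(hit) > 1) {
        out$multi[i] <- TRUE
        out$unmapped[i] <- FALSE
      }
    }
  }
  out
}

#' Read a 12-column tabular alignment hit table
#'
#' The classic 12-column tabular dialect: query, subject, percent identity,
#' alignment length, mismatches, gap opens, qstart, qend, sstart, send,
#' evalue, bitscore.
#' @param path file path.
#' @export
read_hit_table <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = FALSE, data.table = FALSE)
  if (ncol(df) < 12) stop("hit table must have 12 columns")
  names(df)[1:12] <- c("query", "subject", "pident", "length", "mismatch",
                       "gapopen", "qstart", "qend", "sstart", "send",
                       "evalue", "bitscore")
  if (any(df$pident < 0 | df$pident > 100)) stop("percent identity out of range")
  if (any(df$evalue < 0)) stop("negative E-value")
  df
}

top_hit <- function(hits, id, id_col = "query") {
  h <- hits[hits[[id_col]] == id, , drop = FALSE]
  if (!nrow(h)) return(NULL)
  h[order(-h$bitscore, h[[if (id_col == "query") "subject" else "query"]]), ][1, ]
}

#' Two-step reciprocal best match of ORFs to reference genes
#'
#' Step 1: an ORF's top forward hit (highest bit score, ties broken by
#' subject id) is its candidate gene if percent identity >= `min_pid` and
#' E-value < `max_evalue`. Step 2: the candidate gene's top reverse hit must
#' be the same ORF under the same filters. ORFs that end up matched to more
#' than one gene are excluded.
#'
#' @param forward,reverse hit tables ([read_hit_table()] format): ORF->gene
#'   and gene->ORF.
#' @param min_pid percent-identity threshold (>= , default 95).
#' @param max_evalue E-value threshold (strict <, default 1e-6).
#' @return data.frame(feature, gene, kind, unmapped, multi) over all forward
#'   query ORFs.
#' @export
orf_reciprocal_best_match <- function(forward, reverse, min_pid = 95,
                                      max_evalue = 1e-6) {
  dedupe <- function(h, what) {
    key <- paste(h$query, h$subject)
    if (anyDuplicated(key)) {
      warning("duplicate (query, subject) rows in ", what, " table: last wins")
      h <- h[!duplicated(key, fromLast = TRUE), , drop = FALSE]
    }
    h
  }
  forward <- dedupe(forward, "forward")
  reverse <- dedupe(reverse, "reverse")
  passes <- function(h) !is.null(h) && h$pident >= min_pid && h$evalue < max_evalue

  orfs <- unique(forward$query)
  out <- data.frame(feature = orfs, gene = NA_character_, kind = "ORF",
                    unmapped = TRUE, multi = FALSE, stringsAsFactors = FALSE)
  for (i in seq_along(orfs)) {
    fwd <- top_hit(forward, orfs[i], "query")
    if (!passes(fwd)) next
    rev_hit <- top_hit(reverse, fwd$subject, "query")
    if (!passes(rev_hit)) next
    if (rev_hit$subject != orfs[i]) next
    out$gene[i] <- fwd$subject
    out$unmapped[i] <- FALSE
  }
  # defensive: drop ORFs matched to more than one gene
  dup <- out$feature[!out$unmapped][duplicated(out$feature[!out$unmapped])]
  if (length(dup)) {
    sel <- out$feature %in% dup
    out$multi[sel] <- TRUE
    out$gene[sel] <- NA_character_
    out$unmapped[sel] <- TRUE
  }
  out
}

#' One representative feature per gene
#'
#' For each gene, keeps the mapped feature with the highest importance
#' (mean absolute SHAP value by convention, Gini when that table is passed);
#' exact ties go to the lexicographically smaller feature id.
#'
#' @param importance data.frame(feature, importance) or an `fs_shap` (mean
#'   absolute attributions are computed).
#' @param map gene map data.frame(feature, gene, unmapped, multi).
#' @return data.frame(gene, feature, importance), one row per mapped gene.
#' @export
gene_representative_feature <- function(importance, map) {
  if (inherits(importance, "fs_shap")) importance <- global_importance_rank(importance)
  m <- map[!map$unmapped & !map$multi & !is.na(map$gene), , drop = FALSE]
  df <- merge(m[, c("feature", "gene")], importance[, c("feature", "importance")],
              by = "feature")
  if (!nrow(df))
    return(data.frame(gene = character(), feature = character(),
                      importance = numeric(), stringsAsFactors = FALSE))
  df <- df[order(df$gene, -df$importance, df$feature), , drop = FALSE]
  out <- df[!duplicated(df$gene), c("gene", "feature", "importance")]
  rownames(out) <- NULL
  out
}
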