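#' Configuration for a synthetic diploid cohort
#'
#' Describes a structured diploid population in the style of a panel of
#' natural yeast isolates: `n_subpops` subpopulations diverged from a common
#' ancestral allele-frequency pool (Balding-Nichols model with divergence
#' `fst`), genotyped at `n_snps` biallelic SNPs and scored for `n_orfs` ORFs
#' as presence/absence (PAV) and copy number (CNV). Defaults are desk-scale:
#' the same 750-isolate cohort size as the motivating panel, with reduced
#' marker counts so tests run in seconds.
#'
#' @param n_isolates number of diploid isolates.
#' @param n_subpops number of subpopulations (>= 1).
#' @param fst divergence fraction in `[0, 1)` between subpopulations.
#' @param n_snps,n_orfs marker counts.
#' @param maf_range range the ancestral allele frequency is drawn from.
#' @param pav_absence_rate marginal probability an ORF is absent.
#' @param cnv_copy_states attainable copy numbers; must include 1 (the
#'   reference single copy). Half-copies such as 0.5 and 1.5 represent
#'   partial duplications.
#' @param missing_rate probability a genotype call is missing.
#' @param seed master seed; every simulation stage derives its own stream.
#' @return a `population_config` list, validated.
#' @export
population_config <- function(n_isolates = 750, n_subpops = 3, fst = 0.15,
                              n_snps = 2000, n_orfs = 500,
                              maf_range = c(0.05, 0.5),
                              pav_absence_rate = 0.1,
                              cnv_copy_states = c(0, 0.5, 1, 1.5, 2, 3),
                              missing_rate = 0.01, seed = 1L) {
  stopifnot(length(maf_range) == 2, maf_range[1] <= maf_range[2])
  if (n_isolates < 1 || n_snps < 1 || n_orfs < 1)
    stop("configuration error: counts must be positive")
  if (n_subpops < 1) stop("configuration error: n_subpops must be >= 1")
  if (!is_fraction(fst) || fst >= 1) stop("fst must lie in [0, 1)")
  for (f in c(maf_range, pav_absence_rate, missing_rate))
    if (!is_fraction(f)) stop("all fractions must lie in [0, 1]")
  if (!1 %in% cnv_copy_states)
    stop("cnv_copy_states must include the reference copy number 1")
  if (any(cnv_copy_states < 0)) stop("copy states must be non-negative")
  structure(list(n_isolates = as.integer(n_isolates),
                 n_subpops = as.integer(n_subpops), fst = fst,
                 n_snps = as.integer(n_snps), n_orfs = as.integer(n_orfs),
                 maf_range = maf_range, pav_absence_rate = pav_absence_rate,
                 cnv_copy_states = sort(unique(cnv_copy_states)),
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "population_config")
}

#' Trait architecture for synthetic multi-environment fitness
#'
#' States the genetic architecture used to simulate fitness: per-environment
#' additive and dominance QTL counts, optional explicit QTLs, planted
#' pairwise (product) interactions, a target narrow-sense heritability, an
#' environment-level genetic correlation matrix, and an optional major locus
#' that forces a bimodal fitness distribution.
#'
#' @param n_environments number of environments.
#' @param n_additive_qtl,n_dominance_qtl QTLs sampled per environment.
#' @param additive_qtl,dominance_qtl optional explicit per-environment lists
#'   of `list(feature =, effect =)`; overrides random sampling when given.
#' @param interaction_pairs list of `list(a =, b =, coef =)` planted product
#'   interactions between feature ids (e.g. `"snp_0001"`, `"pav_0002"`).
#' @param effect_scale standard deviation of sampled QTL effects.
#' @param target_h2 target heritability per environment (recycled).
#' @param env_genetic_correlation optional symmetric PSD matrix with unit
#'   diagonal adding an environment-correlated polygenic genetic value.
#' @param major_locus optional `list(feature =, effect =)`.
#' @param variant_channel channels the sampled additive QTLs are drawn from,
#'   any of `"SNP"`, `"PAV"`, `"CNV"` (recycled over QTLs).
#' @param noise_sd optional fixed residual standard deviation; when given it
#'   overrides the heritability-based noise scaling (useful for controlled
#'   ablation experiments).
#' @export
trait_architecture <- function(n_environments = 6, n_additive_qtl = 20,
                               n_dominance_qtl = 5,
                               additive_qtl = NULL, dominance_qtl = NULL,
                               interaction_pairs = list(), effect_scale = 1,
                               target_h2 = 0.5,
                               env_genetic_correlation = NULL,
                               major_locus = NULL,
                               variant_channel = "SNP",
                               noise_sd = NULL) {
  n_environments <- as.integer(n_environments)
  stopifnot(n_environments >= 1, effect_scale > 0)
  target_h2 <- rep_len(target_h2, n_environments)
  if (any(target_h2 < 0 | target_h2 > 1)) stop("target_h2 must lie in [0, 1]")
  if (!is.null(env_genetic_correlation)) {
    R <- env_genetic_correlation
    stopifnot(is.matrix(R), nrow(R) == n_environments, ncol(R) == n_environments)
    if (max(abs(R - t(R))) > 1e-8) stop("env_genetic_correlation must be symmetric")
    if (max(abs(diag(R) - 1)) > 1e-8) stop("env_genetic_correlation needs unit diagonal")
    if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
      stop("env_genetic_correlation must be positive semi-definite")
  }
  stopifnot(all(variant_channel %in% c("SNP", "PAV", "CNV")))
  structure(list(n_environments = n_environments,
                 n_additive_qtl = n_additive_qtl,
                 n_dominance_qtl = n_dominance_qtl,
                 additive_qtl = additive_qtl, dominance_qtl = dominance_qtl,
                 interaction_pairs = interaction_pairs,
                 effect_scale = effect_scale, target_h2 = target_h2,
                 env_genetic_correlation = env_genetic_correlation,
                 major_locus = major_locus,
                 variant_channel = variant_channel,
                 noise_sd = noise_sd),
            class = "trait_architecture")
}

#' Simulate a structured diploid SNP population
#'
#' Balding-Nichols generative model: each SNP has an ancestral frequency p
#' drawn from `maf_range`; each subpopulation draws its own frequency from
#' Beta(p(1-F)/F, (1-p)(1-F)/F) with F = `fst` (at F = 0 the ancestral
#' frequency is used directly), and diploid dosages are binomial(2) draws.
#' Missing calls are planted uniformly at `missing_rate`.
#'
#' @param config a [population_config()].
#' @return list with `geno` (a `fs_geno` genotype matrix, raw 0/1/2 encoding
#'   with `NA` for missing) and `subpop` (factor of subpopulation labels).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "population_config"))
  with_seed(derive_seed(config$seed, "population"), {
    n <- config$n_isolates; m <- config$n_snps; k <- config$n_subpops
    subpop <- factor(paste0("pop", rep_len(seq_len(k), n)))
    p_anc <- runif(m, config$maf_range[1], config$maf_range[2])
    freq <- matrix(0, k, m)
    if (config$fst > 0) {
      f <- config$fst
      a <- p_anc * (1 - f) / f
      b <- (1 - p_anc) * (1 - f) / f
      for (s in seq_len(k)) freq[s, ] <- rbeta(m, a, b)
    } else {
      freq <- matrix(rep(p_anc, each = k), k, m)
    }
    dos <- matrix(0L, n, m)
    for (s in seq_len(k)) {
      rows <- which(as.integer(subpop) == s)
      dos[rows, ] <- matrix(rbinom(length(rows) * m, 2L,
                                   rep(freq[s, ], each = length(rows))),
                            length(rows), m)
    }
    if (config$missing_rate > 0)
      dos[matrix(runif(n * m) < config$missing_rate, n, m)] <- NA_integer_
    isolates <- sprintf("iso_%04d", seq_len(n))
    # 16 chromosomes, positions spaced 500 bp, alternating alleles
    chrom <- sprintf("chr%02d", rep_len(seq_len(16), m))
    pos <- 1000L + 500L * (seq_len(m) - 1L) %/% 16L
    snps <- data.frame(id = sprintf("snp_%05d", seq_len(m)), chrom = chrom,
                       pos = pos,
                       ref = rep_len(c("A", "C", "G", "T"), m),
                       alt = rep_len(c("G", "T", "A", "C"), m),
                       stringsAsFactors = FALSE)
    geno <- new_genotype_matrix(dos, isolates, snps, encoding = "raw012")
    geno$subpop <- subpop
    list(geno = geno, subpop = subpop)
  })
}

#' Derive PAV and CNV matrices coupled to population structure
#'
#' Presence/absence profiles follow the isolate's subpopulation with
#' probability `coupling` and are independent noise otherwise; copy-number
#' profiles use a strictly lower coupling (`coupling * cnv_coupling_factor`),
#' reproducing the empirical ordering in which kinship correlates with PAV
#' similarity much more than with CNV similarity.
#'
#' @param geno genotype matrix from [simulate_population()] (used for isolate
#'   ids and, when present, subpopulation labels).
#' @param config the [population_config()].
#' @param coupling fraction in `[0, 1]`.
#' @param subpop optional explicit subpopulation factor.
#' @param cnv_coupling_factor multiplier (< 1) applied to `coupling` for CNV.
#' @return list with `pav` and `cnv`, both `fs_orf` matrices.
#' @export
derive_structural_variants <- function(geno, config, coupling = 0.7,
                                       subpop = NULL,
                                       cnv_coupling_factor = 0.3) {
  stopifnot(inherits(config, "population_config"), is_fraction(coupling))
  subpop <- subpop %||% geno$subpop
  if (is.null(subpop)) stop("subpopulation labels required")
  with_seed(derive_seed(config$seed, "structural"), {
    n <- length(geno$isolates); m <- config$n_orfs; k <- nlevels(subpop)
    s <- as.integer(subpop)
    orfs <- sprintf("orf_%04d", seq_len(m))

    # PAV: subpop-level absence template vs independent noise
    template <- matrix(rbinom(k * m, 1L, config$pav_absence_rate), k, m)
    noise <- matrix(rbinom(n * m, 1L, config$pav_absence_rate), n, m)
    follow <- matrix(runif(n * m) < coupling, n, m)
    absent <- ifelse(follow, template[s, , drop = FALSE], noise)
    pav <- 1L - absent

    # CNV: same construction over copy states, weaker coupling
    states <- config$cnv_copy_states
    w <- ifelse(states == 1, 0.7, 0.3 / max(1, sum(states != 1)))
    draw_states <- function(len) sample(states, len, replace = TRUE, prob = w)
    cnv_template <- matrix(draw_states(k * m), k, m)
    cnv_noise <- matrix(draw_states(n * m), n, m)
    cnv_follow <- matrix(runif(n * m) < coupling * cnv_coupling_factor, n, m)
    cnv <- ifelse(cnv_follow, cnv_template[s, , drop = FALSE], cnv_noise)

    list(pav = new_orf_matrix(pav, geno$isolates, orfs, "PAV"),
         cnv = new_orf_matrix(cnv, geno$isolates, orfs, "CNV"))
  })
}

# resolve feature ids like "snp_00012" / "pav_0003" / "orf_0003" / "cnv_0003"
# against the three variant matrices; returns the numeric column.
feature_column <- function(id, geno, pav, cnv) {
  if (id %in% geno$snps$id) {
    x <- geno$dosages[, match(id, geno$snps$id)]
    if (anyNA(x)) x[is.na(x)] <- mean(x, na.rm = TRUE)
    return(x)
  }
  base <- sub("^(pav|cnv)_", "orf_", id)
  if (startsWith(id, "pav") || (!is.null(pav) && startsWith(id, "orf"))) {
    j <- match(base, pav$orfs)
    if (!is.na(j)) return(pav$values[, j])
  }
  if (startsWith(id, "cnv")) {
    j <- match(base, cnv$orfs)
    if (!is.na(j)) return(cnv$values[, j])
  }
  stop("unknown feature id: ", id)
}

#' Simulate multi-environment fitness with known genetic ground truth
#'
#' Per environment, a genetic value is assembled from sampled (or explicit)
#' additive QTL dosage effects, dominance effects on heterozygosity
#' indicators, planted product interactions, an optional major locus, and an
#' optional environment-correlated polygenic term; Gaussian noise is scaled
#' so the realized heritability approximates `target_h2`. Fitness is
#' presented on a colony-size-ratio-like scale (location 1, spread 0.3) and
#' shifted to be strictly positive if needed.
#'
#' @param geno,pav,cnv variant matrices (`pav`/`cnv` may be `NULL` when no
#'   QTL uses those channels).
#' @param arch a [trait_architecture()].
#' @param seed integer seed for this stage.
#' @return list with `fitness` (`fs_fitness`) and `truth` (`fs_truth`).
#' @export
simulate_fitness <- function(geno, pav = NULL, cnv = NULL, arch, seed = 1L) {
  stopifnot(inherits(arch, "trait_architecture"))
  n <- length(geno$isolates)
  n_env <- arch$n_environments
  env_names <- sprintf("env_%02d", seq_len(n_env))

  dos <- geno$dosages
  if (anyNA(dos)) {
    cm <- colMeans(dos, na.rm = TRUE)
    idx <- which(is.na(dos), arr.ind = TRUE)
    dos[idx] <- cm[idx[, 2]]
  }

  with_seed(derive_seed(seed, "polygenic"), {
    U <- NULL
    if (!is.null(arch$env_genetic_correlation)) {
      # polygenic genetic values, correlated across environments through
      # correlated marker-effect vectors: W ~ MN(0, I_p, R)
      Xs <- scale(dos)
      Xs[is.na(Xs)] <- 0
      W0 <- matrix(rnorm(ncol(Xs) * n_env), ncol(Xs), n_env)
      W <- W0 %*% chol(arch$env_genetic_correlation)
      U <- Xs %*% W / sqrt(ncol(Xs))
    }
  })

  fitness <- matrix(NA_real_, n, n_env, dimnames = list(geno$isolates, env_names))
  truth <- vector("list", n_env)
  names(truth) <- env_names

  for (e in seq_len(n_env)) {
    parts <- with_seed(derive_seed(seed, paste0("effects_", e)), {
      channels <- rep_len(arch$variant_channel, max(1, arch$n_additive_qtl))
      if (!is.null(arch$additive_qtl)) {
        aq <- if (length(arch$additive_qtl) && !is.null(arch$additive_qtl[[1]]$feature))
          arch$additive_qtl else arch$additive_qtl[[e]]
      } else if (arch$n_additive_qtl > 0) {
        aq <- list()
        pool <- list(SNP = geno$snps$id,
                     PAV = if (!is.null(pav)) sub("^orf_", "pav_", pav$orfs),
                     CNV = if (!is.null(cnv)) sub("^orf_", "cnv_", cnv$orfs))
        for (ch in unique(channels)) {
          ids <- sample(pool[[ch]], sum(channels == ch))
          aq <- c(aq, lapply(ids, function(id)
            list(feature = id, effect = rnorm(1, 0, arch$effect_scale))))
        }
      } else aq <- list()

      if (!is.null(arch$dominance_qtl)) {
        dq <- if (length(arch$dominance_qtl) && !is.null(arch$dominance_qtl[[1]]$feature))
          arch$dominance_qtl else arch$dominance_qtl[[e]]
      } else if (arch$n_dominance_qtl > 0) {
        ids <- sample(geno$snps$id, arch$n_dominance_qtl)
        dq <- lapply(ids, function(id)
          list(feature = id, effect = rnorm(1, 0, arch$effect_scale)))
      } else dq <- list()

      g <- numeric(n)
      for (q in aq) g <- g + q$effect * feature_column(q$feature, geno, pav, cnv)
      for (q in dq) {
        x <- feature_column(q$feature, geno, pav, cnv)
        g <- g + q$effect * as.numeric(abs(x - 1) < .Machine$double.eps^0.5)
      }
      for (ip in arch$interaction_pairs) {
        fa <- feature_column(ip$a, geno, pav, cnv)
        fb <- feature_column(ip$b, geno, pav, cnv)
        g <- g + ip$coef * fa * fb
      }
      if (!is.null(arch$major_locus))
        g <- g + arch$major_locus$effect *
          feature_column(arch$major_locus$feature, geno, pav, cnv)
      if (!is.null(U)) {
        sdg <- sd(g)
        g <- g + U[, e] * if (sdg > 0) sdg / max(sd(U[, e]), 1e-12) else 1
      }
      list(g = g, additive = aq, dominance = dq)
    })
    g <- parts$g

    h2 <- arch$target_h2[e]
    eps <- with_seed(derive_seed(seed, paste0("noise_", e)), rnorm(n))

    if (!is.null(arch$noise_sd)) {
      raw <- g + arch$noise_sd * eps
      f <- 1 + raw
    } else if (h2 == 0) {
      raw <- 0.3 * eps
      g <- numeric(n)           # fitness carries no genetic signal
      f <- 1 + raw
    } else {
      sdg <- sd(g)
      if (sdg == 0)
        stop("degenerate architecture: target_h2 > 0 with zero genetic variance")
      raw <- g + sdg * sqrt((1 - h2) / h2) * eps
      f <- 1 + 0.3 * (raw - mean(raw)) / sd(raw)
    }
    if (min(f) <= 0) f <- f - min(f) + 0.05
    fitness[, e] <- f
    # variance ratios are invariant to the affine presentation scale
    realized <- if (var(g) == 0) 0 else var(g) / var(raw)
    truth[[e]] <- list(environment = env_names[e],
                       additive = parts$additive,
                       dominance = parts$dominance,
                       interaction_pairs = arch$interaction_pairs,
                       major_locus = arch$major_locus,
                       target_h2 = h2, realized_h2 = realized)
  }

  ft <- structure(list(values = fitness, isolates = geno$isolates,
                       environments = env_names), class = "fs_fitness")
  tr <- structure(list(environments = truth,
                       subpop = as.character(geno$subpop %||% NA)),
                  class = "fs_truth")
  list(fitness = ft, truth = tr)
}

#' Generate a complete synthetic cohort in one call
#'
#' Convenience wrapper running [simulate_population()],
#' [derive_structural_variants()] and [simulate_fitness()] under one master
#' seed (taken from `config$seed` unless overridden).
#'
#' @param config a [population_config()].
#' @param arch a [trait_architecture()].
#' @param coupling PAV-structure coupling passed to
#'   [derive_structural_variants()].
#' @param seed optional override of the master seed.
#' @return list with `geno`, `subpop`, `pav`, `cnv`, `fitness`, `truth`.
#' @export
simulate_cohort <- function(config, arch, coupling = 0.7, seed = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  pop <- simulate_population(config)
  sv <- derive_structural_variants(pop$geno, config, coupling)
  fit <- simulate_fitness(pop$geno, sv$pav, sv$cnv, arch,
                          seed = derive_seed(config$seed, "fitness"))
  list(geno = pop$geno, subpop = pop$subpop, pav = sv$pav, cnv = sv$cnv,
       fitness = fit$fitness, truth = fit$truth)
}

#' Write a cohort to disk (VCF + TSV + truth JSON)
#'
#' Emits `genotypes.vcf` (VCF 4.2, GT field, `./.` for missing),
#' `pav.tsv` / `cnv.tsv` / `fitness.tsv` (isolate id column + one column per
#' ORF/environment) and `truth.json`, and returns a manifest with MD5
#' checksums. Round-trips losslessly through the package readers.
#'
#' @param cohort list as returned by [simulate_cohort()].
#' @param dir output directory (created if absent).
#' @return data.frame manifest (file, md5, bytes).
#' @export
write_cohort <- function(cohort, dir) {
  geno <- cohort$geno
  if (length(geno$isolates) == 0) stop("cannot write a cohort with 0 isolates")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  vcf_path <- file.path(dir, "genotypes.vcf")
  write_genotypes_vcf(geno, vcf_path)
  write_matrix_tsv(cohort$pav$values, cohort$pav$isolates, cohort$pav$orfs,
                   file.path(dir, "pav.tsv"), id_col = "isolate")
  write_matrix_tsv(cohort$cnv$values, cohort$cnv$isolates, cohort$cnv$orfs,
                   file.path(dir, "cnv.tsv"), id_col = "isolate")
  write_matrix_tsv(cohort$fitness$values, cohort$fitness$isolates,
                   cohort$fitness$environments,
                   file.path(dir, "fitness.tsv"), id_col = "isolate")
  jsonlite::write_json(unclass(cohort$truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  files <- c("genotypes.vcf", "pav.tsv", "cnv.tsv", "fitness.tsv", "truth.json")
  paths <- file.path(dir, files)
  data.frame(file = files, md5 = unname(tools::md5sum(paths)),
             bytes = file.size(paths), stringsAsFactors = FALSE)
}

#' Synthetic gene annotation over simulated SNPs
#'
#' Tiles consecutive genomic windows into synthetic "genes" so gene-level
#' analyses (interval mapping, enrichment) can run on simulated cohorts with
#' a known SNP-to-gene truth. Windows cover a configurable fraction of SNP
#' positions; uncovered SNPs are intergenic by construction.
#'
#' @param geno a genotype matrix with `snps` metadata.
#' @param snps_per_gene how many consecutive SNPs (per chromosome) one gene
#'   spans.
#' @param genic_fraction fraction of windows annotated as genes.
#' @return data.frame(gene, chrom, start, end, strand).
#' @export
synthetic_annotation <- function(geno, snps_per_gene = 5, genic_fraction = 0.8) {
  snps <- geno$snps
  out <- list()
  gid <- 0L
  for (ch in unique(snps$chrom)) {
    s <- snps[snps$chrom == ch, ]
    s <- s[order(s$pos), ]
    grp <- (seq_len(nrow(s)) - 1L) %/% snps_per_gene
    for (g in unique(grp)) {
      if (genic_fraction < 1 &&
          ((g + 1L) %% round(1 / max(1e-9, 1 - genic_fraction))) == 0)
        next  # leave every k-th window intergenic (first window always kept)
      rows <- s[grp == g, ]
      gid <- gid + 1L
      out[[gid]] <- data.frame(gene = sprintf("gene_%04d", gid), chrom = ch,
                               start = min(rows$pos), end = max(rows$pos),
                               strand = "+", stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
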