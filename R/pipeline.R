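#' Parse a plain-text pipeline configuration file
#'
#' Minimal `key = value` format (also accepts `key: value`); values are
#' auto-typed (number, TRUE/FALSE, comma-separated vectors, everything else
#' string). Lines starting with `#` are comments.
#' @param path config file path.
#' @return named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*[:=]\\s*(.*)$", ln))[[1]]
    if (length(m) < 3) stop("cannot parse config line: ", ln)
    key <- m[2]; val <- trimws(m[3])
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    typed <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(typed)) typed
                  else if (all(parts %in% c("TRUE", "FALSE"))) as.logical(parts)
                  else if (length(parts) > 1) parts else val
  }
  out
}

default_run_config <- function() {
  list(n_isolates = 200, n_subpops = 3, fst = 0.15, n_snps = 400, n_orfs = 120,
       n_environments = 3, n_additive_qtl = 10, target_h2 = 0.5,
       coupling = 0.7, algorithms = c("rrBLUP", "RF"),
       feature_types = c("PC", "SNP", "PAV", "CNV"),
       n_repeats = 2, n_trees = 60, seed = 1)
}

pipeline_hash <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

#' Run the analysis pipeline end-to-end
#'
#' Orchestrates the stages in dependency order on either a synthetic cohort
#' (default) or files named in the config (`vcf`, `pav`, `cnv`, `fitness`
#' paths): simulate/ingest, preprocess (filter, impute, kinship, PCs, GRMs),
#' fit (per environment x feature type x algorithm under the holdout +
#' repeated-CV design), select (Gini ranking + subset curve for the RF SNP
#' model), interpret (SHAP attributions and global ranks), map (synthetic
#' annotation), enrich (true causal genes as the benchmark set), crossenv
#' (environment clustering + gene-sharing permutation test), and interact
#' (interaction tensor on the top SNP features). Every artifact lands in
#' `out_dir` and is listed in the returned manifest with its MD5 checksum;
#' an audit log records the isolate ids used per phase.
#'
#' @param config named list (see `default_run_config` fields) or path to a
#'   config file; missing fields take defaults.
#' @param out_dir output directory.
#' @return manifest data.frame(stage, file, md5).
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("fitscape_run_")) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- modifyList(default_run_config(), config)

  # pre-flight: any referenced input file must exist before anything is run
  for (key in c("vcf", "pav", "cnv", "fitness")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
      stop("pre-flight error: missing input file for '", key, "': ", cfg[[key]])
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  emit <- function(stage, file) {
    manifest[[length(manifest) + 1]] <<- data.frame(
      stage = stage, file = basename(file),
      md5 = unname(tools::md5sum(file)), stringsAsFactors = FALSE)
  }

  # --- stage: simulate | ingest -------------------------------------------
  if (is.null(cfg$vcf)) {
    pc <- population_config(n_isolates = cfg$n_isolates,
                            n_subpops = cfg$n_subpops, fst = cfg$fst,
                            n_snps = cfg$n_snps, n_orfs = cfg$n_orfs,
                            seed = cfg$seed)
    arch <- trait_architecture(n_environments = cfg$n_environments,
                               n_additive_qtl = cfg$n_additive_qtl,
                               target_h2 = cfg$target_h2)
    cohort <- simulate_cohort(pc, arch, coupling = cfg$coupling)
    man <- write_cohort(cohort, file.path(out_dir, "cohort"))
    for (f in man$file) emit("simulate", file.path(out_dir, "cohort", f))
    geno <- cohort$geno; pav <- cohort$pav; cnv <- cohort$cnv
    fitness <- cohort$fitness; truth <- cohort$truth
  } else {
    geno <- read_genotypes_vcf(cfg$vcf)
    pav_m <- read_matrix_tsv(cfg$pav)
    cnv_m <- read_matrix_tsv(cfg$cnv)
    fit_m <- read_matrix_tsv(cfg$fitness)
    pav <- new_orf_matrix(pav_m, rownames(pav_m), colnames(pav_m), "PAV")
    cnv <- new_orf_matrix(cnv_m, rownames(cnv_m), colnames(cnv_m), "CNV")
    fitness <- new_fitness_table(fit_m, rownames(fit_m), colnames(fit_m))
    truth <- NULL
  }

  # --- stage: preprocess ---------------------------------------------------
  geno <- impute_missing(filter_snps(geno))
  kin <- kinship_centered_ibs(geno)
  pcs <- principal_components(geno, n = min(5, length(geno$isolates) - 1))
  grm <- relationship_matrices(geno)
  write_matrix_tsv(kin$values, kin$isolates, kin$isolates,
                   file.path(out_dir, "kinship.tsv"), id_col = "isolate")
  write_matrix_tsv(pcs$scores, rownames(pcs$scores), colnames(pcs$scores),
                   file.path(out_dir, "pcs.tsv"), id_col = "isolate")
  emit("preprocess", file.path(out_dir, "kinship.tsv"))
  emit("preprocess", file.path(out_dir, "pcs.tsv"))

  feature_sets <- list(PC = pcs$scores, SNP = geno$dosages,
                       PAV = pav$values, CNV = cnv$values)
  feature_sets <- feature_sets[intersect(cfg$feature_types, names(feature_sets))]

  # --- stage: fit ----------------------------------------------------------
  scheme <- split_scheme(n_repeats = cfg$n_repeats, seed = cfg$seed)
  split <- split_holdout(geno$isolates, scheme)
  audit <- list(train = split$train, test = split$test)
  rf_grid <- data.frame(max_depth = c(5, 10), max_features = "sqrt",
                        n_estimators = cfg$n_trees, stringsAsFactors = FALSE)
  records <- list(); fits <- list()
  for (env in fitness$environments) {
    y <- setNames(fitness$values[, env], fitness$isolates)
    for (ft in names(feature_sets)) {
      X <- feature_sets[[ft]]
      for (algo in cfg$algorithms) {
        cv <- cross_validate(X[split$train, , drop = FALSE], y[split$train],
                             algo, scheme = scheme,
                             X_test = X[split$test, , drop = FALSE],
                             y_test = y[split$test],
                             environment = env, feature_type = ft,
                             grid = if (algo %in% c("RF", "GBM")) rf_grid)
        records[[paste(env, ft, algo)]] <- cv$record
        fits[[paste(env, ft, algo)]] <- cv
      }
    }
  }
  perf <- do.call(rbind, records)
  perf_path <- file.path(out_dir, "performance.tsv")
  data.table::fwrite(perf, perf_path, sep = "\t")
  emit("fit", perf_path)
  jsonlite::write_json(audit, file.path(out_dir, "audit.json"))
  emit("fit", file.path(out_dir, "audit.json"))

  # --- stage: select + interpret (RF SNP model of the first environment) ---
  env1 <- fitness$environments[1]
  key <- paste(env1, "SNP", if ("RF" %in% cfg$algorithms) "RF" else cfg$algorithms[1])
  sel <- NULL; shap <- NULL; imp_tab <- NULL
  if ("RF" %in% cfg$algorithms) {
    cv <- fits[[key]]
    imp_tab <- rank_by_gini(cv)
    y <- setNames(fitness$values[, env1], fitness$isolates)
    sel <- feature_selection_curve(
      feature_sets$SNP[split$train, , drop = FALSE], y[split$train], imp_tab,
      variant_type = "SNP", scheme = split_scheme(n_repeats = 1, seed = cfg$seed),
      grid = rf_grid[1, , drop = FALSE], max_size = 256)
    data.table::fwrite(data.frame(size = sel$sizes, r2 = sel$scores),
                       file.path(out_dir, "selection_curve.tsv"), sep = "\t")
    emit("select", file.path(out_dir, "selection_curve.tsv"))
    shap <- compute_shap(cv$model, feature_sets$SNP[split$train, , drop = FALSE])
    shap_imp <- global_importance_rank(shap)
    data.table::fwrite(shap_imp, file.path(out_dir, "shap_importance.tsv"),
                       sep = "\t")
    emit("interpret", file.path(out_dir, "shap_importance.tsv"))
  }

  # --- stage: map + enrich -------------------------------------------------
  annot <- synthetic_annotation(geno)
  gene_map <- snp_to_gene(geno$snps, annot)
  data.table::fwrite(gene_map, file.path(out_dir, "gene_map.tsv"), sep = "\t")
  emit("map", file.path(out_dir, "gene_map.tsv"))
  if (!is.null(truth) && !is.null(imp_tab)) {
    causal <- unique(unlist(lapply(truth$environments, function(e)
      vapply(e$additive, `[[`, "", "feature"))))
    causal_genes <- unique(gene_map$gene[gene_map$feature %in% causal &
                                           !gene_map$unmapped & !gene_map$multi])
    reps <- gene_representative_feature(imp_tab, gene_map)
    if (length(causal_genes) && nrow(reps) >= 20) {
      enr <- percentile_benchmark_enrichment(reps$gene[order(-reps$importance)],
                                             causal_genes)
      data.table::fwrite(enr, file.path(out_dir, "benchmark_enrichment.tsv"),
                         sep = "\t")
      emit("enrich", file.path(out_dir, "benchmark_enrichment.tsv"))
    }
  }

  # --- stage: crossenv -----------------------------------------------------
  if (length(fitness$environments) >= 2) {
    ec <- environment_clusters(fitness)
    data.table::fwrite(data.frame(environment = names(ec$clusters),
                                  cluster = ec$clusters),
                       file.path(out_dir, "environment_clusters.tsv"), sep = "\t")
    emit("crossenv", file.path(out_dir, "environment_clusters.tsv"))
  }

  # --- stage: interact -----------------------------------------------------
  if (!is.null(shap)) {
    top <- head(global_importance_rank(shap)$feature, 15)
    rf_small <- tree_fit(feature_sets$SNP[split$train, top, drop = FALSE],
                         fitness$values[split$train, env1],
                         "RF", grid = rf_grid[1, , drop = FALSE],
                         scheme = split_scheme(n_repeats = 1, seed = cfg$seed))
    it <- shap_interaction_tensor(rf_small,
                                  feature_sets$SNP[split$train, top, drop = FALSE])
    ps <- interaction_pair_scores(it)
    data.table::fwrite(ps, file.path(out_dir, "interaction_pairs.tsv"),
                       sep = "\t")
    emit("interact", file.path(out_dir, "interaction_pairs.tsv"))
  }

  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA)
  emit("config", cfg_path)
  out <- do.call(rbind, manifest)
  out$config_hash <- pipeline_hash(cfg)
  rownames(out) <- NULL
  out
}
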