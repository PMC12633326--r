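test_that("population simulation is deterministic and respects the config", {
  cfg <- population_config(n_isolates = 80, n_snps = 120, n_orfs = 30,
                           missing_rate = 0.05, seed = 3)
  a <- simulate_population(cfg)
  b <- simulate_population(cfg)
  expect_identical(a$geno$dosages, b$geno$dosages)
  expect_identical(a$subpop, b$subpop)
  expect_true(all(a$geno$dosages %in% c(0, 1, 2) | is.na(a$geno$dosages)))
  expect_gt(mean(is.na(a$geno$dosages)), 0.02)
  expect_lt(mean(is.na(a$geno$dosages)), 0.10)
  expect_error(population_config(n_isolates = 0), "positive")
  expect_error(population_config(fst = 1.2), "fst")
  expect_error(population_config(cnv_copy_states = c(0, 2)), "reference copy")
})

test_that("fst = 0 gives no allele-frequency divergence between subpopulations", {
  cfg <- population_config(n_isolates = 600, n_subpops = 2, fst = 0,
                           n_snps = 400, missing_rate = 0, seed = 5)
  pop <- simulate_population(cfg)
  f1 <- colMeans(pop$geno$dosages[pop$subpop == "pop1", ]) / 2
  f2 <- colMeans(pop$geno$dosages[pop$subpop == "pop2", ]) / 2
  expect_lt(mean(abs(f1 - f2)), 0.05)
})

test_that("fst = 0.3 subpopulations are linearly separable on two PCs", {
  cfg <- population_config(n_isolates = 300, n_subpops = 3, fst = 0.3,
                           n_snps = 600, missing_rate = 0, seed = 7)
  pop <- simulate_population(cfg)
  pcs <- principal_components(pop$geno, n = 2)
  ld <- MASS::lda(pcs$scores, grouping = pop$subpop)
  acc <- mean(predict(ld)$class == pop$subpop)
  expect_gt(acc, 0.9)
})

test_that("structural variants couple to structure, PAV more than CNV", {
  cfg <- population_config(n_isolates = 240, n_subpops = 3, fst = 0.3,
                           n_snps = 500, n_orfs = 300, missing_rate = 0,
                           seed = 9)
  pop <- simulate_population(cfg)
  sv <- derive_structural_variants(pop$geno, cfg, coupling = 1)
  kin <- kinship_centered_ibs(pop$geno)
  lt <- lower.tri(kin$values)
  r_pav <- cor(kin$values[lt], cor(t(sv$pav$values))[lt], method = "spearman")
  r_cnv <- cor(kin$values[lt], cor(t(sv$cnv$values))[lt], method = "spearman")
  expect_gt(r_pav, r_cnv)
  expect_true(all(sv$pav$values %in% c(0, 1)))
  expect_true(all(sv$cnv$values %in% cfg$cnv_copy_states))
})

test_that("uncoupled PAV columns are independent of subpopulation labels", {
  cfg <- population_config(n_isolates = 300, n_subpops = 3, fst = 0.3,
                           n_snps = 50, n_orfs = 200, missing_rate = 0,
                           pav_absence_rate = 0.3, seed = 13)
  pop <- simulate_population(cfg)
  sv <- derive_structural_variants(pop$geno, cfg, coupling = 0)
  ps <- apply(sv$pav$values, 2, function(col) {
    if (length(unique(col)) < 2) return(NA_real_)
    suppressWarnings(chisq.test(table(col, pop$subpop))$p.value)
  })
  ps <- ps[!is.na(ps)]
  # p-values approximately uniform: no excess of small p beyond chance
  expect_lt(mean(ps < 0.05), 0.12)
  expect_gt(mean(ps), 0.35)
})

test_that("zero absence rate yields an all-present PAV matrix", {
  cfg <- population_config(n_isolates = 40, n_snps = 30, n_orfs = 25,
                           pav_absence_rate = 0, missing_rate = 0, seed = 2)
  pop <- simulate_population(cfg)
  sv <- derive_structural_variants(pop$geno, cfg, coupling = 0.5)
  expect_true(all(sv$pav$values == 1))
})

test_that("target_h2 = 0 decouples fitness from genotype", {
  cfg <- population_config(n_isolates = 300, n_snps = 150, missing_rate = 0,
                           seed = 4)
  pop <- simulate_population(cfg)
  arch <- trait_architecture(n_environments = 1, n_additive_qtl = 10,
                             target_h2 = 0)
  fit <- simulate_fitness(pop$geno, arch = arch, seed = 4)
  y <- fit$fitness$values[, 1]
  causal <- vapply(fit$truth$environments[[1]]$additive, `[[`, "", "feature")
  X <- pop$geno$dosages[, causal, drop = FALSE]
  r2 <- summary(lm(y ~ X))$r.squared
  expect_lt(r2, 0.08)
  expect_equal(fit$truth$environments[[1]]$realized_h2, 0)
  expect_true(all(y > 0))
})

test_that("a strong major locus makes fitness bimodal (density-valley oracle)", {
  # oracle: the density at the midpoint between the two 2-means centers,
  # relative to the density at the centers -- deep valley = bimodal
  valley_ratio <- function(y) {
    km <- kmeans(y, 2, nstart = 5)
    f <- approxfun(density(y)$x, density(y)$y)
    f(mean(km$centers)) / max(f(km$centers[1]), f(km$centers[2]))
  }
  cfg <- population_config(n_isolates = 500, n_snps = 100, n_orfs = 50,
                           pav_absence_rate = 0.4, missing_rate = 0, seed = 6)
  pop <- simulate_population(cfg)
  sv <- derive_structural_variants(pop$geno, cfg, coupling = 0)
  arch <- trait_architecture(n_environments = 1, n_additive_qtl = 3,
                             target_h2 = 0.9,
                             major_locus = list(feature = "pav_0005", effect = 8))
  y <- simulate_fitness(pop$geno, sv$pav, sv$cnv, arch, seed = 6)$fitness$values[, 1]
  expect_lt(valley_ratio(y), 0.5)
  # a matched polygenic trait shows no valley
  arch0 <- trait_architecture(n_environments = 1, n_additive_qtl = 30,
                              target_h2 = 0.5)
  y0 <- simulate_fitness(pop$geno, arch = arch0, seed = 6)$fitness$values[, 1]
  expect_gt(valley_ratio(y0), 0.7)
})

test_that("block environment correlations appear in fitness correlations", {
  cfg <- population_config(n_isolates = 400, n_snps = 300, missing_rate = 0,
                           seed = 8)
  pop <- simulate_population(cfg)
  R <- diag(6); R[1:3, 1:3] <- 0.9; R[4:6, 4:6] <- 0.9; diag(R) <- 1
  arch <- trait_architecture(n_environments = 6, n_additive_qtl = 0,
                             n_dominance_qtl = 0, target_h2 = 0.6,
                             env_genetic_correlation = R)
  fit <- simulate_fitness(pop$geno, arch = arch, seed = 8)
  cc <- cor(fit$fitness$values)
  within <- c(cc[1:3, 1:3][lower.tri(diag(3))], cc[4:6, 4:6][lower.tri(diag(3))])
  between <- as.vector(cc[1:3, 4:6])
  expect_gt(min(within), max(between))
})

test_that("ablating planted interactions removes the analytic variance share", {
  cfg <- population_config(n_isolates = 4000, n_subpops = 1, fst = 0,
                           n_snps = 50, maf_range = c(0.4, 0.4),
                           missing_rate = 0, seed = 10)
  pop <- simulate_population(cfg)
  ids <- pop$geno$snps$id
  qtl <- list(list(feature = ids[1], effect = 1))
  pair <- list(list(a = ids[10], b = ids[20], coef = 0.8))
  base_arch <- function(pairs) trait_architecture(
    n_environments = 1, additive_qtl = qtl, n_dominance_qtl = 0,
    interaction_pairs = pairs, target_h2 = 0.5, noise_sd = 0.5)
  f_with <- simulate_fitness(pop$geno, arch = base_arch(pair), seed = 10)
  f_without <- simulate_fitness(pop$geno, arch = base_arch(list()), seed = 10)
  dv <- var(f_with$fitness$values[, 1]) - var(f_without$fitness$values[, 1])
  # analytic: Var(c ab) for independent a, b ~ Bin(2, 0.4):
  # E[a]=0.8, Var(a)=0.48, E[a^2]=1.12 -> c^2 (1.12^2 - 0.64^2) = 0.5409
  analytic <- 0.8^2 * (1.12^2 - 0.64^2)
  expect_lt(abs(dv - analytic) / analytic, 0.10)
})

test_that("a cohort writes to disk and round-trips losslessly", {
  coh <- small_cohort(n = 40, snps = 60, orfs = 20, seed = 14)
  dir <- withr::local_tempdir()
  man <- write_cohort(coh, dir)
  expect_setequal(man$file, c("genotypes.vcf", "pav.tsv", "cnv.tsv",
                              "fitness.tsv", "truth.json"))
  expect_true(all(nchar(man$md5) == 32))
  g2 <- read_genotypes_vcf(file.path(dir, "genotypes.vcf"))
  expect_equal(g2$dosages, coh$geno$dosages)
  expect_equal(read_matrix_tsv(file.path(dir, "pav.tsv")), coh$pav$values,
               ignore_attr = FALSE)
  expect_equal(read_matrix_tsv(file.path(dir, "fitness.tsv")),
               coh$fitness$values, tolerance = 1e-12)
  expect_error(write_cohort(list(geno = list(isolates = character(0))), dir),
               "0 isolates")
})

test_that("the light VCF reader agrees with the Bioconductor reader", {
  skip_if_not_installed("VariantAnnotation")
  coh <- small_cohort(n = 25, snps = 40, orfs = 10, seed = 15,
                      missing_rate = 0.05)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  light <- read_genotypes_vcf(file.path(dir, "genotypes.vcf"))
  bioc <- suppressWarnings(
    read_genotypes_vcf(file.path(dir, "genotypes.vcf"),
                       method = "VariantAnnotation"))
  expect_equal(unname(light$dosages), unname(bioc$dosages))
})
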