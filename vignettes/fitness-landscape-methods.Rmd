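---
title: "Methods: multi-environment genomic prediction and interpretation of yeast fitness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-environment genomic prediction and interpretation of yeast fitness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

fitscape predicts the fitness of diploid budding-yeast isolates — the ratio
of colony size under a stress environment to colony size under the reference
condition — from three variant channels: biallelic SNPs, ORF
presence/absence variants (PAV), and ORF copy-number variants (CNV,
including fractional copies for partial duplications). It then interprets
the fitted models at the level of features, genes, gene sets, and gene-gene
interactions. This vignette documents the models, the parameters that
matter, the numerical choices, and what the synthetic-data tests do and do
not establish.

## Data model and pre-processing

Genotypes enter as VCF (GT field; `./.` missing) and are filtered to
single-base biallelic substitutions with minor allele frequency strictly
above 5% (computed on non-missing calls) and missing fraction strictly
below 20%. Both boundaries are enforced exactly as printed: a SNP at MAF
exactly 0.05, or missing in exactly 20% of isolates, is removed.

Two dosage encodings are supported. `raw012` counts copies of the
alternative allele (the reference genome is the all-zero profile, which is
what genetic distances to the reference background rely on). `signed` maps
major-homozygote, heterozygote and minor-homozygote to −1/0/1; when the two
alleles are exactly equifrequent the reference allele is treated as major,
a deterministic and documented tie-break.

Missing calls are imputed with the per-SNP mode of the observed calls
(ties to the lower dosage). The study this package operationalizes used
haplotype-model imputation; a haplotype imputer is deliberately out of
scope here because at most 20% of calls per SNP can be missing post-filter
and all downstream synthetic tests run on complete data. Imputed objects
are flagged so the provenance is visible.

Relationship matrices: kinship uses the centered identity-by-state
estimator K = WW′/Σ 2p(1−p) with W the column-centered dosage matrix — the
same quantity as the VanRaden additive GRM, which is why
`kinship_centered_ibs()` and the A of `relationship_matrices()` agree
exactly. The dominance GRM uses the classical parameterization:
heterozygosity indicators centered by 2pq and normalized by Σ(2pq)². The
exact normalization constant used by other implementations of centered IBS
may differ; only relative structure matters downstream, and exact equality
with any external tool's output is not claimed. Population structure is
summarized by the top principal components (five by default) of the
centered dosage matrix.

## Learners

Five learners share one evaluation harness.

**rrBLUP.** y = 1μ + Xu + e with u ~ N(0, Iσ²ᵤ). The variance ratio
λ = σ²ₑ/σ²ᵤ is profiled by REML using one eigendecomposition of XX′ and a
1-D optimization of the restricted likelihood over log λ in [−12, 12].
Marker effects are the BLUP u = X′(XX′+λI)⁻¹(y−1μ̂), equal by the
push-through identity to the explicit ridge solution — the test suite pins
this equality at 1e−8 on random instances. A zero-variance response yields
zero effects with a warning rather than an error.

**BayesC and Bayesian LASSO.** Gibbs samplers written for this package
(no whole-genome-regression package ships with the target environment).
BayesC uses a spike-slab effect prior with fixed inclusion probability
π = 0.01 (configurable) and a common slab variance with a
scaled-inverse-χ² prior (df = 5); the Bayesian LASSO uses the
normal–exponential mixture with λ² updated from a diffuse Gamma prior.
Prior scales follow the usual convention of an assumed genomic R² of 0.5
split over markers: the slab-variance prior mode is R²·var(y)/(π·Σvar(xⱼ)),
and the residual-variance prior mode is (1−R²)·var(y). Chains default to
32,000 iterations with 3,200 burn-in, the design-scale setting; tests use
1,500–2,000 iterations, which the sparse-recovery checks show is ample at
desk scale.

**Random forest and gradient boosting.** CART regression trees
(variance-reduction splits, midpoint thresholds, random feature subsets
per node) are implemented in C++ because no tree-ensemble package is
available in the target environment. RF uses bootstrap bagging and
exhaustive grid search (depth {3, 5, 10} × feature fraction
{0.1, 0.5, √p, log₂p, all} × {100, 500, 1000} trees by default) scored by
negative mean squared error under the inner cross-validation; GBM uses
randomized search (100 draws by default) over learning rate 0.01–0.4,
depth 2–10, subsample 0.5–1, column subsample 0.7–1, and 5–500 trees in
steps of 5, scored by mean R². Gini importance is the per-tree-normalized
impurity decrease averaged over trees, and over training repetitions when
several fits are supplied.

**Evaluation design.** One-sixth of isolates (rounded) are held out once
and touched only for the final test-set R²; the rest is evaluated by
five-fold cross-validation whose folds are re-randomized each repeat.
Validation R² is the mean over repeats of the pooled out-of-fold R²; the
final model refits the best-validation repeat's hyperparameters on the full
training set. R² is the squared-error coefficient of determination
1 − SSE/SST and may be negative. Repeat counts are configurable; package
defaults are desk-scale (a handful of repeats) rather than the study-scale
20/10/100, which are documented in `split_scheme()` and `ModelSpec`-style
arguments and can be restored by the user.

## Heritability

`fit_ad_mixed_model()` estimates σ²_A, σ²_D, σ²_e for
y = μ + u_A + u_D + e by REML: expectation-maximization updates (monotone
by construction; the trace is exposed and tested) with average-information
steps accepted only when they do not lower the restricted likelihood, and
non-negativity kept by projection onto a small positive floor. An all-zero
dominance matrix drops that component. The reported h² is
σ²_A/(σ²_A+σ²_D+σ²_e): the total in the denominator includes the dominance
component, the standard narrow-sense definition, even though the estimate
is sometimes loosely called narrow-sense while fitting dominance.

## Feature selection

Features are ranked by average Gini importance (zero-importance features
dropped, average ranks on ties, lexicographic order for display). Subset
sizes follow two series — powers of two (2…1024) joined with an arithmetic
series (1000·n for SNPs, 250·n for PAV/CNV, n ≤ 30) — truncated at the
available feature count. The "inflection point" of the resulting
performance curve is operationalized as the smallest size whose mean
validation R² is within δ = 0.01 of the curve maximum; δ is configurable,
and the plateau rule is deterministic where an eyeballed inflection would
not be.

## Shapley attributions and interactions

Tree ensembles are explained with the exact polynomial-time tree-path
Shapley algorithm over each tree's cover-weighted conditional
expectations; linear models use exact linear attributions
(weight × centered feature). Local accuracy — base value plus attribution
row equals the prediction — is a hard assertion at 1e−6 on every computed
attribution matrix, and the test suite additionally checks exact equality
with brute-force Shapley enumeration on small trees.

Pairwise interaction values condition the attribution recursion on one
feature being present or absent; half the difference gives that feature's
off-diagonal row. The tensor is then symmetrized and the diagonal closed
so that symmetry and the row-sum identity Σₖ Φ[i,j,k] = φ[i,j] hold to
machine precision. The quadratic cost is capped (500 features by default),
matching the intended use on reduced, benchmark-gene feature sets.

Isolates are clustered on their attribution profiles over the top 20
features (Ward linkage, Euclidean distance — `ward.D2`, the squared-
increment Ward variant). Cutting thresholds are data-dependent in the
original study and unavailable; the default here asks for eight clusters,
matching the environment-cluster granularity, and both the threshold and
the count are configurable. The cluster-fitness trend regresses each
isolate's cluster-median fitness (replicated within cluster, which keeps
the regression well-posed while using the per-isolate median |SHAP| as x)
on an ordinary least-squares line with a Wald-t p for zero slope.

## Gene mapping and enrichment

SNPs map to genes by 1-based inclusive genic intervals, strand-agnostic;
intergenic SNPs stay unmapped and SNPs under overlapping genes are flagged
multi-mapped and excluded from gene-level analyses. ORFs map to reference
genes by a two-step reciprocal best match over 12-column alignment hit
tables: the top forward hit (bit score, ties by subject id) must pass
percent identity ≥ 95 and E-value < 1e−6, and the candidate gene's top
reverse hit must return the same ORF under the same filters. Alignment
itself is consumed as tabular input, never executed. One feature
represents each gene — the highest mean |SHAP| (or Gini on request), ties
to the smaller feature id.

Enrichment uses 2×2 Fisher exact tests (two-sided; odds ratio reported as
the sample cross-ratio with zero-cell conventions documented) with a
correction variant that removes tests at p = 1 before Benjamini–Hochberg
and reports their q as undefined. Rank-percentile enrichment cuts the top
ceiling(τ·N) genes so the top set is never empty. GO annotations are read
from GAF 2.2 filtered to experimental and high-throughput evidence codes;
term membership is tested by direct annotation without propagation up the
ontology, a documented simplification.

## Cross-environment analyses

Environment clustering computes pairwise Pearson correlations on
pairwise-complete isolates, clusters the correlation profiles
(average-linkage on Euclidean distances), and reports the coarsest
partition whose within-cluster minimum pairwise r exceeds the threshold
(0.51 by default).

The gene-sharing permutation test deserves a note. The source procedure
compares the distribution of per-gene environment counts against the
per-permutation *median* row sums with a one-sided KS test. As stated,
that comparison is degenerate: any spread-out count distribution differs
from a near-point-mass of medians, so the test rejects under a completely
random presence matrix — and under the scipy/R orientation of "greater" a
strongly shared matrix actually returns p = 1. This package therefore
tests the observed counts against the pooled permuted count distribution
(each environment column shuffled independently), with the alternative
oriented so "greater" means observed sharing exceeds the null. The
per-permutation medians are still computed and returned. Under this form
the test is calibrated (random matrices give p > 0.05), detects planted
universally-shared cores, and returns p = 1 on the permutation-invariant
all-ones matrix.

The performance meta-regression is OLS with the full three-way factorial
design in heritability, median fitness and fitness variance (8
coefficients, requiring at least 9 environments), with adjusted R² and
per-observation linear attributions coefficient × (term − mean term).

## Interaction-level analyses

Predicted feature pairs aggregate to unordered gene pairs (unmapped
features skipped and counted, same-gene pairs dropped, one row per gene
pair per variant-pair kind holding the strongest supporting score).
Validated networks are 2-column edge lists, optionally filtered by the
stringent screen threshold p < 0.05 and |ε| > 0.12; overlap enrichment
reuses the Fisher + BH machinery per rank percentile. The genetic-distance
contrast clusters isolates by k-means on distance-matrix rows with k
chosen from 2–10 by the maximum discrete second difference of inertia
(with the k = 1 total sum of squares prepended so the first candidate can
be the elbow — the original chose k by eye); the cluster containing the
reference profile is compared to the remaining isolates by a one-sided
(greater) Mann–Whitney U on per-isolate median |SHAP| of benchmark-gene
features. The source text calls this test "two-sided … (alternative =
'greater')", which is contradictory; the alternative argument governs.

## The synthetic cohort generator

`simulate_population()` draws a Balding–Nichols structured population:
per-SNP ancestral frequencies from `maf_range`, subpopulation frequencies
from Beta(p(1−F)/F, (1−p)(1−F)/F), diploid dosages binomial, missingness
uniform. Defaults state a desk-scale analogue of the motivating panel:
750 isolates, 3 subpopulations, F_ST 0.15, 2,000 SNPs, 500 ORFs, 1%
missing calls. PAV profiles follow the isolate's subpopulation with
probability `coupling` (default 0.7) and CNV profiles with a strictly
smaller coupling (×0.3), reproducing the observed ordering in which
kinship correlates with PAV similarity but much less with CNV similarity;
the real generative process of structural variants is uncharacterized, so
these couplings are stated constructions, not estimates. CNV states
default to {0, 0.5, 1, 1.5, 2, 3} with 70% of mass on the single
reference copy.

Fitness is intercept 1 plus 0.3 × the standardized sum of additive QTL
effects, dominance effects on heterozygosity indicators, planted product
interactions, an optional major locus, an optional environment-correlated
polygenic term (correlated marker-effect vectors), and Gaussian noise
scaled so the realized heritability approximates the target; traits are
shifted to stay strictly positive, mimicking colony-size ratios around 1
with spread 0.3. When an explicit `noise_sd` is supplied the trait is left
on its raw scale so that variance arithmetic (e.g. interaction-ablation
checks) stays exact. Realized h² is recorded per environment as
var(genetic)/var(genetic + noise), which is affine-invariant.

What a green synthetic test establishes: that each stage implements its
stated computation, that planted structure (population clusters, QTLs,
interactions, shared genes, heritability) is recovered at the stated
sizes, and that the stages compose end-to-end. What it does not establish:
realism of linkage beyond subpopulation structure (no recombination map),
realism of the PAV/CNV generative process, transfer of the measured
recovery rates to the real panel, or any of the study's dataset-specific
headline numbers, which depend on external data and database snapshots.

Three test-world choices are worth restating. Planted-QTL recovery uses
equal-magnitude, random-sign effects: with Gaussian effects the smallest
of 20 QTLs carries arbitrarily little variance and is unrecoverable by any
method, so a recovery fraction would measure the effect-size lottery, not
the method. Planted-interaction recovery uses common causal variants
(MAF 0.2–0.5) and a purely epistatic architecture: products of rare-allele
dosages are near-constant, and the check targets epistasis recovery
specifically. The benchmark-ablation ordering uses a benchmark list
covering half the causal genes: with a complete causal benchmark the
"combined" set can only add selection-biased noise and the ordering fails
by construction, whereas the design being probed is precisely that
incomplete curated lists are complemented by important non-benchmark
genes.

## Numerical conventions

Quantiles are R type 7 (linear interpolation). Spearman correlations use
the large-sample approximation (no exact p under ties). Fisher p-values
are clamped to [0, 1] against the 1e−16 overshoot of summed hypergeometric
tails. All randomness flows from a master seed through per-stage derived
streams (`derive_seed`), so every artifact stage is independently
reproducible and identical configurations produce byte-identical cohorts
and manifests. Distances, PCs and GRMs require complete data and say so.

## Limitations

No phasing, LD pruning, or haplotype imputation; no GO-graph propagation;
no multi-task (multi-environment) learners — models are single-environment
by design; the interaction tensor is exact but quadratic, hence capped;
and BayesC's π is fixed rather than sampled. The pipeline orchestrator is
an R function (`run_pipeline()`) with a plain-text config format rather
than a shell binary; the package's functions are its interface.
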