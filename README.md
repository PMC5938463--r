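# potamorph

Shell morphometrics, clonal genetics and variance partitioning for invasive
mud snails.

Invasive European populations of the New Zealand mud snail *Potamopyrgus
antipodarum* are entirely clonal — a handful of multilocus genotypes nested
in two mitochondrial lineages — yet their shells vary enormously across
streams, lakes and brackish sites. Because the same clones recur across
habitats, the invaded range acts as a natural transplant experiment for
asking which part of shell morphology is genetic and which part is
phenotypic plasticity. `potamorph` implements the complete analysis for
that question, for morphometricians and population biologists working with
landmark data and clonal marker panels.

## What the package computes

**Geometric morphometrics.** TPS landmark I/O; centroid size
`CS = sqrt(sum_i ||p_i - centroid||^2)`; partial generalized Procrustes
superimposition (rotations restricted to det +1; tolerance 1e-10); tangent
projection; Procrustes distances `d(a, b) = min_R ||a - bR||`; multivariate
regression of shape on CS with pooled R² and permutation test; PCA and
rank-truncated CVA; permutation tests on group mean-shape distances with a
Bonferroni-adjusted threshold; Goodall's F with `df = (2k-4, (2k-4)(n1+n2-2))`.

**Clonal genetics.** Haplotype assignment and site-difference divergence;
the dosage-agnostic SNP encoding (two alphabetically ordered characters per
locus, `??` for missing); multilocus genotype collapsing; substitution
distances under pairwise deletion; Bandelt-style median-joining networks
(ε-relaxed minimum spanning network plus median vectors), exported as edge
lists and GraphML.

**Variance partitioning.** LMMs/GLMMs (via lme4) with haplotype and
genotype-nested-in-haplotype random intercepts; marginal and conditional
R² (`R²m = var(Xb) / (var(Xb) + σ²_hap + σ²_gen + σ²_dist)`, with the
random components added to the numerator for R²c); type-II Wald chi-square
tables and backward model reduction; a Kendall-tau collinearity screen.

**Synthetic cohorts.** A generator that emulates the survey — 21 sites × 20
snails, a 92/8 lineage split confined to 3 sites, the ten published SNP
genotypes, lineage-driven shape, environment-driven size, and
interaction-structured brood counts — with full ground truth for recovery
testing.

## Worked example

```r
library(potamorph)

co  <- generate_cohort(seed = 1)            # synthetic 21-site survey
al  <- tangent_project(gpa(co$configs))     # Procrustes superimposition
al
#> <aligned_shapes> 420 specimens, 20 landmarks; 4 iterations (delta 1.8e-12), tangent-projected

fit <- allometric_regression(al, n_perm = 999, seed = 2)
fit
#> <allometry_fit> n = 420, pooled R2 = 0.0305, permutation p = 0.001

p <- shape_pca(fit$residuals)
p
#> <shape_space> PC axes: PC1 73.77%, PC2 4.86%, PC3 1.71% ... (40 axes)

spn <- co$specimens
spn$pc1 <- p$pc_scores[, 1]
m <- fit_lmm(build_design(spn,
        model_spec("pc1", fixed = c("temperature", "nitrate", "latitude",
                                    "flow", "turbidity")),
        sites = co$sites))
m
#> <mixed_fit> gaussian pc1 (ML), n = 420
#>   var components: haplotype 0.003632, genotype(haplotype) 2.875e-05, residual 0.001016
#>   R2 marginal 0.0571 / conditional 0.7952; logLik 843.88
```

Reading the output: shape depends only weakly on size (allometric
R² ≈ 0.03, removed before ordination); PC1 carries most of the
size-corrected shape variance; and in the mixed model almost all of the
explained PC1 variance sits in the genetic random intercepts (conditional
R² ≈ 0.80 against a marginal R² ≈ 0.06), with the haplotype component two
orders of magnitude above the genotype component — shape is mostly
lineage. Running the same model on centroid size gives a haplotype variance
of exactly 0: size is environmental.

The genetics side works directly from the bundled genotype table:

```r
t2  <- table2_fixture()                     # ten published SNP genotypes
mlg_distance(t2$encoded[["9"]], t2$encoded[["10"]])
#> [1] 3
net <- median_joining_network(unname(t2$encoded), labels = names(t2$encoded))
net
#> <haplotype_network> 10 observed + 1 median nodes, 10 edges (epsilon = 0)
```

`run_pipeline(out_dir, seed)` chains every stage (landmarks → Procrustes →
allometry → PCA/CVA → permutation tests → genotypes → network → mixed
models → report) and writes all stage artifacts plus a manifest under
`out_dir`.

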