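---
title: "Separating genetic and plastic control of shell morphology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating genetic and plastic control of shell morphology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(potamorph)
```

## The scientific problem

Invasive European populations of the New Zealand mud snail *Potamopyrgus
antipodarum* are wholly clonal and genetically depauperate, yet their shell
morphology varies enormously across habitats. Because the same handful of
clonal lineages occurs across a wide range of streams, lakes and brackish
sites, the invaded range behaves like a natural transplant experiment: if
shell traits track the environment *within* a lineage, the variation is
plastic; if they track the lineage regardless of environment, it is genetic.
`potamorph` implements the full analysis chain for that question:

1. **Geometric morphometrics.** Twenty two-dimensional landmarks per shell
   (apex, suture–outline intersections, body-whorl extremes, aperture
   extremes and auxiliary points) are read from TPS files, superimposed by
   generalized Procrustes analysis (GPA), and summarized by centroid size
   (CS) and shape coordinates.
2. **Clonal genotyping.** Mitochondrial 16S / cyt-*b* haplotypes are
   assigned by nearest-reference matching; nuclear SNP calls are collapsed
   into multilocus genotypes with a dosage-agnostic two-characters-per-locus
   encoding, and genotype relationships are displayed as a median-joining
   network.
3. **Variance partitioning.** Linear and generalized linear mixed models
   relate shape (PC1), size (CS), shell smoothness and brood size to
   environmental covariates, with haplotype and genotype-nested-in-haplotype
   random intercepts; marginal and conditional R² split the explained
   variance into fixed (environmental) and random (genetic) shares.

## Procrustes machinery

**Superimposition.** We use *partial* Procrustes superimposition: each
configuration is centred, scaled to unit centroid size, and rotated onto the
evolving consensus with the optimal rotation restricted to determinant +1.
Reflections are disallowed by default because shells are chiral (a flag
lifts the restriction). The consensus is the arithmetic mean of the aligned
coordinates; iteration stops when its root-mean-square change falls below
`tol = 1e-10` (at most 100 iterations; non-convergence is a flagged warning,
not an error). After convergence the whole solution is rotated into a
deterministic canonical orientation (principal axes of the consensus, major
axis vertical, sign fixed by the largest-magnitude landmark), which makes
the output invariant to specimen input order.

**Tangent projection.** Shape statistics operate on the linear tangent
space at the consensus. The orthogonal projection
`x -> c + (I - cc')(x - c)` is idempotent, fixes the consensus, and agrees
with the unprojected coordinates to second order in the deviation, so for
small shape variation the choice is immaterial. Both code paths exist;
the pipeline default is projection on.

**Distances and tests.** The Procrustes distance is the root summed squared
coordinate difference after optimal superimposition. Group mean shapes are
compared by the Procrustes distance between the means (reconstructed as
consensus + mean deviation when the inputs are regression residuals), with
permutation tests that reshuffle the two groups' specimens while preserving
group sizes. P-values use the `(1 + exceedances) / (n_perm + 1)` convention,
so the attainable minimum is `1/(n_perm + 1)` and zero never occurs.
Table-wide comparisons report a Bonferroni-adjusted significance threshold
(`alpha / n_pairs`) rather than modified p-values. Goodall's F compares two
groups' mean shapes against pooled within-group variation under the
isotropic model, on `q = 2k - 4` and `q(n1 + n2 - 2)` degrees of freedom —
with `k = 20` landmarks and 19 shells per group this gives df (36, 1296).
It serves here as the digitization repeatability check.

**Allometry.** Shape coordinates are regressed on raw CS (the conventional
choice for this workflow; log-CS is a switch), the pooled R² is the summed
predicted sum of squares over all 40 coordinates divided by the summed
total, and the residuals are the size-corrected shape variables used by
PCA, CVA and the mixed models. PCA uses the covariance matrix (Procrustes
coordinates are commensurate) with the sign convention that each loading's
largest-magnitude entry is positive. CVA solves the between- versus pooled
within-group eigenproblem in the subspace spanned by the within-covariance's
non-null eigenvectors (rank truncation at relative eigenvalue 1e-10),
because Procrustes data are rank deficient by construction.

## Clonal genetics

Presence/absence SNP assays cannot resolve allele dosage in polyploids, so
each locus is encoded by its set of detected alleles: two identical
characters for a homozygote, the alphabetically sorted pair for a
heterozygote, `??` for a missing locus. Individuals sharing an encoded
string collapse into one multilocus genotype, numbered by descending
abundance. Two policies deserve note:

* **Distances use pairwise deletion.** Positions where either genotype is
  missing are skipped. Masking whole columns instead would merge the two
  published genotypes whose differences sit in columns that carry `?`
  elsewhere, contradicting the observed genotype count. Pairwise deletion
  makes the distance a pseudo-metric — symmetry and zero self-distance
  hold, the triangle inequality is not guaranteed — and the code documents
  rather than asserts the latter.
* **Missingness is a literal during collapsing.** Genotypes that differ
  only in their missing loci stay distinct, as in the published table.

The median-joining network is built Bandelt-style: an ε-relaxed minimum
spanning network over the observed genotypes (ε = 0 reduces to the minimum
spanning network, with all tied links retained), followed by greedy addition
of consensus (median) vectors of connected triplets whenever they shorten
the total network length, and cleanup of median vectors of degree < 3.
Tie-breaking is lexicographic on candidate links and median strings, so the
construction is deterministic for a fixed input order. The method is meant
for collapsed genotype sets (tens of nodes); the candidate search is capped
per round for robustness on larger inputs.

## Mixed models

Fixed effects are the site-level environmental covariates that survive a
Kendall-tau collinearity screen (threshold 0.38, with an explicit drop-list
so salinity yields to conductivity and longitude to latitude); flow
(`none < low < high`) and turbidity (`clear < unclear`) enter as integer
ordinal scores, all continuous covariates are standardized, and interaction
columns are products of the transformed columns. Random intercepts are
haplotype and genotype-within-haplotype; random slopes are not modelled.
Gaussian models are fitted by ML (REML available), binomial-logit and
Poisson-log models by Laplace approximation, all through `lme4` — the
de-facto standard fitter for this model class. Variance components are
non-negative by construction; boundary estimates are reported as exact
zeros with a flag, since "no detectable lineage variance" is itself the
scientifically interesting outcome for size.

Marginal R² is `var(Xb)` over the total of fixed, random and
distribution-specific variance; conditional R² adds the random components
to the numerator. The distribution-specific variance is the residual
variance (gaussian), π²/3 (binomial-logit), or the lognormal approximation
`log(1 + 1/λ)` with λ evaluated at the intercept plus half the
random-effect variance (Poisson-log); the choice is recorded on the result.
Model reduction drops the least significant term by type-II Wald chi-square
(each main effect tested in a refit that excludes its interactions;
interactions always leave before their main effects) until every retained
term is significant or protected, keeping a full audit trail.

Embryo counts default to a Poisson-log family — they are small counts
(0–90) — with a gaussian switch for sensitivity runs; a negative-binomial
option in the generator exists to probe Poisson misspecification. Sampling
month enters as a numeric covariate, not a cyclic factor: the survey spans
a few summer months where a monotone trend is the plausible signal.

### Identifiability of the haplotype variance

With only two mitochondrial lineages, the haplotype variance component rests
on a single contrast: any estimator of σ²~hap~ is approximately
σ²~hap~·χ²₁-distributed, whose median is 0.455 of the true value. The
*population* variance of a two-level factor is therefore not recoverable at
useful precision from one draw — a structural property of the design, not a
fitter defect. What the model does recover precisely is the *realized*
spread of the two lineage effects, which is also what matters for the
biological claim ("these two lineages differ strongly in shape"); a test
verifies that recovery directly. Components with many levels
(genotype-within-haplotype, residual) are recovered within a few percent at
the simulated sizes.

## The synthetic-data generator

The generator emulates the survey's structure so that the complete pipeline
can be validated against known truth:

* 21 sites × 20 specimens; the rare lineage (8% overall) confined to 3
  sites, mirroring the field distribution; ten multilocus genotypes with the
  published encodings, the common genotype at 80% within its lineage.
* Shape = lineage template (slender vs stout, Procrustes-separated by
  ≈0.15) + small genotype offsets + weak environmental displacements
  (temperature widening, latitude and nitrate slimming, acting mainly along
  the slender–stout axis) + an allometric displacement calibrated to a
  pooled R² near 0.03 + isotropic landmark noise + an individual width
  scatter that makes the lineages overlap continuously, as real shells do.
* CS = environment only (flow, latitude, turbidity positive; nitrate,
  coverage negative) with specimen-level noise — no lineage term, encoding
  the headline contrast (shape genetic, size plastic) as the generator's
  null configuration.
* Embryo counts are Poisson with a positive size effect and shape×flow,
  size×flow and size×turbidity interactions, so slender shells do
  relatively better in flowing water.
* Landmarks are emitted with a random rigid motion and a digitizer scale
  factor, so the TPS reader and the Procrustes machinery are genuinely
  exercised; classical measurements (shell height, aperture height/width)
  are taken off the emitted landmarks.

Magnitudes the study does not state (noise levels, effect sizes, the
embryo-model coefficients) were chosen once to be realistic for this system
and are fixed package defaults. The generator does **not** emulate spatial
autocorrelation among sites, measurement error in the environmental
covariates, within-site microhabitat structure, or temporal variation —
passing recovery tests therefore demonstrates correctness of the machinery
under the stated model, not robustness to every feature of field data.

## Numerical choices and problem sizes

Rotations use the closed-form two-dimensional optimum; tests verify it
against explicit angle-grid searches. GPA convergence is 1e-10 on the
consensus RMS change. CVA rank truncation is at relative eigenvalue 1e-10.
Permutation p-values use the +1 convention; the calibration experiment in
the test suite runs 1000 replicates of 200 permutations and checks the
type-I rate at nominal 0.05 within twice its Monte-Carlo standard error.
Recovery experiments use n = 2000 with 200 simulation seeds for variance
components and R², and 50 seeds for full-pipeline sign recovery — sizes
chosen to give stable medians on a single CPU. Random-number streams are
seeded once per experiment rather than per replicate (consecutive integer
seeds of the Mersenne twister are not independent streams; the test suite
learned this the empirical way).

## Interfaces

The package is a library in the vegan/geomorph mould: the R functions and
this vignette are the interface, `run_pipeline()` orchestrates the whole
analysis (simulate mode or user files) and persists every stage artifact
(CSV/JSON/TPS/FASTA/GraphML) under one output directory with a manifest,
and `scripts/acceptance.R` is the scripted entry point that recomputes the
headline numbers. `pipeline_report()` regenerates the summary from the
persisted stage files alone.

## Known limitations

* Two-dimensional landmarks only; no semilandmarks, sliding, or deformation
  grids.
* The median-joining search is exhaustive over triplets and intended for
  collapsed genotype sets, not for hundreds of haplotypes.
* The Poisson R² uses the lognormal approximation; strongly overdispersed
  counts deserve the negative-binomial sensitivity path.
* With two haplotype levels the haplotype variance component carries one
  degree of freedom (see above); its numerical value describes the sampled
  lineages, not a population of lineages.
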