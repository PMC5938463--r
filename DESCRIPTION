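Package: potamorph
Title: Shell Morphometrics, Clonal Genetics and Variance Partitioning for
    Invasive Mud Snails
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Disentangles genetic and plastic control of shell morphology in
    clonal populations of the New Zealand mud snail Potamopyrgus antipodarum.
    Provides TPS landmark input and output, generalized Procrustes
    superimposition with centroid size, tangent projection and Procrustes
    distances, allometric correction, principal component and canonical
    variate ordination, permutation tests on group mean-shape distances,
    Goodall's F repeatability test, classical shell measurements and
    nonparametric statistics, dosage-agnostic SNP multilocus genotype
    encoding with missing-data-aware distances and median-joining network
    reconstruction, mitochondrial haplotype assignment, and mixed-effect
    models with haplotype and genotype-nested-in-haplotype random intercepts
    including marginal and conditional R-squared and type-II Wald model
    reduction. A synthetic-data generator emulating lineage-structured shape,
    environment-driven size and fecundity supplies ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    lme4,
    stats,
    tools,
    utils
Suggests:
    car,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
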