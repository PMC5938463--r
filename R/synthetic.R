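#' Template shell landmark configurations
#'
#' Hand-specified 20-landmark outlines of a slender (freshwater-lineage-like)
#' and a stout (brackish-lineage-like) shell, following the fixed labelling
#' scheme of [landmark_labels()]: apex, six suture-outline intersections,
#' body-whorl extremes, four aperture extremes and seven auxiliary points.
#' Coordinates are returned centered with unit centroid size.
#'
#' @param width_factor horizontal stretch relative to the slender template
#'   (1 = slender; the stout default is 1.35).
#' @return A 20 x 2 matrix with unit centroid size.
#' @export
shell_template <- function(width_factor = 1) {
  base <- matrix(c(
     0.02, 1.00,   # apex
     0.10, 0.86,  -0.08, 0.80,   0.16, 0.66,  -0.14, 0.60,
     0.22, 0.45,  -0.20, 0.38,   # sutures LM2-7
     0.30, 0.22,  -0.28, 0.16,   # body whorl extremes
     0.02, 0.34,   0.18, 0.20,  -0.12, 0.16,   0.04, 0.02,  # aperture
     0.26, 0.34,  -0.24, 0.28,   0.12, 0.10,  -0.10, 0.06,
     0.06, 0.52,   0.00, 0.24,  -0.02, 0.12   # auxiliary
  ), ncol = 2L, byrow = TRUE)
  base[, 1L] <- base[, 1L] * width_factor
  center_scale(base)
}

#' Default configuration of the synthetic cohort generator
#'
#' Encodes the study conditions the analysis assumes: 21 sites of 20
#' specimens; two mitochondrial lineages at 92%/8% overall frequency with
#' the rare lineage confined to 3 sites; ten multilocus genotypes with the
#' published encodings, star-like around the common genotype (derivatives
#' 1-2 steps away plus one 6-7 step outlier); a slender and a stout
#' template shape separated by a Procrustes distance of about 0.15; shape
#' driven by lineage (dominant), small genotype offsets, weak environmental
#' effects (temperature negative, latitude and nitrate positive) and weak
#' allometry (pooled R-squared near 0.03); centroid size driven by
#' environment only (flow, latitude and turbidity positive, nitrate and
#' sunlight coverage negative); embryo counts Poisson with a positive size
#' effect and shape-by-flow, size-by-flow and size-by-turbidity
#' interactions. All magnitudes are package defaults chosen to be realistic
#' for this system; the methods vignette discusses them.
#'
#' @return A `generator_config` list; override fields as needed.
#' @export
default_generator_config <- function() {
  structure(list(
    n_sites = 21L,
    specimens_per_site = 20L,
    hap_names = c("t/22", "z2/37"),
    rare_hap_sites = 3L,          # number of sites harbouring z2/37
    rare_hap_within_freq = 0.58,  # z2/37 frequency inside those sites
    genotype_freq = list(
      "t/22" = c(`1` = 0.80, `2` = 0.06, `3` = 0.05, `4` = 0.03,
                 `5` = 0.02, `6` = 0.02, `7` = 0.01, `8` = 0.01),
      "z2/37" = c(`9` = 0.67, `10` = 0.33)),
    stout_width_factor = 1.35,
    template_mix = c("t/22" = 0, "z2/37" = 1),  # 0 = slender, 1 = stout
    geno_shape_sd = 0.004,        # per-coordinate genotype offset sd
    individual_shape_sd = 0.03,   # per-specimen scatter along the width axis
    env_shape_effects = c(temperature = -0.010, latitude = 0.010,
                          nitrate = 0.008),     # vector norms per sd
    allometry_strength = 0.010,   # shape displacement norm per CS sd
    landmark_noise_sd = 0.004,    # per-coordinate, unit-CS space
    cs_base = 5.8, cs_sd = 0.23,  # mm
    cs_effects = c(flow = 0.17, latitude = 0.15, turbidity = 0.12,
                   nitrate = -0.12, coverage = -0.09),
    embryo_coef = c(intercept = log(22), cs = 0.22, shape = -0.10,
                    shape_flow = 0.12, cs_flow = -0.08, cs_turbidity = -0.06),
    missing_rate = 0,             # per-locus specimen-level dropout; genotype-
                                  # level missingness already comes from the
                                  # published encodings (genotypes 8 and 10)
    tps_scale = 0.01              # mm per digitizer unit in emitted TPS
  ), class = "generator_config")
}

#' Synthetic haplotype reference sequences
#'
#' Deterministic stand-in reference sequences for the two mitochondrial
#' markers (the real accessions are not bundled): a 481-site 16S alignment
#' with haplotypes `t`, `z` and `z2` (t and z2 differ at six sites; z2
#' differs from z by a single further substitution) and a 497-site cyt-b
#' alignment with haplotypes `22` and `37` differing at six sites. The
#' sequences are synthetic; only their pairwise difference structure
#' mirrors the study system.
#'
#' @param marker `"16S"` or `"cytb"`.
#' @return Named character vector of aligned sequences.
#' @export
synthetic_haplotype_refs <- function(marker = c("16S", "cytb")) {
  marker <- match.arg(marker)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(20180402L)
  bases <- c("A", "C", "G", "T")
  len16 <- 481L; len_cytb <- 497L
  s16 <- sample(bases, len16, replace = TRUE)
  scb <- sample(bases, len_cytb, replace = TRUE)
  sub_at <- function(seq, pos) {
    for (p in pos) seq[p] <- bases[bases != seq[p]][1L]
    seq
  }
  if (marker == "16S") {
    t_seq <- s16
    z2 <- sub_at(t_seq, c(40L, 120L, 200L, 280L, 360L, 440L))
    z <- sub_at(z2, 456L)   # z2 differs from z by one substitution at site 456
    c(t = paste(t_seq, collapse = ""),
      z = paste(z, collapse = ""),
      z2 = paste(z2, collapse = ""))
  } else {
    h22 <- scb
    h37 <- sub_at(h22, c(50L, 140L, 230L, 320L, 410L, 490L))
    c(`22` = paste(h22, collapse = ""), `37` = paste(h37, collapse = ""))
  }
}

#' The ten published multilocus genotypes (bundled fixture)
#'
#' Returns the ten SNP genotypes over the 16 variable loci as shipped in
#' `inst/extdata/table2_genotypes.csv` (dot = same state as genotype 1,
#' `?` = missing), expanded against genotype 1 and encoded with
#' [encode_genotype()].
#'
#' @return List with `table` (expanded allele table, one row per genotype),
#'   `encoded` (named character vector, names = genotype numbers),
#'   `haplotype` (per genotype), `loci` (16 locus names).
#' @export
table2_fixture <- function() {
  path <- system.file("extdata", "table2_genotypes.csv",
                      package = "potamorph", mustWork = TRUE)
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                  colClasses = "character")
  allele_cols <- setdiff(names(raw), c("genotype", "haplotype"))
  loci <- unique(sub("_[AB]$", "", allele_cols))
  expanded <- raw
  for (cc in allele_cols)
    expanded[[cc]] <- ifelse(raw[[cc]] == ".", raw[[cc]][1L], raw[[cc]])
  encoded <- vapply(seq_len(nrow(expanded)), function(i) {
    calls <- lapply(loci, function(lc) {
      al <- c(expanded[[paste0(lc, "_A")]][i], expanded[[paste0(lc, "_B")]][i])
      if (any(al == "?")) "?" else al
    })
    encode_genotype(calls)
  }, character(1))
  list(table = expanded,
       encoded = setNames(encoded, raw$genotype),
       haplotype = setNames(raw$haplotype, raw$genotype),
       loci = loci)
}

ordinal_score <- function(x, levels) as.numeric(match(x, levels) - 1L)

#' Generate a synthetic site environment table
#'
#' One row per site: water temperature, conductivity, salinity (generated
#' as conductivity times a factor plus small noise, so the collinearity
#' screen has something to find), pH, nitrite, nitrate, flow class
#' (none/low/high), sunlight coverage (%), turbidity (clear/unclear),
#' latitude and correlated longitude, and sampling month.
#'
#' @param config a [default_generator_config()] (fields `n_sites` used).
#' @param seed RNG seed (optional; set it for reproducibility).
#' @return Data frame with one row per site.
#' @export
generate_sites <- function(config = default_generator_config(), seed = NULL) {
  if (config$n_sites < 2L) stop("config error: need at least 2 sites")
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_sites
  conductivity <- rnorm(n, 800, 250)
  latitude <- rnorm(n, 52.5, 1.5)
  data.frame(
    site_id = sprintf("S%02d", seq_len(n)),
    temperature = round(rnorm(n, 16, 3), 1),
    salinity = round(conductivity * 5e-4 + rnorm(n, 0, 0.01), 3),
    conductivity = round(conductivity, 0),
    ph = round(rnorm(n, 7.8, 0.4), 2),
    nitrite = round(exp(rnorm(n, -2, 0.7)), 3),
    nitrate = round(pmax(rnorm(n, 10, 4), 0.1), 2),
    flow = sample(c("none", "low", "high"), n, replace = TRUE,
                  prob = c(0.45, 0.35, 0.20)),
    coverage = round(runif(n, 0, 100), 0),
    turbidity = sample(c("clear", "unclear"), n, replace = TRUE,
                       prob = c(0.6, 0.4)),
    latitude = round(latitude, 4),
    longitude = round(4 + 1.2 * (latitude - 52.5) + rnorm(n, 0, 1.8), 4),
    month = sample(6:9, n, replace = TRUE),
    stringsAsFactors = FALSE)
}

#' Generate a complete synthetic cohort with recorded ground truth
#'
#' Draws, per specimen: a haplotype (the rare lineage confined to
#' `rare_hap_sites` sites), a multilocus genotype within the haplotype, a
#' centroid size driven only by environmental factors, and a shape composed
#' of the lineage template, a genotype-specific offset, environmental
#' displacement vectors, an allometric displacement proportional to CS, and
#' isotropic landmark noise. Landmark configurations are emitted at mm
#' scale with a random rigid motion (so the Procrustes machinery has work
#' to do); classical measurements (shell height, aperture height/width) are
#' measured off the emitted landmarks; whorl counts, ridging and embryo
#' counts are drawn from the configured models. Genotype calls are decoded
#' from the assigned genotype's encoded string with per-locus missingness.
#'
#' @param config a [default_generator_config()].
#' @param seed RNG seed; the same seed reproduces the cohort bit-for-bit.
#' @return List with `configs` (landmark configurations), `specimens`,
#'   `sites`, `genotypes` (per-specimen call table), `haplotype_refs`
#'   (16S and cyt-b reference sets), `truth` (per-specimen assignments,
#'   true effect vectors and all generator parameters).
#' @export
generate_cohort <- function(config = default_generator_config(), seed = 1L) {
  set.seed(seed)
  sites <- generate_sites(config)
  n_sites <- config$n_sites
  nps <- config$specimens_per_site
  n <- n_sites * nps
  site_idx <- rep(seq_len(n_sites), each = nps)

  t2 <- table2_fixture()
  hap_of_geno <- t2$haplotype

  slender <- shell_template(1)
  stout <- shell_template(config$stout_width_factor)
  # lineage axis: unit displacement from slender to stout
  lin_axis <- as.vector(t(stout - slender))
  lin_norm <- sqrt(sum(lin_axis^2))
  lin_unit <- lin_axis / lin_norm

  rare_sites <- sort(sample.int(n_sites, config$rare_hap_sites))
  p_rare <- ifelse(site_idx %in% rare_sites, config$rare_hap_within_freq, 0)
  hap <- ifelse(runif(n) < p_rare, config$hap_names[2L], config$hap_names[1L])
  geno <- vapply(hap, function(h) {
    f <- config$genotype_freq[[h]]
    sample(names(f), 1L, prob = f)
  }, character(1))

  # genotype-specific shape offsets (random directions, small norm)
  geno_levels <- names(hap_of_geno)
  geno_offsets <- matrix(rnorm(length(geno_levels) * 40L, 0,
                               config$geno_shape_sd),
                         nrow = length(geno_levels),
                         dimnames = list(geno_levels, NULL))

  # environmental shape effects act mainly along the slender-stout axis
  # (as the field system suggests: temperature widens, latitude and nitrate
  # slim the shell) with a small random off-axis component; allometry may
  # point anywhere.
  rand_unit <- function() { v <- rnorm(40L); v / sqrt(sum(v^2)) }
  slender_axis <- -lin_unit
  env_dirs <- lapply(config$env_shape_effects, function(mag) {
    ortho <- rand_unit()
    ortho <- ortho - sum(ortho * slender_axis) * slender_axis
    mag * slender_axis + 0.3 * abs(mag) * ortho
  })
  allo_dir <- rand_unit() * config$allometry_strength

  std <- function(x) (x - mean(x)) / sd(x)
  env_std <- data.frame(
    temperature = std(sites$temperature), latitude = std(sites$latitude),
    nitrate = std(sites$nitrate), coverage = std(sites$coverage))
  flow_sc <- ordinal_score(sites$flow, c("none", "low", "high"))
  turb_sc <- ordinal_score(sites$turbidity, c("clear", "unclear"))

  cs_eff <- config$cs_effects
  cs_mean_site <- config$cs_base +
    cs_eff["flow"] * flow_sc + cs_eff["latitude"] * env_std$latitude +
    cs_eff["turbidity"] * turb_sc + cs_eff["nitrate"] * env_std$nitrate +
    cs_eff["coverage"] * env_std$coverage
  cs <- rnorm(n, cs_mean_site[site_idx], config$cs_sd)
  cs <- pmax(cs, 0.3 * config$cs_base)
  cs_std_all <- std(cs)

  mix <- config$template_mix

  shape_env <- matrix(0, n, 40L)
  for (v in names(env_dirs))
    shape_env <- shape_env + outer(env_std[[v]][site_idx], env_dirs[[v]])
  shape_allo <- outer(cs_std_all, allo_dir)
  shape_geno <- geno_offsets[geno, , drop = FALSE]
  # individual (non-genetic, non-measured) width variation: lineages overlap
  shape_indiv <- outer(rnorm(n, 0, config$individual_shape_sd), slender_axis)
  shape_noise <- matrix(rnorm(n * 40L, 0, config$landmark_noise_sd), n, 40L) +
    shape_indiv

  configs <- vector("list", n)
  ids <- sprintf("sp%04d", seq_len(n))
  shape_flat <- matrix(NA_real_, n, 40L)
  height <- numeric(n)
  for (i in seq_len(n)) {
    tmpl <- (1 - mix[[hap[i]]]) * slender + mix[[hap[i]]] * stout
    dev <- shape_env[i, ] + shape_allo[i, ] + shape_geno[i, ] + shape_noise[i, ]
    shp <- tmpl + matrix(dev, ncol = 2L, byrow = TRUE)
    shape_flat[i, ] <- as.vector(t(shp))
    m0 <- shp / centroid_size(shp) * cs[i]   # upright, mm
    height[i] <- diff(range(m0[, 2L]))
    theta <- runif(1, -pi, pi)
    R <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2L)
    m <- sweep(m0 %*% R, 2L, -runif(2, -10, 10))  # random rigid motion
    configs[[i]] <- landmark_config(m, specimen_id = ids[i],
                                    scale = 1, image = NA_character_)
    configs[[i]]$scale <- config$tps_scale   # metadata for TPS emission
  }
  # use shape-space aperture landmarks (rotation-free) scaled by CS
  ap_h <- abs(shape_flat[, 2L * 10L] - shape_flat[, 2L * 13L]) * cs
  ap_w <- abs(shape_flat[, 2L * 11L - 1L] - shape_flat[, 2L * 12L - 1L]) * cs
  whorls <- pmin(pmax(round((3.875 + 0.45 * std(height) +
                             rnorm(n, 0, 0.25)) * 8) / 8, 2.5), 6)
  ridged <- runif(n) < stats::plogis(-4 + 3.2 * (hap == config$hap_names[2L]) +
                                     1.2 * (turb_sc[site_idx] == 0))
  slender_score <- std(-drop(shape_flat %*% lin_unit))  # + = more slender
  ec <- config$embryo_coef
  flow_c <- flow_sc[site_idx] - mean(flow_sc[site_idx])
  turb_i <- turb_sc[site_idx]
  log_lambda <- ec["intercept"] + ec["cs"] * cs_std_all +
    ec["shape"] * slender_score + ec["shape_flow"] * slender_score * flow_c +
    ec["cs_flow"] * cs_std_all * flow_c + ec["cs_turbidity"] * cs_std_all * turb_i
  embryos <- rpois(n, exp(log_lambda))

  specimens <- data.frame(
    specimen_id = ids, site_id = sites$site_id[site_idx],
    shell_height = round(height, 4),
    aperture_height = round(ap_h, 4), aperture_width = round(ap_w, 4),
    whorls = whorls, ridged = ridged, embryo_count = embryos,
    sex = "f", infected = FALSE,
    haplotype = hap, genotype = geno, stringsAsFactors = FALSE)

  # per-specimen SNP calls decoded from the genotype encoding, with missingness
  enc <- t2$encoded[geno]
  call_mat <- t(vapply(enc, decode_genotype,
                       character(length(t2$loci))))
  miss <- matrix(runif(n * length(t2$loci)) < config$missing_rate, n)
  call_mat[miss] <- "?"
  genotype_table <- data.frame(specimen_id = ids,
                               site_id = sites$site_id[site_idx],
                               call_mat, stringsAsFactors = FALSE,
                               check.names = FALSE)
  names(genotype_table) <- c("specimen_id", "site_id", t2$loci)

  truth <- list(
    seed = seed, config = config,
    per_specimen = data.frame(specimen_id = ids,
                              site_id = sites$site_id[site_idx],
                              haplotype = hap, genotype = geno,
                              cs_true = cs, slender_score = slender_score),
    env_shape_dirs = env_dirs, allometry_dir = allo_dir,
    lineage_axis = lin_axis, geno_offsets = geno_offsets,
    rare_sites = sites$site_id[rare_sites])

  list(configs = configs, specimens = specimens, sites = sites,
       genotypes = genotype_table,
       haplotype_refs = list(`16S` = synthetic_haplotype_refs("16S"),
                             cytb = synthetic_haplotype_refs("cytb")),
       truth = truth, config = config)
}

#' Write a synthetic cohort to disk in the pipeline's input formats
#'
#' Emits `landmarks.tps`, `specimens.csv`, `sites.csv`, `genotypes.csv`,
#' `haplotypes_16s.fasta`, `haplotypes_cytb.fasta` and `truth.json`.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tps(cohort$configs, file.path(dir, "landmarks.tps"))
  write.csv(cohort$specimens, file.path(dir, "specimens.csv"),
            row.names = FALSE)
  write.csv(cohort$sites, file.path(dir, "sites.csv"), row.names = FALSE)
  write.csv(cohort$genotypes, file.path(dir, "genotypes.csv"),
            row.names = FALSE)
  write_haplotypes(cohort$haplotype_refs$`16S`,
                   file.path(dir, "haplotypes_16s.fasta"))
  write_haplotypes(cohort$haplotype_refs$cytb,
                   file.path(dir, "haplotypes_cytb.fasta"))
  truth <- cohort$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
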