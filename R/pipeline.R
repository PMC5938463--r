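#' Run the end-to-end shell morphology analysis
#'
#' Orchestrates the full workflow on either a synthetic cohort (default) or
#' user-supplied input files: landmark reading, generalized Procrustes
#' superimposition (optionally tangent-projected), allometric correction,
#' PCA and CVA, pairwise group mean-shape permutation tests, haplotype
#' divergence, multilocus genotype collapsing and median-joining network
#' reconstruction, the collinearity screen on the environment table, and
#' mixed models for shape (PC1), centroid size, shell smoothness and embryo
#' counts (the last with shape-by-environment and size-by-environment
#' interactions). Stage outputs are written as named CSV/JSON artifacts
#' together with a run manifest, so the report can be regenerated from the
#' persisted files alone.
#'
#' @param out_dir output directory (created; stage files written inside).
#' @param seed RNG seed governing simulation and permutation tests.
#' @param config [default_generator_config()] for simulate mode, or a list
#'   `list(mode = "files", tps = ..., specimens = ..., sites = ...,
#'   genotypes = ...)` of input paths.
#' @param n_perm permutation rounds for the allometry and group-distance
#'   tests (default 999; the headline study convention is 10000).
#' @param distance_groups grouping for the pairwise mean-shape tests:
#'   `"haplotype"` (default) or `"site"` (site-level tests multiply the
#'   number of pairs and hence runtime).
#' @param tangent apply tangent projection before shape statistics
#'   (default `TRUE`).
#' @param reduce apply backward model reduction to the fitted models
#'   (default `FALSE`: full models, as summarized in the report).
#' @param models subset of `c("pc1", "cs", "smoothness", "embryos")`.
#' @return Invisibly, a list with all stage results (`cohort`, `aligned`,
#'   `allometry`, `pca`, `cva`, `distances`, `genetics`, `models`,
#'   `report`, `manifest`); the same content is persisted under `out_dir`.
#' @export
run_pipeline <- function(out_dir, seed = 1L,
                         config = default_generator_config(),
                         n_perm = 999L,
                         distance_groups = c("haplotype", "site"),
                         tangent = TRUE, reduce = FALSE,
                         models = c("pc1", "cs", "smoothness", "embryos")) {
  distance_groups <- match.arg(distance_groups)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(fmt, ...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   sprintf(fmt, ...))
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    message(msg)
  }
  manifest <- list(package_version = as.character(packageVersion("potamorph")),
                   seed = seed, n_perm = n_perm, stages = list())
  timed <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
    manifest$stages[[stage]] <<- list(seconds = round(proc.time()[["elapsed"]] - t0, 2))
    logf("stage %s done (%.1fs)", stage, proc.time()[["elapsed"]] - t0)
    res
  }

  # --- inputs -------------------------------------------------------------
  cohort <- timed("inputs", {
    if (!is.null(config$mode) && identical(config$mode, "files")) {
      list(configs = read_tps(config$tps),
           specimens = read.csv(config$specimens, stringsAsFactors = FALSE),
           sites = read.csv(config$sites, stringsAsFactors = FALSE),
           genotypes = read_genotype_csv(config$genotypes),
           haplotype_refs = list(`16S` = synthetic_haplotype_refs("16S"),
                                 cytb = synthetic_haplotype_refs("cytb")),
           truth = NULL, config = config)
    } else {
      co <- generate_cohort(config, seed = seed)
      write_cohort(co, file.path(out_dir, "inputs"))
      co
    }
  })
  manifest$n_specimens <- length(cohort$configs)
  manifest$n_sites <- nrow(cohort$sites)

  # --- morphometrics ------------------------------------------------------
  aligned <- timed("gpa", {
    al <- gpa(cohort$configs)
    if (tangent) al <- tangent_project(al)
    export_aligned(al, file.path(out_dir, "aligned_coords.csv"))
    al
  })
  allom <- timed("allometry",
    allometric_regression(aligned, n_perm = min(n_perm, 999L),
                          seed = seed + 1L))
  pca <- timed("pca", {
    p <- shape_pca(allom$residuals)
    write.csv(data.frame(specimen_id = aligned$specimen_ids,
                         p$pc_scores[, seq_len(min(10L, ncol(p$pc_scores)))]),
              file.path(out_dir, "pc_scores.csv"), row.names = FALSE)
    write.csv(data.frame(axis = seq_along(p$pct_variance),
                         eigenvalue = p$eigenvalues,
                         pct_variance = p$pct_variance),
              file.path(out_dir, "variance_table.csv"), row.names = FALSE)
    p
  })
  spn <- cohort$specimens
  cva <- timed("cva", {
    cv <- shape_cva(allom$residuals, spn$haplotype)
    write.csv(data.frame(specimen_id = aligned$specimen_ids, cv$cv_scores),
              file.path(out_dir, "cv_scores.csv"), row.names = FALSE)
    cv
  })
  distances <- timed("group_distances", {
    gg <- if (distance_groups == "haplotype") spn$haplotype else spn$site_id
    gd <- pairwise_group_distances(allom$residuals, gg, n_perm = n_perm,
                                   seed = seed + 2L,
                                   consensus = allom$consensus)
    write.csv(gd$table, file.path(out_dir, "group_distances.csv"),
              row.names = FALSE)
    gd
  })

  # --- genetics -----------------------------------------------------------
  genetics <- timed("genetics", {
    refs16 <- cohort$haplotype_refs$`16S`
    refscb <- cohort$haplotype_refs$cytb
    div16 <- pairwise_divergence(refs16[["t"]], refs16[["z2"]])
    divcb <- pairwise_divergence(refscb[["22"]], refscb[["37"]])
    enc <- encode_genotype_table(cohort$genotypes)
    mlg <- collapse_mlg(unname(enc), ids = names(enc),
                        loci = setdiff(names(cohort$genotypes),
                                       c("specimen_id", "site_id")))
    net <- median_joining_network(mlg)
    write_network(net, edge_csv = file.path(out_dir, "network_edges.csv"),
                  graphml = file.path(out_dir, "network.graphml"))
    list(divergence_16s = div16, divergence_cytb = divcb, mlg = mlg,
         network = net)
  })

  # --- models -------------------------------------------------------------
  model_fits <- timed("models", {
    screen <- screen_collinear(
      cohort$sites[c("temperature", "salinity", "conductivity", "ph",
                     "nitrite", "nitrate", "coverage", "latitude",
                     "longitude", "month")],
      threshold_tau = 0.38,
      drop_list = c(salinity = "conductivity", longitude = "latitude"))
    env <- c(intersect(screen$retained,
                       c("temperature", "conductivity", "ph", "nitrite",
                         "nitrate", "coverage", "latitude", "month")),
             "flow", "turbidity")
    spn2 <- spn
    spn2$pc1 <- pca$pc_scores[, 1L]
    spn2$cs <- unname(aligned$centroid_sizes)
    spn2$smoothness <- as.integer(!spn2$ridged)  # 1 = smooth, 0 = ridged
    fits <- list()
    if ("pc1" %in% models)
      fits$pc1 <- fit_lmm(build_design(spn2, model_spec("pc1", "gaussian",
                                                        fixed = env),
                                       sites = cohort$sites))
    if ("cs" %in% models)
      fits$cs <- fit_lmm(build_design(spn2, model_spec("cs", "gaussian",
                                                       fixed = env),
                                      sites = cohort$sites))
    if ("smoothness" %in% models)
      fits$smoothness <- fit_glmm(build_design(
        spn2, model_spec("smoothness", "binomial", fixed = env),
        sites = cohort$sites), family = "binomial")
    if ("embryos" %in% models) {
      inter <- list(c("pc1", "flow"), c("pc1", "nitrate"),
                    c("pc1", "coverage"), c("pc1", "ph"),
                    c("cs", "flow"), c("cs", "turbidity"))
      inter <- Filter(function(ia) all(ia %in% c(env, "pc1", "cs")), inter)
      fits$embryos <- fit_glmm(build_design(
        spn2, model_spec("embryo_count", "poisson",
                         fixed = c("pc1", "cs", env),
                         interactions = inter),
        sites = cohort$sites), family = "poisson")
    }
    if (reduce) {
      fits <- lapply(fits, function(f)
        reduce_model(f$design, family = f$family)$fit)
    }
    for (nm in names(fits)) {
      co <- fits[[nm]]$coefficients
      write.csv(co, file.path(out_dir, sprintf("coefficients_%s.csv", nm)),
                row.names = FALSE)
    }
    attr(fits, "screen") <- screen
    fits
  })
  names(model_fits) <- sub("^embryos$", "embryos", names(model_fits))

  report <- pipeline_report(list(pca = pca, cva = cva, distances = distances,
                                 genetics = genetics, models = model_fits,
                                 allometry = allom, aligned = aligned))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(report_text(report), file.path(out_dir, "report.txt"))
  manifest$inputs <- if (!is.null(config$mode) && config$mode == "files")
    lapply(config[c("tps", "specimens", "sites", "genotypes")],
           function(p) unname(tools::md5sum(p)))
  else list(simulated = TRUE, generator_seed = seed)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  logf("pipeline complete: %s", out_dir)
  invisible(list(cohort = cohort, aligned = aligned, allometry = allom,
                 pca = pca, cva = cva, distances = distances,
                 genetics = genetics, models = model_fits, report = report,
                 manifest = manifest, out_dir = out_dir))
}

#' Summarize pipeline stage outputs into a machine-readable report
#'
#' Builds the summary document (variance components, marginal/conditional
#' R-squared, Wald tables, PC/CV variance shares, group distance matrix
#' with Bonferroni flags, network summary and effect directions) either
#' from the in-memory stage list returned by [run_pipeline()] or from a run
#' directory containing the persisted stage files.
#'
#' @param run a [run_pipeline()] stage list, or a path to a run directory.
#' @return A nested list (serializable to JSON). Missing stages are
#'   reported as `NULL` with a `gaps` entry naming them.
#' @export
pipeline_report <- function(run) {
  if (is.character(run)) return(report_from_dir(run))
  gaps <- character(0)
  rep <- list()
  if (!is.null(run$allometry))
    rep$allometry <- list(r_squared = run$allometry$r_squared,
                          permutation_p = run$allometry$permutation_p)
  else gaps <- c(gaps, "allometry")
  if (!is.null(run$pca)) {
    pct <- run$pca$pct_variance
    rep$pca <- list(pc1_pct = pct[1L],
                    pc1_3_pct = sum(pct[seq_len(min(3L, length(pct)))]))
  } else gaps <- c(gaps, "pca")
  if (!is.null(run$cva)) {
    cpct <- run$cva$cv_pct_variance
    rep$cva <- list(cv1_pct = cpct[1L],
                    cv1_3_pct = sum(cpct[seq_len(min(3L, length(cpct)))]))
  } else gaps <- c(gaps, "cva")
  if (!is.null(run$distances))
    rep$group_distances <- run$distances$table
  else gaps <- c(gaps, "distances")
  if (!is.null(run$genetics)) {
    net <- run$genetics$network
    rep$genetics <- list(
      divergence_16s = run$genetics$divergence_16s,
      divergence_cytb = run$genetics$divergence_cytb,
      n_genotypes = nrow(run$genetics$mlg$genotypes),
      n_variable_loci = length(run$genetics$mlg$variable_loci),
      network = list(n_observed = sum(net$nodes$type == "observed"),
                     n_median = sum(net$nodes$type == "median"),
                     n_edges = nrow(net$edges),
                     total_length = sum(net$edges$weight)))
  } else gaps <- c(gaps, "genetics")
  if (!is.null(run$models) && length(run$models)) {
    rep$models <- lapply(run$models, function(f) {
      wt <- wald_type2(f)
      co <- f$coefficients[f$coefficients$name != "(Intercept)", ]
      list(family = f$family, n = f$n,
           variance_components = list(
             haplotype = f$var_haplotype,
             genotype_in_haplotype = f$var_genotype_in_haplotype,
             residual = f$var_residual),
           r2_marginal = f$r2_marginal, r2_conditional = f$r2_conditional,
           wald = wt,
           effect_directions = data.frame(
             term = co$name,
             sign = ifelse(co$estimate >= 0, "positive", "negative"),
             estimate = co$estimate))
    })
  } else gaps <- c(gaps, "models")
  rep$gaps <- if (length(gaps)) gaps else NULL
  rep
}

report_from_dir <- function(dir) {
  jpath <- file.path(dir, "report.json")
  if (file.exists(jpath)) return(jsonlite::read_json(jpath, simplifyVector = TRUE))
  rep <- list(); gaps <- character(0)
  vt <- file.path(dir, "variance_table.csv")
  if (file.exists(vt)) {
    v <- read.csv(vt)
    rep$pca <- list(pc1_pct = v$pct_variance[1L],
                    pc1_3_pct = sum(v$pct_variance[seq_len(min(3L, nrow(v)))]))
  } else gaps <- c(gaps, "pca")
  gd <- file.path(dir, "group_distances.csv")
  if (file.exists(gd)) rep$group_distances <- read.csv(gd)
  else gaps <- c(gaps, "distances")
  ne <- file.path(dir, "network_edges.csv")
  if (file.exists(ne)) {
    e <- read.csv(ne)
    rep$genetics <- list(network = list(n_edges = nrow(e),
                                        total_length = sum(e$weight)))
  } else gaps <- c(gaps, "genetics")
  rep$gaps <- if (length(gaps)) gaps else NULL
  rep
}

report_text <- function(rep) {
  out <- c("== shell morphology pipeline report ==")
  if (!is.null(rep$allometry))
    out <- c(out, sprintf("allometry: R2 = %.4f (perm p = %.4g)",
                          rep$allometry$r_squared,
                          rep$allometry$permutation_p))
  if (!is.null(rep$pca))
    out <- c(out, sprintf("PCA: PC1 %.2f%%, PC1-3 %.2f%%",
                          rep$pca$pc1_pct, rep$pca$pc1_3_pct))
  if (!is.null(rep$cva))
    out <- c(out, sprintf("CVA: CV1 %.2f%%, CV1-3 %.2f%%",
                          rep$cva$cv1_pct, rep$cva$cv1_3_pct))
  if (!is.null(rep$genetics))
    out <- c(out, sprintf("genotypes: %d (%d variable loci); network: %d edges, total length %g",
                          rep$genetics$n_genotypes,
                          rep$genetics$n_variable_loci,
                          rep$genetics$network$n_edges,
                          rep$genetics$network$total_length))
  for (nm in names(rep$models)) {
    m <- rep$models[[nm]]
    out <- c(out, sprintf("model %s (%s): R2m %.4f R2c %.4f; var(hap) %.4g var(gen|hap) %.4g",
                          nm, m$family, m$r2_marginal, m$r2_conditional,
                          m$variance_components$haplotype,
                          m$variance_components$genotype_in_haplotype))
  }
  out
}
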