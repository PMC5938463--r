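# shared simulator for nested-random-intercept data
sim_nested <- function(n_hap, gen_per_hap, n_per_gen, s2_hap, s2_gen, s2_res,
                       beta_x = 0, seed = 1) {
  set.seed(seed)
  hap <- rep(seq_len(n_hap), each = gen_per_hap * n_per_gen)
  gen <- rep(seq_len(n_hap * gen_per_hap), each = n_per_gen)
  u_h <- rnorm(n_hap, 0, sqrt(s2_hap))
  u_g <- rnorm(n_hap * gen_per_hap, 0, sqrt(s2_gen))
  x <- rnorm(length(hap))
  y <- beta_x * x + u_h[hap] + u_g[gen] + rnorm(length(hap), 0, sqrt(s2_res))
  data.frame(y = y, x = x,
             haplotype = paste0("h", hap),
             genotype = paste0("g", gen))
}

test_that("design building standardizes, codes ordinals, and checks nesting", {
  spn <- data.frame(
    specimen_id = sprintf("s%d", 1:6),
    site_id = rep(c("A", "B", "C"), 2),
    y = rnorm(6), haplotype = "h1", genotype = c("g1", "g2"))
  sites <- data.frame(site_id = c("A", "B", "C"),
                      temperature = c(10, 15, 20),
                      flow = c("none", "low", "high"),
                      turbidity = c("clear", "unclear", "clear"))
  d <- build_design(spn, model_spec("y", fixed = c("temperature", "flow",
                                                   "turbidity")),
                    sites = sites)
  expect_lt(abs(mean(d$frame$temperature)), 1e-12)
  expect_equal(sd(d$frame$temperature), 1)
  expect_setequal(unique(d$frame$flow), c(0, 1, 2))
  expect_setequal(unique(d$frame$turbidity), c(0, 1))
  # interactions are products of the transformed columns
  d2 <- build_design(spn, model_spec("y", fixed = c("temperature", "flow"),
                                     interactions = list(c("temperature", "flow"))),
                     sites = sites)
  expect_equal(d2$frame$temperature_x_flow,
               d2$frame$temperature * d2$frame$flow)
  # corrupted nesting: same genotype under two haplotypes
  bad <- spn
  bad$haplotype <- rep(c("h1", "h2"), each = 3)
  bad$genotype <- "g1"
  expect_error(build_design(bad, model_spec("y", fixed = "temperature"),
                            sites = sites),
               "nesting violation")
  # missing data are excluded with a count
  spn$y[1] <- NA
  d3 <- build_design(spn, model_spec("y", fixed = "temperature"),
                     sites = sites)
  expect_equal(d3$excluded_n, 1L)
})

test_that("with no group variance the LMM matches ordinary least squares", {
  df <- sim_nested(2, 5, 40, 0, 0, 1, beta_x = 0.7, seed = 2)
  d <- build_design(df, model_spec("y", fixed = "x"))
  fit <- fit_lmm(d)
  ols <- lm(d$frame$.y ~ d$frame$x)
  expect_equal(unname(fit$beta), unname(coef(ols)), tolerance = 1e-6)
  expect_true(all(c("haplotype", "genotype") %in% fit$boundary) ||
              fit$var_haplotype + fit$var_genotype_in_haplotype < 0.01)
})

test_that("balanced one-way REML matches the method-of-moments estimator", {
  set.seed(3)
  g <- rep(sprintf("h%02d", 1:12), each = 25)
  y <- rnorm(12, 0, sqrt(0.5))[as.integer(factor(g))] + rnorm(300)
  df <- data.frame(y = y, haplotype = g)
  d <- build_design(df, model_spec("y", random = "haplotype"))
  fit <- fit_lmm(d, REML = TRUE)
  mom <- mom_oneway(y, g)
  skip_if(mom$sigma2_between <= 0)   # boundary case: estimator undefined
  expect_equal(fit$var_haplotype, mom$sigma2_between, tolerance = 1e-6)
  expect_equal(fit$var_residual, mom$sigma2_within, tolerance = 1e-6)
})

test_that("GLMM with vanishing group variance matches a plain GLM", {
  set.seed(4)
  n <- 600
  x <- rnorm(n)
  df <- data.frame(y = rbinom(n, 1, stats::plogis(-0.3 + 0.8 * x)), x = x,
                   haplotype = rep(c("h1", "h2"), each = n / 2),
                   genotype = rep(sprintf("g%d", 1:6), each = n / 6))
  d <- build_design(df, model_spec("y", family = "binomial", fixed = "x"))
  fit <- fit_glmm(d, "binomial")
  ref <- glm(.y ~ x, data = d$frame, family = binomial())
  skip_if(fit$var_haplotype + fit$var_genotype_in_haplotype > 1e-4)
  expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-3)
})

test_that("Poisson GLMM recovers a log-linear size effect", {
  set.seed(5)
  n <- 2000
  cs_std <- rnorm(n)
  gen <- rep(sprintf("g%d", 1:20), each = n / 20)
  hap <- rep(c("h1", "h2"), each = n / 2)
  y <- rpois(n, exp(3 + 0.5 * cs_std))
  df <- data.frame(y = y, cs_std = cs_std, haplotype = hap, genotype = gen)
  fit <- fit_glmm(build_design(df, model_spec("y", family = "poisson",
                                              fixed = "cs_std")), "poisson")
  slope <- fit$coefficients$estimate[fit$coefficients$name == "cs_std"]
  expect_lt(abs(slope - 0.5) / 0.5, 0.1)
  expect_equal(fit$method, "Laplace")
})

test_that("logistic GLMM recovers the realized lineage spread", {
  # two lineage levels contain one contrast's worth of information, so the
  # estimable quantity is the realized spread of the two effects
  ratios <- vapply(1:40, function(s) {
    set.seed(100 + s)
    u <- rnorm(2, 0, 2)
    hap <- rep(c("h1", "h2"), each = 200)
    y <- rbinom(400, 1, stats::plogis(u[as.integer(factor(hap))]))
    df <- data.frame(y = y, haplotype = hap,
                     genotype = rep(sprintf("g%d", 1:4), each = 100))
    fit <- fit_glmm(build_design(df, model_spec("y", family = "binomial",
                                                fixed = character())),
                    "binomial")
    realized <- abs(diff(u)) / 2
    sqrt(fit$var_haplotype) / realized
  }, numeric(1))
  expect_gt(median(ratios), 0.5)
  expect_lt(median(ratios), 2)
})

test_that("marginal and conditional R2 behave at the degenerate limits", {
  set.seed(6)
  # intercept-only, no random terms
  df <- data.frame(y = rnorm(100))
  d0 <- build_design(df, model_spec("y", random = character()))
  f0 <- fit_lmm(d0)
  expect_equal(f0$r2_marginal, 0)
  expect_equal(f0$r2_conditional, 0)
  # noiseless fixed-effect-only data
  x <- rnorm(100)
  d1 <- build_design(data.frame(y = 2 * x, x = x),
                     model_spec("y", fixed = "x", random = character()))
  f1 <- suppressWarnings(fit_lmm(d1))   # lm warns on a perfect fit
  expect_gt(f1$r2_marginal, 0.999999)
  expect_gt(f1$r2_conditional, 0.999999)
  # binomial distribution-specific variance is pi^2/3
  r2 <- r2_nakagawa(fit_glmm(build_design(
    data.frame(y = rbinom(200, 1, 0.5), haplotype = rep(c("a", "b"), 100),
               genotype = rep(c("g1", "g2", "g3", "g4"), 50)),
    model_spec("y", family = "binomial")), "binomial"))
  expect_equal(r2$distribution_variance, pi^2 / 3)
})

test_that("single-coefficient Wald chi-square equals the squared z", {
  df <- sim_nested(3, 4, 25, 0.2, 0.1, 1, beta_x = 0.4, seed = 7)
  fit <- fit_lmm(build_design(df, model_spec("y", fixed = "x")))
  wt <- wald_type2(fit)
  z <- fit$coefficients$z[fit$coefficients$name == "x"]
  expect_equal(wt$chisq[wt$term == "x"], z^2, tolerance = 1e-9)
  expect_equal(wt$df, 1L)
})

test_that("type-II Wald p-values are uniform for a pure-noise predictor", {
  set.seed(300)
  ps <- vapply(1:300, function(s) {
    n <- 250
    df <- data.frame(y = rnorm(n), x = rnorm(n), z = rnorm(n))
    fit <- fit_lmm(build_design(df, model_spec("y", fixed = c("x", "z"),
                                               random = character())))
    wald_type2(fit)$p[1]
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("Wald and likelihood-ratio chi-squares agree asymptotically", {
  df <- sim_nested(4, 5, 100, 0.1, 0.05, 1, beta_x = 0.15, seed = 8)
  d <- build_design(df, model_spec("y", fixed = "x"))
  fit <- fit_lmm(d)
  wt <- wald_type2(fit)
  drop_fit <- potamorph:::fit_mixed(d, "gaussian", drop_terms = "x")
  lrt <- 2 * (fit$log_likelihood - drop_fit$log_likelihood)
  expect_lt(abs(wt$chisq[wt$term == "x"] - lrt) / lrt, 0.15)
})

test_that("type-II refitting makes main-effect tests ignore their interactions", {
  set.seed(9)
  n <- 500
  x <- rnorm(n); z <- rnorm(n)
  y <- 0.5 * x + 0.5 * x * z + rnorm(n)
  df <- data.frame(y = y, x = x, z = z)
  d <- build_design(df, model_spec("y", fixed = c("x", "z"),
                                   interactions = list(c("x", "z")),
                                   random = character()))
  fit <- fit_lmm(d)
  wt <- wald_type2(fit)
  expect_setequal(wt$term, c("x", "z", "x:z"))
  # the x main-effect test must come from a model without x:z
  fit_nox <- potamorph:::fit_mixed(d, "gaussian", drop_terms = "x:z")
  z_x <- with(fit_nox$coefficients, z[name == "x"])
  expect_equal(wt$chisq[wt$term == "x"], z_x^2, tolerance = 1e-9)
})

test_that("type-II Wald tests agree with an independent implementation", {
  skip_if_not_installed("car")
  df <- sim_nested(3, 4, 30, 0.3, 0.1, 1, beta_x = 0.4, seed = 12)
  df$z <- rnorm(nrow(df))
  fit <- fit_lmm(build_design(df, model_spec("y", fixed = c("x", "z"))))
  ours <- wald_type2(fit)
  ref <- as.data.frame(car::Anova(fit$model, type = 2))
  expect_equal(ours$chisq[match(c("x", "z"), ours$term)],
               ref$Chisq[match(c("x", "z"), rownames(ref))],
               tolerance = 1e-6)
})

test_that("model reduction strips noise, keeps signal, and is deterministic", {
  set.seed(10)
  n <- 400
  df <- data.frame(y = rnorm(n), a = rnorm(n), b = rnorm(n), c = rnorm(n))
  d <- build_design(df, model_spec("y", fixed = c("a", "b", "c"),
                                   random = character()))
  red <- reduce_model(d)
  expect_length(red$fit$terms, 0)   # all-noise reduces to intercept-only
  expect_equal(nrow(red$dropped), 3)
  # one strong predictor among noise is retained
  keeps <- vapply(1:100, function(s) {
    set.seed(500 + s)
    df <- data.frame(y = NA, a = rnorm(200), b = rnorm(200), c = rnorm(200))
    df$y <- 0.5 * df$a + rnorm(200)
    red <- reduce_model(build_design(df,
      model_spec("y", fixed = c("a", "b", "c"), random = character())))
    "a" %in% names(red$fit$terms)
  }, logical(1))
  expect_gte(mean(keeps), 0.95)
  # interactions leave before their main effects
  set.seed(11)
  df2 <- data.frame(x = rnorm(300), z = rnorm(300))
  df2$y <- 0.6 * df2$x + rnorm(300)
  d2 <- build_design(df2, model_spec("y", fixed = c("x", "z"),
                                     interactions = list(c("x", "z")),
                                     random = character()))
  red2 <- reduce_model(d2)
  if ("x:z" %in% red2$dropped$term && "x" %in% red2$dropped$term)
    expect_lt(which(red2$dropped$term == "x:z"),
              which(red2$dropped$term == "x"))
  expect_true("x" %in% names(red2$fit$terms))
  # deterministic: same data, same trail
  red2b <- reduce_model(d2)
  expect_equal(red2$dropped, red2b$dropped)
})
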