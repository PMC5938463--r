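#' Specify a mixed model for the morphology pipeline
#'
#' Declares response, family, fixed environmental terms, interactions and
#' the genetic random-intercept structure used throughout the analysis
#' (haplotype, and genotype nested in haplotype).
#'
#' @param response response column name (e.g. `"pc1"`, `"cs"`,
#'   `"smoothness"`, `"embryos"`).
#' @param family `"gaussian"`, `"binomial"` (logit) or `"poisson"` (log).
#' @param fixed character vector of fixed-effect column names.
#' @param interactions list of length-2 character vectors, each an
#'   interaction between two columns (products formed after scaling).
#' @param random character vector of grouping columns; the default encodes
#'   haplotype plus genotype-within-haplotype intercepts. Use `character(0)`
#'   for a fixed-effects-only model.
#' @return A `model_spec` list.
#' @export
model_spec <- function(response, family = c("gaussian", "binomial", "poisson"),
                       fixed = character(), interactions = list(),
                       random = c("haplotype", "genotype")) {
  structure(list(response = response, family = match.arg(family),
                 fixed = fixed, interactions = interactions, random = random),
            class = "model_spec")
}

#' Build model matrices and grouping indices
#'
#' Merges specimen and site tables, transforms predictors (continuous
#' columns standardized to mean 0 / sd 1; ordinal factors coded as integer
#' scores, flow `none < low < high` as 0/1/2 and turbidity
#' `clear < unclear` as 0/1), forms interaction columns as products of the
#' transformed columns, and validates the nested grouping (every genotype
#' level must map to exactly one haplotype). Specimens with a missing
#' response, predictor or grouping value are excluded with a logged count.
#'
#' @param specimens per-specimen data frame (must contain `site_id` when
#'   `sites` is given, plus the grouping and response columns).
#' @param spec a [model_spec()].
#' @param sites optional per-site environment data frame with `site_id`.
#' @param ordinal named list of ordered level vectors for ordinal columns
#'   (default: flow and turbidity codings above).
#' @return Object of class `model_design`: list with `frame` (response,
#'   transformed predictors, groups), `terms` (term -> column names),
#'   `spec`, `scaling` (centre/sd per continuous column), `excluded_n`.
#' @export
build_design <- function(specimens, spec, sites = NULL,
                         ordinal = list(flow = c("none", "low", "high"),
                                        turbidity = c("clear", "unclear"))) {
  stopifnot(inherits(spec, "model_spec"))
  df <- as.data.frame(specimens)
  if (!is.null(sites)) {
    if (!("site_id" %in% names(df)) || !("site_id" %in% names(sites)))
      stop("both tables need a site_id column for merging")
    df <- merge(df, as.data.frame(sites), by = "site_id", sort = FALSE)
  }
  needed <- unique(c(spec$response, spec$fixed, unlist(spec$interactions),
                     spec$random))
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("design error: missing columns: ", paste(missing_cols, collapse = ", "))
  keep <- complete.cases(df[needed])
  excluded <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  if (!nrow(df)) stop("design error: no complete cases")

  frame <- data.frame(row.names = seq_len(nrow(df)))
  frame$.y <- df[[spec$response]]
  scaling <- list()
  base_cols <- unique(c(spec$fixed, unlist(spec$interactions)))
  col_name <- function(v) make.names(v)
  for (v in base_cols) {
    x <- df[[v]]
    if (v %in% names(ordinal)) {
      lev <- ordinal[[v]]
      if (!all(x %in% lev))
        stop(sprintf("design error: '%s' has values outside %s", v,
                     paste(lev, collapse = "<")))
      frame[[col_name(v)]] <- as.numeric(match(x, lev) - 1L)
    } else if (is.numeric(x)) {
      s <- sd(x)
      if (s == 0) stop(sprintf("design error: constant column '%s'", v))
      frame[[col_name(v)]] <- (x - mean(x)) / s
      scaling[[v]] <- c(center = mean(x), sd = s)
    } else if (is.logical(x)) {
      frame[[col_name(v)]] <- as.numeric(x)
    } else stop(sprintf("design error: column '%s' is not numeric, logical or ordinal", v))
  }
  terms <- as.list(setNames(col_name(spec$fixed), spec$fixed))
  for (ia in spec$interactions) {
    nm <- paste(ia, collapse = ":")
    cn <- paste(col_name(ia), collapse = "_x_")
    frame[[cn]] <- frame[[col_name(ia[1L])]] * frame[[col_name(ia[2L])]]
    terms[[nm]] <- cn
  }
  if (length(spec$random) == 2L) {
    hap <- as.factor(df[[spec$random[1L]]])
    gen <- as.factor(df[[spec$random[2L]]])
    map <- unique(data.frame(g = gen, h = hap))
    if (anyDuplicated(map$g))
      stop("nesting violation: a genotype occurs under more than one haplotype")
    frame$.haplotype <- hap
    frame$.genotype <- factor(paste(hap, gen, sep = ":"))
  } else if (length(spec$random) == 1L) {
    frame$.haplotype <- as.factor(df[[spec$random[1L]]])
  } else if (length(spec$random) > 2L) {
    stop("at most two nested random grouping columns are supported")
  }
  structure(list(frame = frame, terms = terms, spec = spec,
                 scaling = scaling, excluded_n = excluded),
            class = "model_design")
}

#' @export
print.model_design <- function(x, ...) {
  cat(sprintf("<model_design> %s ~ %s; random: %s; n = %d (%d excluded)\n",
              x$spec$response, paste(names(x$terms), collapse = " + "),
              paste(x$spec$random, collapse = " + "),
              nrow(x$frame), x$excluded_n))
  invisible(x)
}

design_formula <- function(design, drop_terms = character()) {
  keep <- setdiff(names(design$terms), drop_terms)
  cols <- unlist(design$terms[keep], use.names = FALSE)
  rhs <- if (length(cols)) paste(cols, collapse = " + ") else "1"
  ran <- character(0)
  if (!is.null(design$frame$.haplotype)) ran <- "(1 | .haplotype)"
  if (!is.null(design$frame$.genotype)) ran <- c(ran, "(1 | .genotype)")
  list(fixed_only = as.formula(paste(".y ~", rhs)),
       full = as.formula(paste(c(paste(".y ~", rhs), ran), collapse = " + ")),
       has_random = length(ran) > 0L, kept = keep)
}

fit_mixed <- function(design, family = "gaussian", REML = FALSE,
                      drop_terms = character()) {
  fm <- design_formula(design, drop_terms)
  dat <- design$frame
  family <- match.arg(family, c("gaussian", "binomial", "poisson"))
  boundary <- character(0)
  if (!fm$has_random) {
    if (family == "gaussian") {
      m <- lm(fm$fixed_only, data = dat)
      var_res <- sum(m$residuals^2) / (if (REML) m$df.residual else nrow(dat))
      method <- if (REML) "REML" else "ML"
    } else {
      m <- glm(fm$fixed_only, data = dat,
               family = if (family == "binomial") stats::binomial()
                        else stats::poisson())
      var_res <- NA_real_
      method <- "ML"
    }
    beta <- coef(m); beta <- beta[!is.na(beta)]   # aliased columns
    V <- vcov(m)
    var_hap <- var_gen <- 0
    ll <- as.numeric(logLik(m))
    model <- m
  } else {
    if (family == "gaussian") {
      model <- lme4::lmer(fm$full, data = dat, REML = REML,
                          control = lme4::lmerControl(calc.derivs = FALSE))
      method <- if (REML) "REML" else "ML"
    } else {
      model <- lme4::glmer(fm$full, data = dat,
                           family = if (family == "binomial") stats::binomial()
                                    else stats::poisson(),
                           control = lme4::glmerControl(calc.derivs = FALSE))
      method <- "Laplace"
    }
    vc <- as.data.frame(lme4::VarCorr(model))
    getv <- function(grp) {
      i <- which(vc$grp == grp)
      if (length(i)) vc$vcov[i[1L]] else 0
    }
    var_hap <- getv(".haplotype")
    var_gen <- getv(".genotype")
    var_res <- if (family == "gaussian") getv("Residual") else NA_real_
    if (var_hap <= 1e-12) { var_hap <- 0; boundary <- c(boundary, "haplotype") }
    if (!is.null(dat$.genotype) && var_gen <= 1e-12) {
      var_gen <- 0; boundary <- c(boundary, "genotype")
    }
    beta <- lme4::fixef(model)
    V <- as.matrix(vcov(model))
    ll <- as.numeric(logLik(model))
  }
  se <- sqrt(diag(V))
  coefs <- data.frame(name = names(beta), estimate = unname(beta),
                      se = unname(se), z = unname(beta / se))
  X <- model.matrix(fm$fixed_only, dat)
  # rank-deficient designs: the fitter may drop columns
  X <- X[, names(beta), drop = FALSE]
  fit <- structure(
    list(design = design, family = family, method = method,
         drop_terms = drop_terms, terms = design$terms[fm$kept],
         coefficients = coefs, vcov = V, X = X, beta = beta,
         var_haplotype = var_hap, var_genotype_in_haplotype = var_gen,
         var_residual = var_res, boundary = boundary,
         log_likelihood = ll, model = model, n = nrow(dat)),
    class = "mixed_fit")
  r2 <- r2_nakagawa(fit)
  fit$r2_marginal <- r2$r2_marginal
  fit$r2_conditional <- r2$r2_conditional
  fit
}

#' Fit a linear mixed model with nested genetic random intercepts
#'
#' Gaussian mixed model `y = Xb + u_hap + u_gen + e` with independent
#' random intercepts for haplotype and genotype-within-haplotype, fitted by
#' maximum likelihood (or REML) via lme4. Variance components are
#' constrained non-negative; boundary estimates are reported as exact zeros
#' with a flag. When the design declares no random terms the model reduces
#' to ordinary least squares.
#'
#' @param design a [build_design()] result.
#' @param REML use REML instead of ML (default `FALSE`).
#' @return Object of class `mixed_fit` with elements `coefficients`
#'   (estimate, se, z), `var_haplotype`, `var_genotype_in_haplotype`,
#'   `var_residual`, `log_likelihood`, `method`, `r2_marginal`,
#'   `r2_conditional`, `boundary`, and the underlying lme4 fit in `model`.
#' @export
fit_lmm <- function(design, REML = FALSE) {
  fit_mixed(design, family = "gaussian", REML = REML)
}

#' Fit a generalized linear mixed model with nested genetic random intercepts
#'
#' Binomial-logit (shell smoothness) or Poisson-log (embryo counts) mixed
#' model with the same random structure as [fit_lmm()], estimated by
#' Laplace-approximate maximum likelihood via lme4. No residual variance is
#' reported for these families.
#'
#' @param design a [build_design()] result.
#' @param family `"binomial"` or `"poisson"`.
#' @return A `mixed_fit` (see [fit_lmm()]).
#' @export
fit_glmm <- function(design, family = c("binomial", "poisson")) {
  fit_mixed(design, family = match.arg(family))
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat(sprintf("<mixed_fit> %s %s (%s), n = %d\n", x$family,
              x$design$spec$response, x$method, x$n))
  cat(sprintf("  var components: haplotype %.4g, genotype(haplotype) %.4g%s%s\n",
              x$var_haplotype, x$var_genotype_in_haplotype,
              if (is.na(x$var_residual)) ""
              else sprintf(", residual %.4g", x$var_residual),
              if (length(x$boundary))
                sprintf(" [boundary: %s]", paste(x$boundary, collapse = ", "))
              else ""))
  cat(sprintf("  R2 marginal %.4f / conditional %.4f; logLik %.2f\n",
              x$r2_marginal, x$r2_conditional, x$log_likelihood))
  invisible(x)
}

#' Marginal and conditional R-squared for a mixed fit
#'
#' Variance-partition R-squared: the marginal value is the variance of the
#' fixed-effect linear predictor over the total
#' (`fixed + random + distribution-specific`), the conditional value adds
#' the random-intercept components to the numerator. The
#' distribution-specific variance is the residual variance for gaussian
#' models, `pi^2 / 3` for binomial-logit, and the lognormal approximation
#' `log(1 + 1/lambda)` (with `lambda` evaluated at the intercept plus half
#' the random-effect variance) for Poisson-log models; the choice is
#' recorded in the result.
#'
#' @param fit a `mixed_fit`.
#' @return List with `r2_marginal`, `r2_conditional`,
#'   `distribution_variance`, `distribution_variance_method`.
#' @export
r2_nakagawa <- function(fit) {
  stopifnot(inherits(fit, "mixed_fit"))
  eta_fixed <- drop(fit$X %*% fit$beta)
  var_f <- if (length(eta_fixed) > 1L) var(eta_fixed) else 0
  var_ran <- fit$var_haplotype + fit$var_genotype_in_haplotype
  if (fit$family == "gaussian") {
    var_dist <- fit$var_residual; how <- "residual variance"
  } else if (fit$family == "binomial") {
    var_dist <- pi^2 / 3; how <- "logit link: pi^2/3"
  } else {
    b0 <- if ("(Intercept)" %in% names(fit$beta))
      fit$beta[["(Intercept)"]] else mean(eta_fixed)
    lambda <- exp(b0 + 0.5 * var_ran)
    var_dist <- log1p(1 / lambda)
    how <- "log link: lognormal approximation log(1 + 1/lambda)"
  }
  total <- var_f + var_ran + var_dist
  if (total <= 0) stop("undefined R2: zero total variance")
  list(r2_marginal = var_f / total,
       r2_conditional = (var_f + var_ran) / total,
       distribution_variance = var_dist,
       distribution_variance_method = how)
}

# interaction terms (a:b) containing a given main term
containing_interactions <- function(term, all_terms) {
  ints <- all_terms[grepl(":", all_terms, fixed = TRUE)]
  ints[vapply(strsplit(ints, ":", fixed = TRUE),
              function(p) term %in% p, logical(1))]
}

#' Type-II Wald chi-square table
#'
#' For each fixed term, the Wald statistic `b' V^-1 b` over the term's
#' coefficients, computed from a refit that includes all other terms except
#' the interactions containing the tested term (the type-II marginality
#' principle); interactions themselves are tested in the full model. A
#' singular sub-covariance triggers rank-adjusted degrees of freedom with a
#' warning.
#'
#' @param fit a `mixed_fit`.
#' @return Data frame with `term`, `chisq`, `df`, `p`.
#' @export
wald_type2 <- function(fit) {
  stopifnot(inherits(fit, "mixed_fit"))
  term_names <- names(fit$terms)
  rows <- lapply(term_names, function(tn) {
    higher <- if (grepl(":", tn, fixed = TRUE)) character(0)
              else containing_interactions(tn, term_names)
    f <- if (length(higher))
      fit_mixed(fit$design, fit$family,
                REML = identical(fit$method, "REML"),
                drop_terms = union(fit$drop_terms, higher))
    else fit
    cols <- fit$design$terms[[tn]]
    idx <- match(cols, names(f$beta))
    idx <- idx[!is.na(idx)]
    if (!length(idx))   # term aliased out of a rank-deficient design
      return(data.frame(term = tn, chisq = NA_real_, df = 0L, p = NA_real_))
    b <- f$beta[idx]
    V <- f$vcov[idx, idx, drop = FALSE]
    qrV <- qr(V)
    df <- length(b)
    if (qrV$rank < df) {
      warning(sprintf("singular covariance for term '%s': rank-adjusted df", tn))
      df <- qrV$rank
    }
    chisq <- tryCatch(drop(t(b) %*% solve(V, b)),
                      error = function(e) drop(t(b) %*% MASS_ginv(V) %*% b))
    data.frame(term = tn, chisq = chisq, df = df,
               p = pchisq(chisq, df, lower.tail = FALSE))
  })
  do.call(rbind, rows)
}

# small Moore-Penrose fallback to avoid a MASS dependency
MASS_ginv <- function(M, tol = 1e-10) {
  s <- svd(M)
  keep <- s$d > tol * max(s$d)
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Backward model reduction on type-II Wald tests
#'
#' Iteratively refits the model, dropping the least-significant droppable
#' term (p above `alpha`) until all retained terms are significant or
#' protected. A main effect is only droppable once no retained interaction
#' contains it, so interactions always leave the model before their main
#' effects. The full audit trail of drops is returned.
#'
#' @param design a [build_design()] result.
#' @param family model family (as in [fit_mixed] wrappers).
#' @param alpha retention threshold (default 0.05).
#' @param protect terms never dropped.
#' @param REML passed to the gaussian fit.
#' @return List with `fit` (final `mixed_fit`), `dropped` (data frame:
#'   `step`, `term`, `chisq`, `df`, `p`), `wald` (final Wald table).
#' @export
reduce_model <- function(design, family = "gaussian", alpha = 0.05,
                         protect = character(), REML = FALSE) {
  dropped <- data.frame(step = integer(), term = character(),
                        chisq = numeric(), df = integer(), p = numeric())
  drop_terms <- character(0)
  step <- 0L
  repeat {
    design_now <- design
    design_now$terms <- design$terms[setdiff(names(design$terms), drop_terms)]
    fit <- fit_mixed(design_now, family, REML = REML)
    if (!length(fit$terms)) break
    wt <- wald_type2(fit)
    retained <- wt$term
    droppable <- vapply(retained, function(tn) {
      if (tn %in% protect) return(FALSE)
      if (!grepl(":", tn, fixed = TRUE) &&
          length(containing_interactions(tn, retained))) return(FALSE)
      TRUE
    }, logical(1))
    cand <- wt[droppable & wt$p > alpha, , drop = FALSE]
    if (!nrow(cand)) break
    worst <- cand[which.max(cand$p), ]
    step <- step + 1L
    dropped <- rbind(dropped, cbind(step = step, worst))
    drop_terms <- c(drop_terms, worst$term)
  }
  list(fit = fit, dropped = dropped,
       wald = if (length(fit$terms)) wald_type2(fit) else NULL)
}
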