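#' Multivariate regression of shape on centroid size (allometry)
#'
#' Fits an independent least-squares regression of every Procrustes
#' coordinate on centroid size and pools the fit into a single R-squared:
#' the summed predicted sums of squares over all 2k coordinates divided by
#' the summed total (centered) sums of squares. Significance is assessed by
#' permuting CS against shapes and recomputing the pooled predicted SS, with
#' `p = (1 + #(perm >= obs)) / (n_perm + 1)`. The residuals (with column
#' means restored to zero) are the size-corrected shape variables used
#' downstream.
#'
#' @param aligned an `aligned_shapes` object from [gpa()] (optionally
#'   tangent-projected), or an n x 2k shape matrix if `cs` is given.
#' @param cs centroid sizes (taken from `aligned` when omitted).
#' @param n_perm number of permutation rounds for the p-value (0 to skip).
#' @param seed RNG seed for the permutations.
#' @param log_cs regress on log(CS) instead of raw CS (default `FALSE`, the
#'   conventional choice for these data).
#' @return Object of class `allometry_fit`: list with `slope_vector` (2k
#'   coefficients), `intercepts`, `r_squared`, `permutation_p` (`NA` if
#'   `n_perm = 0`), `residuals` (n x 2k, centered), `fitted`, `cs`,
#'   `consensus` (when available), `n`.
#' @export
allometric_regression <- function(aligned, cs = NULL, n_perm = 0L,
                                  seed = NULL, log_cs = FALSE) {
  if (inherits(aligned, "aligned_shapes")) {
    Y <- shape_matrix(aligned)
    if (is.null(cs)) cs <- unname(aligned$centroid_sizes)
    consensus <- aligned$consensus
  } else {
    Y <- as.matrix(aligned)
    consensus <- NULL
    if (is.null(cs)) stop("cs must be supplied when aligned is a matrix")
  }
  n <- nrow(Y)
  if (n < 3L) stop("allometric regression needs n >= 3")
  x <- if (log_cs) log(cs) else as.numeric(cs)
  if (sd(x) < .Machine$double.eps) stop("degenerate predictor: constant CS")
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  Yc <- sweep(Y, 2L, colMeans(Y))
  sxy <- drop(crossprod(Yc, xc))             # per-coordinate covariances * (n-1)
  slope <- sxy / sxx
  pred_ss <- sum(sxy^2) / sxx
  tot_ss <- sum(Yc^2)
  r2 <- pred_ss / tot_ss
  fitted <- outer(xc, slope)
  residuals <- Yc - fitted
  p <- NA_real_
  if (n_perm >= 1L) {
    if (!is.null(seed)) set.seed(seed)
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      xp <- xc[sample.int(n)]
      ss <- sum(drop(crossprod(Yc, xp))^2) / sum(xp^2)
      if (ss >= pred_ss) exceed <- exceed + 1L
    }
    p <- (1 + exceed) / (n_perm + 1)
  }
  structure(
    list(slope_vector = slope, intercepts = colMeans(Y) - slope * mean(x),
         r_squared = r2, permutation_p = p, residuals = residuals,
         fitted = fitted, cs = cs, log_cs = log_cs, consensus = consensus,
         n = n),
    class = "allometry_fit")
}

#' @export
print.allometry_fit <- function(x, ...) {
  cat(sprintf("<allometry_fit> n = %d, pooled R2 = %.4f, permutation p = %s\n",
              x$n, x$r_squared,
              if (is.na(x$permutation_p)) "not computed"
              else format.pval(x$permutation_p)))
  invisible(x)
}

# sign convention shared by PCA/CVA axes: largest-|loading| entry positive
fix_axis_signs <- function(loadings, scores) {
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(loadings = loadings, scores = scores)
}

#' Principal component analysis of shape residuals
#'
#' Eigen-decomposition of the covariance matrix of the (allometry-corrected)
#' Procrustes coordinates. Scores are centered; per-axis variance
#' percentages sum to 100; each loading vector is oriented so that its
#' largest-magnitude entry is positive.
#'
#' @param residuals n x 2k matrix of shape variables (e.g.
#'   `allometric_regression(...)$residuals`).
#' @return Object of class `shape_space`: list with `pc_scores`,
#'   `loadings`, `eigenvalues` (non-increasing), `pct_variance`, `center`.
#' @export
shape_pca <- function(residuals) {
  X <- as.matrix(residuals)
  if (nrow(X) < 2L) stop("PCA needs n >= 2")
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  fixed <- fix_axis_signs(pc$rotation, pc$x)
  structure(
    list(pc_scores = fixed$scores, loadings = fixed$loadings,
         eigenvalues = ev, pct_variance = 100 * ev / sum(ev),
         center = pc$center),
    class = "shape_space")
}

#' @export
print.shape_space <- function(x, ...) {
  ax <- if (!is.null(x$cv_scores)) "CV" else "PC"
  pct <- if (ax == "CV") x$cv_pct_variance else x$pct_variance
  m <- min(3L, length(pct))
  cat(sprintf("<shape_space> %s axes: %s ... (%d axes)\n", ax,
              paste(sprintf("%s%d %.2f%%", ax, seq_len(m), pct[seq_len(m)]),
                    collapse = ", "), length(pct)))
  invisible(x)
}

#' Canonical variate analysis of shape residuals
#'
#' Solves the generalized eigenproblem of the between-group against the
#' pooled within-group covariance, computed in the subspace spanned by the
#' non-null eigenvectors of the within-group covariance (rank truncation at
#' relative eigenvalue `rank_tol`): Procrustes coordinate matrices are rank
#' deficient, so plain inversion is not available. At most
#' `min(g - 1, within-rank)` axes are returned; axis variance percentages
#' are shares among the retained axes.
#'
#' @param residuals n x 2k shape matrix.
#' @param groups factor (or coercible) of group labels, one per row.
#' @param rank_tol relative eigenvalue cut-off for the within-covariance
#'   rank truncation (default 1e-10).
#' @return Object of class `shape_space` with `cv_scores`, `cv_loadings`,
#'   `cv_eigenvalues`, `cv_pct_variance`, `groups`.
#' @export
shape_cva <- function(residuals, groups, rank_tol = 1e-10) {
  X <- as.matrix(residuals)
  g <- droplevels(as.factor(groups))
  if (nlevels(g) < 2L) stop("CVA needs at least 2 groups")
  if (any(table(g) < 2L)) stop("every group needs at least 2 members")
  n <- nrow(X); ng <- nlevels(g)
  Xc <- sweep(X, 2L, colMeans(X))
  means <- rowsum(Xc, g) / as.vector(table(g))
  W <- crossprod(Xc - means[g, , drop = FALSE]) / (n - ng)
  cnt <- as.vector(table(g))
  B <- crossprod(means * sqrt(cnt)) / (ng - 1)
  ew <- eigen(W, symmetric = TRUE)
  keep <- ew$values > rank_tol * max(ew$values)
  U <- ew$vectors[, keep, drop = FALSE]
  whiten <- U %*% diag(1 / sqrt(ew$values[keep]), sum(keep))
  Bw <- crossprod(whiten, B %*% whiten)
  eb <- eigen((Bw + t(Bw)) / 2, symmetric = TRUE)
  n_axes <- min(ng - 1L, sum(keep))
  vals <- pmax(eb$values[seq_len(n_axes)], 0)
  axes <- whiten %*% eb$vectors[, seq_len(n_axes), drop = FALSE]
  scores <- Xc %*% axes
  fixed <- fix_axis_signs(axes, scores)
  colnames(fixed$scores) <- paste0("CV", seq_len(n_axes))
  structure(
    list(cv_scores = fixed$scores, cv_loadings = fixed$loadings,
         cv_eigenvalues = vals,
         cv_pct_variance = 100 * vals / sum(vals),
         groups = g, within_rank = sum(keep)),
    class = "shape_space")
}

#' Pairwise group mean-shape distances with permutation tests
#'
#' For every pair of groups, the Procrustes distance between the two group
#' mean shapes, tested by reshuffling the pair's specimens between the two
#' groups (group sizes preserved) and recomputing the distance;
#' `p = (1 + #(null >= obs)) / (n_perm + 1)`. A Bonferroni-adjusted
#' significance threshold (`alpha / n_pairs`) is reported alongside, the
#' p-values themselves are not modified.
#'
#' @param shapes an `aligned_shapes` object, or an n x 2k matrix of shape
#'   variables (e.g. allometry residuals).
#' @param groups group labels, one per specimen.
#' @param n_perm permutation rounds per pair (default 10000).
#' @param seed RNG seed (`NULL`: use the ambient RNG state).
#' @param alpha nominal table-wide significance level (default 0.05).
#' @param consensus reference shape (k x 2 matrix or 2k vector) added to
#'   group mean deviations before superimposition when `shapes` is a
#'   residual matrix; an `allometry_fit` carries it as `$consensus`. When
#'   `NULL` and `shapes` is a matrix, the Euclidean distance between mean
#'   vectors is used instead (appropriate for tangent-space residuals,
#'   where the two coincide to first order).
#' @return Object of class `group_distances`: list with `distance` and `p`
#'   matrices (p diagonal `NA`), long-format `table` (`group_a, group_b,
#'   distance, p, significant_bonferroni`), `n_permutations`,
#'   `alpha_bonferroni`.
#' @export
pairwise_group_distances <- function(shapes, groups, n_perm = 10000L,
                                     seed = NULL, alpha = 0.05,
                                     consensus = NULL) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (inherits(shapes, "aligned_shapes")) {
    X <- shape_matrix(shapes)
    cvec <- numeric(ncol(X))      # rows are already full shapes
    superimpose <- TRUE
  } else {
    X <- as.matrix(shapes)
    superimpose <- !is.null(consensus)
    cvec <- if (superimpose) as.vector(t(as.matrix(consensus)))[seq_len(ncol(X))]
            else numeric(ncol(X))
  }
  g <- droplevels(as.factor(groups))
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  if (!is.null(seed)) set.seed(seed)
  lev <- levels(g)
  npair <- choose(length(lev), 2L)
  D <- P <- matrix(0, length(lev), length(lev), dimnames = list(lev, lev))
  dist_fun <- function(ma, mb) {
    if (superimpose)
      procrustes_distance_num(matrix(ma + cvec, ncol = 2L, byrow = TRUE),
                              matrix(mb + cvec, ncol = 2L, byrow = TRUE))
    else sqrt(sum((ma - mb)^2))
  }
  rows <- list()
  for (i in seq_along(lev)[-length(lev)]) for (j in seq((i + 1L), length(lev))) {
    ia <- which(g == lev[i]); ib <- which(g == lev[j])
    na <- length(ia)
    pool <- X[c(ia, ib), , drop = FALSE]
    obs <- dist_fun(colMeans(pool[seq_len(na), , drop = FALSE]),
                    colMeans(pool[-seq_len(na), , drop = FALSE]))
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      idx <- sample.int(nrow(pool), na)
      d <- dist_fun(colMeans(pool[idx, , drop = FALSE]),
                    colMeans(pool[-idx, , drop = FALSE]))
      if (d >= obs) exceed <- exceed + 1L
    }
    p <- (1 + exceed) / (n_perm + 1)
    D[i, j] <- D[j, i] <- obs
    P[i, j] <- P[j, i] <- p
    rows[[length(rows) + 1L]] <-
      data.frame(group_a = lev[i], group_b = lev[j], distance = obs, p = p,
                 significant_bonferroni = p < alpha / npair)
  }
  diag(P) <- NA_real_
  structure(
    list(distance = D, p = P, table = do.call(rbind, rows),
         n_permutations = n_perm, alpha = alpha,
         alpha_bonferroni = alpha / npair),
    class = "group_distances")
}

#' @export
print.group_distances <- function(x, ...) {
  cat(sprintf("<group_distances> %d groups, %d permutations, Bonferroni alpha = %.4g\n",
              nrow(x$distance), x$n_permutations, x$alpha_bonferroni))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Goodall's F test for two groups of shapes
#'
#' Compares two groups' mean shapes against the pooled within-group
#' Procrustes variation, assuming isotropic landmark variation:
#' `F = [d^2 / (1/n1 + 1/n2)] / [SS_within / (n1 + n2 - 2)]` with `d` the
#' Procrustes distance between the group mean shapes, on
#' `q = 2k - 4` and `q (n1 + n2 - 2)` degrees of freedom. Used in this
#' workflow as a digitization repeatability test (photograph the same snails
#' twice; a large p indicates negligible measurement error).
#'
#' @param group_a,group_b lists of [landmark_config()] objects or
#'   k x 2 x n arrays.
#' @param allow_reflection passed to [gpa()].
#' @return Object of class `goodall_f`: list with `f_value`, `df_num`,
#'   `df_den`, `p_value`, `procrustes_d`, `n1`, `n2`, `k`.
#' @export
goodall_f <- function(group_a, group_b, allow_reflection = FALSE) {
  arr_a <- if (is.array(group_a)) group_a else config_array(group_a)
  arr_b <- if (is.array(group_b)) group_b else config_array(group_b)
  n1 <- dim(arr_a)[3L]; n2 <- dim(arr_b)[3L]
  if (n1 < 2L || n2 < 2L)
    stop("insufficient replication: both groups need n >= 2")
  if (dim(arr_a)[1L] != dim(arr_b)[1L])
    stop("shape mismatch: landmark counts differ")
  k <- dim(arr_a)[1L]
  joint <- array(c(arr_a, arr_b), dim = c(k, 2L, n1 + n2))
  dimnames(joint) <- list(NULL, c("x", "y"),
                          c(paste0("a", seq_len(n1)), paste0("b", seq_len(n2))))
  al <- gpa(joint, allow_reflection = allow_reflection)
  M <- shape_matrix(al)
  ma <- colMeans(M[seq_len(n1), , drop = FALSE])
  mb <- colMeans(M[-seq_len(n1), , drop = FALSE])
  d <- procrustes_distance_num(matrix(ma, ncol = 2L, byrow = TRUE),
                               matrix(mb, ncol = 2L, byrow = TRUE),
                               allow_reflection)
  ssw <- sum(sweep(M[seq_len(n1), , drop = FALSE], 2L, ma)^2) +
         sum(sweep(M[-seq_len(n1), , drop = FALSE], 2L, mb)^2)
  q <- 2L * k - 4L
  df_den <- q * (n1 + n2 - 2L)
  f <- if (ssw <= 0) 0 else (d^2 / (1 / n1 + 1 / n2)) / (ssw / (n1 + n2 - 2L))
  structure(
    list(f_value = f, df_num = q, df_den = df_den,
         p_value = pf(f, q, df_den, lower.tail = FALSE),
         procrustes_d = d, n1 = n1, n2 = n2, k = k),
    class = "goodall_f")
}

#' @export
print.goodall_f <- function(x, ...) {
  cat(sprintf("<goodall_f> F = %.4f, df = %d, %d; p = %.4g (d = %.5g)\n",
              x$f_value, x$df_num, x$df_den, x$p_value, x$procrustes_d))
  invisible(x)
}
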