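#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances of each landmark from the
#' centroid of the configuration: the only size measure of a landmark set
#' that is uncorrelated with shape under isotropic landmark error. Invariant
#' to translation and rotation; scales linearly under uniform scaling.
#'
#' @param x a [landmark_config()] or a k x 2 coordinate matrix (mm).
#' @return Positive scalar, in mm.
#' @export
centroid_size <- function(x) {
  m <- if (inherits(x, "landmark_config")) x$points else as.matrix(x)
  if (nrow(m) < 2L) stop("centroid size needs at least 2 landmarks")
  cen <- colMeans(m)
  cs <- sqrt(sum((m[, 1L] - cen[1L])^2 + (m[, 2L] - cen[2L])^2))
  if (cs <= .Machine$double.eps * nrow(m))
    stop("degenerate configuration: all landmarks coincide")
  cs
}

# Optimal 2-D rotation matrix R (det +1) minimizing ||A R - B||_F for
# centered row-wise coordinate matrices. Closed form: the optimal angle is
# atan2(sum(a x b), sum(a . b)).
rot2_optimal <- function(A, B) {
  a <- sum(A * B)                               # sum of dot products
  b <- sum(A[, 1L] * B[, 2L] - A[, 2L] * B[, 1L])  # sum of cross products
  r <- sqrt(a * a + b * b)
  if (r < .Machine$double.eps) return(diag(2))
  c0 <- a / r; s0 <- b / r
  matrix(c(c0, -s0, s0, c0), 2L, 2L)            # row-vector convention: p %*% R
}

center_scale <- function(m) {
  m <- sweep(m, 2L, colMeans(m))
  m / sqrt(sum(m * m))
}

# Deterministic canonical orientation for a GPA solution: rotate so that the
# consensus' principal axes align with the coordinate axes (major axis on y,
# i.e. shell height vertical), with sign fixed by the largest-|y| landmark.
# Keeps GPA output invariant to specimen input order.
canonical_rotation <- function(consensus) {
  sv <- svd(consensus)                          # 20 x 2, centered
  V <- sv$v
  if (det(V) < 0) V[, 2L] <- -V[, 2L]
  # put major axis (first singular vector) on y
  V <- V[, c(2L, 1L)]
  if (det(V) < 0) V[, 1L] <- -V[, 1L]
  rot <- consensus %*% V
  iy <- which.max(abs(rot[, 2L]))
  if (rot[iy, 2L] < 0) V <- -V                  # 180 degree flip, det kept
  V
}

#' Generalized Procrustes superimposition
#'
#' Partial Procrustes superimposition of a set of landmark configurations:
#' each configuration is centered at the origin, scaled to unit centroid
#' size, and iteratively rotated to the evolving consensus using the optimal
#' orthogonal rotation restricted to determinant +1 (no reflection, because
#' shells are chiral; set `allow_reflection = TRUE` to lift the restriction).
#' Iteration stops when the root-mean-square change of the consensus falls
#' below `tol`. The final solution is rotated into a deterministic canonical
#' orientation so that the result does not depend on input order.
#'
#' @param configs list of [landmark_config()] objects, or a k x 2 x n array.
#' @param tol convergence tolerance on consensus RMS change (default 1e-10).
#' @param max_iter maximum number of iterations (default 100).
#' @param allow_reflection permit improper rotations (default `FALSE`).
#' @return Object of class `aligned_shapes`: list with `coords`
#'   (k x 2 x n array of unit-centroid-size Procrustes coordinates),
#'   `consensus` (k x 2 mean shape), `centroid_sizes` (mm), `specimen_ids`,
#'   `tangent_projected` (`FALSE`), `iterations`, `convergence_delta`,
#'   `converged` (a warning is issued, not an error, on non-convergence).
#' @export
gpa <- function(configs, tol = 1e-10, max_iter = 100L,
                allow_reflection = FALSE) {
  arr <- if (is.array(configs) && length(dim(configs)) == 3L) configs
         else config_array(configs)
  n <- dim(arr)[3L]
  if (n < 2L) stop("GPA needs at least 2 configurations")
  ids <- dimnames(arr)[[3L]]
  if (is.null(ids)) ids <- sprintf("specimen_%d", seq_len(n))
  cs <- apply(arr, 3L, centroid_size)
  X <- array(NA_real_, dim = dim(arr))
  for (i in seq_len(n)) X[, , i] <- center_scale(arr[, , i])

  rotate_onto <- function(A, ref) {
    R <- rot2_optimal(A, ref)
    if (allow_reflection) {
      Ar <- A; Ar[, 2L] <- -Ar[, 2L]            # reflected candidate
      Rr <- rot2_optimal(Ar, ref)
      if (sum((Ar %*% Rr - ref)^2) < sum((A %*% R - ref)^2)) return(Ar %*% Rr)
    }
    A %*% R
  }

  consensus <- X[, , 1L]
  delta <- Inf; it <- 0L
  while (it < max_iter && delta >= tol) {
    it <- it + 1L
    for (i in seq_len(n)) X[, , i] <- rotate_onto(X[, , i], consensus)
    new_cons <- apply(X, c(1L, 2L), mean)   # the consensus IS the mean shape
    delta <- sqrt(mean((new_cons - consensus)^2))
    consensus <- new_cons
  }
  converged <- delta < tol
  if (!converged)
    warning(sprintf("GPA did not converge in %d iterations (delta = %.3g)",
                    max_iter, delta))
  V <- canonical_rotation(consensus)
  consensus <- consensus %*% V
  for (i in seq_len(n)) X[, , i] <- X[, , i] %*% V
  dimnames(X) <- list(NULL, c("x", "y"), ids)
  structure(
    list(coords = X, consensus = consensus, centroid_sizes = setNames(cs, ids),
         specimen_ids = ids, tangent_projected = FALSE, iterations = it,
         convergence_delta = delta, converged = converged),
    class = "aligned_shapes")
}

#' @export
print.aligned_shapes <- function(x, ...) {
  cat(sprintf(paste0("<aligned_shapes> %d specimens, %d landmarks;",
                     " %d iterations (delta %.2g)%s%s\n"),
              dim(x$coords)[3L], dim(x$coords)[1L], x$iterations,
              x$convergence_delta,
              if (x$tangent_projected) ", tangent-projected" else "",
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Orthogonal projection onto the tangent space at the consensus
#'
#' Projects each aligned configuration onto the linear space tangent to the
#' unit shape sphere at the consensus: `x -> c + (I - cc')(x - c)` with `c`
#' the flattened unit-size consensus. Idempotent; the consensus maps to
#' itself; for small deviations projected and unprojected coordinates agree
#' to second order in the deviation.
#'
#' @param aligned an `aligned_shapes` object from [gpa()].
#' @return The `aligned_shapes` object with projected coordinates and
#'   `tangent_projected = TRUE`.
#' @export
tangent_project <- function(aligned) {
  stopifnot(inherits(aligned, "aligned_shapes"))
  cvec <- as.vector(aligned$consensus)
  cvec <- cvec / sqrt(sum(cvec^2))
  k2 <- length(cvec)
  n <- dim(aligned$coords)[3L]
  for (i in seq_len(n)) {
    x <- as.vector(aligned$coords[, , i])
    x <- x - cvec * (sum(cvec * x) - sum(cvec * as.vector(aligned$consensus)))
    aligned$coords[, , i] <- matrix(x, ncol = 2L)
  }
  aligned$tangent_projected <- TRUE
  aligned
}

#' Procrustes distance between two shapes
#'
#' Square root of the summed squared coordinate differences after optimal
#' (partial Procrustes) superimposition of `b` onto `a`: both shapes are
#' centered, scaled to unit centroid size, and `b` is rotated onto `a` with
#' the determinant +1 rotation. Symmetric; zero iff the shapes are identical
#' up to a similarity transform.
#'
#' @param a,b [landmark_config()] objects or k x 2 coordinate matrices with
#'   equal landmark counts.
#' @param allow_reflection permit improper rotations (default `FALSE`).
#' @return Object of class `shape_distance`: list with `value` and `pair`.
#' @export
procrustes_distance <- function(a, b, allow_reflection = FALSE) {
  ma <- if (inherits(a, "landmark_config")) a$points else as.matrix(a)
  mb <- if (inherits(b, "landmark_config")) b$points else as.matrix(b)
  if (nrow(ma) != nrow(mb))
    stop("shape mismatch: configurations have different landmark counts")
  value <- procrustes_distance_num(ma, mb, allow_reflection)
  structure(list(value = value,
                 pair = c(if (inherits(a, "landmark_config")) a$specimen_id else NA,
                          if (inherits(b, "landmark_config")) b$specimen_id else NA)),
            class = "shape_distance")
}

# bare numeric fast path used in permutation loops
procrustes_distance_num <- function(ma, mb, allow_reflection = FALSE) {
  A <- center_scale(ma); B <- center_scale(mb)
  d2 <- sum((B %*% rot2_optimal(B, A) - A)^2)
  if (allow_reflection) {
    Br <- B; Br[, 2L] <- -Br[, 2L]
    d2 <- min(d2, sum((Br %*% rot2_optimal(Br, A) - A)^2))
  }
  sqrt(max(d2, 0))
}

#' @export
print.shape_distance <- function(x, ...) {
  cat(sprintf("<shape_distance> %.6g (%s vs %s)\n", x$value,
              x$pair[1L], x$pair[2L]))
  invisible(x)
}

#' Flatten aligned shapes to an n x 2k matrix
#'
#' Rows are specimens; columns are interleaved coordinates
#' `lm1_x, lm1_y, ..., lmk_y`.
#'
#' @param aligned an `aligned_shapes` object.
#' @return Numeric matrix with specimen ids as row names.
#' @export
shape_matrix <- function(aligned) {
  stopifnot(inherits(aligned, "aligned_shapes"))
  k <- dim(aligned$coords)[1L]; n <- dim(aligned$coords)[3L]
  M <- t(apply(aligned$coords, 3L, function(m) as.vector(t(m))))
  dimnames(M) <- list(aligned$specimen_ids,
                      paste0(rep(paste0("lm", seq_len(k)), each = 2L),
                             c("_x", "_y")))
  M
}

#' Export aligned coordinates as CSV
#'
#' Writes one row per specimen: `specimen_id`, `lm1_x` ... `lm<k>_y`, `cs`.
#'
#' @param aligned an `aligned_shapes` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_aligned <- function(aligned, path) {
  M <- shape_matrix(aligned)
  df <- data.frame(specimen_id = aligned$specimen_ids, M,
                   cs = unname(aligned$centroid_sizes),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
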