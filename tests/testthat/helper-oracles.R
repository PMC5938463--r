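# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own linear-algebra shortcuts: rotations are searched
# on explicit angle grids, rank statistics are computed by pair counting,
# and spanning trees come from a plain Prim's algorithm.

rot_mat <- function(theta) {
  matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2L, 2L)
}

center_unit <- function(m) {
  m <- sweep(m, 2L, colMeans(m))
  m / sqrt(sum(m^2))
}

# minimum of ||A %*% R(theta) - B||^2 over a theta grid (explicit matmuls)
grid_min_ss <- function(A, B, resolution = 1e-4) {
  thetas <- seq(0, 2 * pi, by = resolution)
  best <- Inf
  for (th in thetas) {
    ss <- sum((A %*% rot_mat(th) - B)^2)
    if (ss < best) best <- ss
  }
  best
}

grid_procrustes_distance <- function(a, b, resolution = 1e-4) {
  sqrt(grid_min_ss(center_unit(b), center_unit(a), resolution))
}

# coarse-to-fine grid search for the 3-configuration GPA objective:
# configs are centered/unit-scaled; rotate configs 2 and 3, consensus is the
# mean, objective is the summed squared deviation from the consensus.
grid_gpa_ss <- function(X1, X2, X3, final_resolution = 1e-3) {
  obj <- function(t2, t3) {
    R2 <- X2 %*% rot_mat(t2); R3 <- X3 %*% rot_mat(t3)
    cons <- (X1 + R2 + R3) / 3
    sum((X1 - cons)^2) + sum((R2 - cons)^2) + sum((R3 - cons)^2)
  }
  coarse <- seq(0, 2 * pi, by = 0.05)
  best <- c(Inf, 0, 0)
  for (t2 in coarse) for (t3 in coarse) {
    v <- obj(t2, t3)
    if (v < best[1L]) best <- c(v, t2, t3)
  }
  fine2 <- seq(best[2L] - 0.06, best[2L] + 0.06, by = final_resolution)
  fine3 <- seq(best[3L] - 0.06, best[3L] + 0.06, by = final_resolution)
  for (t2 in fine2) for (t3 in fine3) {
    v <- obj(t2, t3)
    if (v < best[1L]) best <- c(v, t2, t3)
  }
  best[1L]
}

# Kendall tau-b by exhaustive pair counting
brute_tau <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
    if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
    else if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (dx == dy) conc <- conc + 1
    else disc <- disc + 1
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

# Mann-Whitney U by exhaustive pair counting (smaller-U convention)
brute_U <- function(a, b) {
  u1 <- 0
  for (x in a) for (y in b) u1 <- u1 + (x > y) + 0.5 * (x == y)
  min(u1, length(a) * length(b) - u1)
}

# Welch's F from the textbook formula
brute_welch_F <- function(values, groups) {
  g <- split(values, groups)
  ni <- vapply(g, length, 0); mi <- vapply(g, mean, 0)
  vi <- vapply(g, var, 0)
  wi <- ni / vi
  mw <- sum(wi * mi) / sum(wi)
  k <- length(g)
  A <- sum(wi * (mi - mw)^2) / (k - 1)
  B <- 1 + 2 * (k - 2) / (k^2 - 1) * sum((1 - wi / sum(wi))^2 / (ni - 1))
  list(F = A / B,
       df2 = (k^2 - 1) / (3 * sum((1 - wi / sum(wi))^2 / (ni - 1))))
}

# balanced one-way method-of-moments variance components
mom_oneway <- function(y, g) {
  g <- as.factor(g)
  m <- length(y) / nlevels(g)
  means <- tapply(y, g, mean)
  msb <- m * sum((means - mean(y))^2) / (nlevels(g) - 1)
  msw <- sum((y - means[g])^2) / (length(y) - nlevels(g))
  list(sigma2_between = (msb - msw) / m, sigma2_within = msw)
}

# Prim's minimum spanning tree: returns total weight
prim_mst_weight <- function(D) {
  n <- nrow(D)
  in_tree <- c(TRUE, rep(FALSE, n - 1L))
  total <- 0
  while (any(!in_tree)) {
    best <- Inf; bj <- NA
    for (i in which(in_tree)) for (j in which(!in_tree)) {
      if (D[i, j] < best) { best <- D[i, j]; bj <- j }
    }
    in_tree[bj] <- TRUE
    total <- total + best
  }
  total
}

random_config <- function(k = 20L, sd = 1) {
  matrix(rnorm(2L * k, sd = sd), k, 2L)
}

# small noisy shell set around a template, as a k x 2 x n array
noisy_shell_array <- function(n, sd = 0.01, k = 20L, template = NULL) {
  if (is.null(template)) template <- shell_template()
  template <- template[seq_len(k), , drop = FALSE]
  arr <- array(NA_real_, c(k, 2L, n))
  for (i in seq_len(n)) arr[, , i] <- template + matrix(rnorm(2L * k, sd = sd), k, 2L)
  arr
}
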