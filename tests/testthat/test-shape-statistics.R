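make_allometric_set <- function(n, beta_scale = 0.02, noise = 0.002,
                                seed = 1) {
  set.seed(seed)
  template <- shell_template()
  beta <- rnorm(40); beta <- beta / sqrt(sum(beta^2)) * beta_scale
  cs <- rnorm(n, 6, 0.5)
  cs_std <- (cs - mean(cs)) / sd(cs)
  Y <- matrix(rep(as.vector(t(template)), n), n, 40, byrow = TRUE) +
    outer(cs_std, beta) + matrix(rnorm(n * 40, sd = noise), n, 40)
  list(Y = Y, cs = cs, beta = beta)
}

test_that("allometric regression recovers an injected allometric field", {
  sim <- make_allometric_set(500, beta_scale = 0.02, noise = 0.002)
  fit <- allometric_regression(sim$Y, cs = sim$cs, n_perm = 99, seed = 7)
  # slope per unit CS; direction must match the injected field
  expect_gt(abs(cor(fit$slope_vector, sim$beta)), 0.99)
  expect_lt(fit$permutation_p, 0.05)
  expect_gt(fit$r_squared, 0.5)
  # residuals are exactly orthogonal to CS
  refit <- allometric_regression(fit$residuals, cs = sim$cs)
  expect_lt(refit$r_squared, 1e-20)
})

test_that("allometric regression is null-calibrated on size-free shapes", {
  set.seed(23)
  n <- 200
  Y <- matrix(rnorm(n * 40, sd = 0.01), n, 40)
  cs <- rnorm(n, 6, 0.5)
  fit <- allometric_regression(Y, cs = cs, n_perm = 199, seed = 3)
  expect_lt(fit$r_squared, 0.02)
  expect_gt(fit$permutation_p, 0.01)
  expect_error(allometric_regression(Y, cs = rep(5, n)), "constant CS")
})

test_that("PCA variance percentages are normalized and axes reconstruct data", {
  set.seed(24)
  # rank-one variation
  direction <- rnorm(10)
  X1 <- outer(rnorm(50), direction)
  p1 <- shape_pca(X1)
  expect_equal(p1$pct_variance[1], 100, tolerance = 1e-9)
  # full-rank reconstruction
  X <- matrix(rnorm(30 * 6), 30, 6)
  p <- shape_pca(X)
  expect_equal(sum(p$pct_variance), 100, tolerance = 1e-6)
  expect_true(all(diff(p$eigenvalues) <= 1e-12))
  back <- p$pc_scores %*% t(p$loadings)
  expect_equal(sweep(back, 2, -p$center), X, tolerance = 1e-9,
               ignore_attr = TRUE)
  # orthonormal axes, sign convention
  expect_equal(crossprod(p$loadings), diag(6), tolerance = 1e-9,
               ignore_attr = TRUE)
  for (j in 1:6) expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
})

test_that("CVA separates distinct groups and collapses under label permutation", {
  set.seed(25)
  n <- 60
  g <- rep(c("a", "b"), each = n / 2)
  offset <- c(rep(0, n / 2), rep(1, n / 2))
  X <- matrix(rnorm(n * 8, sd = 0.1), n, 8)
  X[, 1] <- X[, 1] + offset * 5 * 0.1
  cv <- shape_cva(X, g)
  expect_equal(cv$cv_pct_variance[1], 100)   # two groups: one axis
  expect_gt(abs(diff(tapply(cv$cv_scores[, 1], g, mean))), 3)
  ev_true <- cv$cv_eigenvalues[1]
  ev_perm <- replicate(20, {
    shape_cva(X, sample(g))$cv_eigenvalues[1]
  })
  expect_gt(ev_true, 10 * median(ev_perm))
  expect_error(shape_cva(X, c("a", rep("b", n - 1))), "at least 2 members")
})

test_that("CVA scores are invariant to invertible linear transforms", {
  set.seed(26)
  n <- 80
  g <- rep(c("a", "b", "c"), length.out = n)
  X <- matrix(rnorm(n * 5), n, 5)
  X[g == "b", 1] <- X[g == "b", 1] + 2
  X[g == "c", 2] <- X[g == "c", 2] + 2
  cv1 <- shape_cva(X, g)
  T <- matrix(rnorm(25), 5, 5) + diag(5)
  cv2 <- shape_cva(X %*% T, g)
  for (j in seq_len(ncol(cv1$cv_scores))) {
    agree <- max(abs(cv1$cv_scores[, j] - cv2$cv_scores[, j]),
                 abs(cv1$cv_scores[, j] + cv2$cv_scores[, j]))
    expect_equal(min(max(abs(cv1$cv_scores[, j] - cv2$cv_scores[, j])),
                     max(abs(cv1$cv_scores[, j] + cv2$cv_scores[, j]))),
                 0, tolerance = 1e-6)
    expect_true(is.finite(agree))
  }
  expect_lte(ncol(cv1$cv_scores), 2L)   # min(g - 1, rank)
})

test_that("CVA rank truncation respects the shape-space dimension bound", {
  set.seed(27)
  al <- gpa(noisy_shell_array(30, sd = 0.02))
  res <- allometric_regression(al)$residuals
  g <- rep(c("a", "b", "c"), each = 10)
  cv <- shape_cva(res, g)
  expect_lte(cv$within_rank, 2 * 20 - 4)
  expect_lte(ncol(cv$cv_scores), min(2, cv$within_rank))
})

test_that("pairwise group distances are symmetric with attainable minimum p", {
  set.seed(28)
  n <- 40
  X <- matrix(rnorm(n * 10, sd = 0.1), n, 10)
  g <- rep(c("a", "b", "c", "d"), each = 10)
  X[g == "b", 3] <- X[g == "b", 3] + 0.5   # 5x noise sd offset
  gd <- pairwise_group_distances(X, g, n_perm = 199, seed = 5)
  expect_equal(gd$distance, t(gd$distance))
  expect_true(all(diag(gd$distance) == 0))
  off <- gd$p[upper.tri(gd$p)]
  expect_true(all(off > 0 & off <= 1))
  # clearly separated pair attains the permutation minimum
  expect_equal(gd$p["a", "b"], 1 / 200)
  expect_equal(gd$alpha_bonferroni, 0.05 / 6)
  expect_error(pairwise_group_distances(X, g, n_perm = 0), "n_perm")
})

test_that("mean-shape distances via the consensus match residual distances to first order", {
  set.seed(45)
  al <- gpa(noisy_shell_array(30, sd = 0.01))
  af <- allometric_regression(al)
  g <- rep(c("a", "b"), each = 15)
  gd_res <- pairwise_group_distances(af$residuals, g, n_perm = 99, seed = 1)
  gd_shape <- pairwise_group_distances(af$residuals, g, n_perm = 99, seed = 1,
                                       consensus = af$consensus)
  expect_equal(gd_res$distance["a", "b"], gd_shape$distance["a", "b"],
               tolerance = 0.05)
  # the aligned_shapes interface agrees with the consensus route
  gd_al <- pairwise_group_distances(al, g, n_perm = 99, seed = 1)
  expect_equal(gd_al$distance["a", "b"], gd_shape$distance["a", "b"],
               tolerance = 0.05)
})

test_that("Goodall's F has the published df structure and null behaviour", {
  # k = 20 landmarks, n1 = n2 = 19 gives df (36, 1296)
  set.seed(29)
  A <- noisy_shell_array(19, sd = 0.01)
  B <- noisy_shell_array(19, sd = 0.01)
  gf <- goodall_f(A, B)
  expect_equal(gf$df_num, 36L)
  expect_equal(gf$df_den, 1296L)
  # an exact copy of the group gives F = 0, p = 1
  gf0 <- goodall_f(A, A)
  expect_equal(gf0$f_value, 0)
  expect_equal(gf0$p_value, 1)
  expect_error(goodall_f(A[, , 1, drop = FALSE], B), "insufficient")
})

test_that("Goodall's F is F-distributed under equal means", {
  set.seed(30)
  k <- 8L
  reps <- 600
  fs <- vapply(seq_len(reps), function(r) {
    A <- noisy_shell_array(5, sd = 0.004, k = k)
    B <- noisy_shell_array(5, sd = 0.004, k = k)
    goodall_f(A, B)$f_value
  }, numeric(1))
  q <- 2 * k - 4
  ks <- suppressWarnings(ks.test(fs, "pf", q, q * 8))
  expect_gt(ks$p.value, 0.01)
})
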