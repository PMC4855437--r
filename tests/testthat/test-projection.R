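# PCA contract and the two diagnostics.

test_that("fit_pca satisfies the model invariants", {
  withr::local_seed(3)
  X <- matrix(rnorm(40 * 6), 40, 6)
  m <- fit_pca(X)
  expect_equal(crossprod(m$loadings), diag(6), tolerance = 1e-8)
  expect_false(is.unsorted(rev(m$eigenvalues)))
  expect_equal(sum(m$eigenvalues), sum(apply(X, 2, var)), tolerance = 1e-6)
  # sign convention: largest-magnitude entry of each column positive
  for (j in 1:6) expect_gt(m$loadings[which.max(abs(m$loadings[, j])), j], 0)
})

test_that("degenerate and low-rank data are handled", {
  # points on a line in 3D: eigenvalue 1 carries all variance
  t_ <- seq(0, 1, length.out = 10)
  X <- cbind(2 * t_, -t_, 3 * t_)
  m <- fit_pca(X)
  expect_equal(m$eigenvalues[1], sum(apply(X, 2, var)), tolerance = 1e-9)
  expect_equal(m$eigenvalues[2:3], c(0, 0), tolerance = 1e-9)
  expect_equal(variance_coverage(m, 1), 1, tolerance = 1e-12)

  # unit square corners: two equal nonzero eigenvalues
  sq <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  m2 <- fit_pca(sq)
  expect_equal(m2$eigenvalues[1], m2$eigenvalues[2], tolerance = 1e-12)
  expect_equal(variance_coverage(m2, 1), 0.5, tolerance = 1e-12)

  # all-identical rows: zero eigenvalues, no failure
  m3 <- fit_pca(matrix(1, 5, 3))
  expect_equal(m3$eigenvalues, rep(0, 3))
  expect_equal(variance_coverage(m3, 1), 1)  # zero total variance convention
})

test_that("projection centers, reconstructs and extends to new data", {
  withr::local_seed(4)
  X <- matrix(rnorm(30 * 5), 30, 5)
  m <- fit_pca(X)
  sc <- pca_project(m, X, k = 5)
  # full-rank projection inverts
  expect_equal(sc %*% t(m$loadings) + rep(1, 30) %o% m$means, X,
               tolerance = 1e-8)
  # score columns have eigenvalue variances
  expect_equal(apply(sc, 2, var), m$eigenvalues, tolerance = 1e-8)
  # the mean row projects to zero
  expect_equal(as.numeric(pca_project(m, matrix(m$means, 1), k = 5)),
               rep(0, 5), tolerance = 1e-12)
  # rank-2 data: third column of scores ~ 0
  Y <- cbind(X[, 1], X[, 2], X[, 1] + X[, 2])
  m2 <- fit_pca(Y)
  expect_equal(max(abs(pca_project(m2, Y, k = 3)[, 3])), 0, tolerance = 1e-8)
  expect_error(pca_project(m, X[, 1:3]), "dimension mismatch")
  expect_error(variance_coverage(m, 0), "out of range")
  expect_error(variance_coverage(m, 6), "out of range")
})

test_that("variance coverage is monotone and complete", {
  withr::local_seed(5)
  X <- matrix(rnorm(25 * 7), 25, 7)
  m <- fit_pca(X)
  cov_k <- vapply(1:7, function(k) variance_coverage(m, k), numeric(1))
  expect_false(is.unsorted(cov_k))
  expect_equal(cov_k[7], 1, tolerance = 1e-12)
})

test_that("distance correlation is 1 at k = D and matches the oracle", {
  withr::local_seed(6)
  X <- matrix(rnorm(20 * 4), 20, 4)
  m <- fit_pca(X)
  expect_equal(distance_correlation(pca_project(m, X, 4), X), 1,
               tolerance = 1e-9)
  # data in a 3-dim subspace, k = 3
  B <- matrix(rnorm(15 * 3), 15, 3)
  Y <- B %*% matrix(rnorm(3 * 6), 3, 6)
  m2 <- fit_pca(Y)
  expect_equal(distance_correlation(pca_project(m2, Y, 3), Y), 1,
               tolerance = 1e-9)

  # exhaustive all-pairs oracle on 10 random 5D points, k = 1
  Z <- matrix(rnorm(10 * 5), 10, 5)
  mz <- fit_pca(Z)
  cz <- pca_project(mz, Z, 1)
  d1 <- d2 <- numeric(0)
  for (i in 1:9) for (j in (i + 1):10) {
    d1 <- c(d1, abs(cz[i, 1] - cz[j, 1]))
    d2 <- c(d2, sqrt(sum((Z[i, ] - Z[j, ])^2)))
  }
  expect_equal(distance_correlation(cz, Z), cor(d1, d2), tolerance = 1e-12)

  # zero variance in distances is an error
  same <- matrix(rep(c(0, 1), each = 3), 3, 2)
  expect_error(distance_correlation(matrix(0, 3, 1), same),
               "zero variance")
})

test_that("pair sampling is seeded, capped and decoded correctly", {
  ij <- chemspace3d:::pair_from_index(seq_len(6), 4)
  expect_equal(ij, cbind(i = c(1, 1, 1, 2, 2, 3), j = c(2, 3, 4, 3, 4, 4)))
  n <- 60
  ij2 <- chemspace3d:::pair_from_index(seq_len(n * (n - 1) / 2), n)
  expect_true(all(ij2[, 1] < ij2[, 2]))
  expect_equal(nrow(unique(ij2)), n * (n - 1) / 2)

  withr::local_seed(7)
  X <- matrix(rnorm(80 * 5), 80, 5)
  m <- fit_pca(X)
  co <- pca_project(m, X, 2)
  r1 <- distance_correlation(co, X, n_pairs = 500, seed = 11)
  r2 <- distance_correlation(co, X, n_pairs = 500, seed = 11)
  r3 <- distance_correlation(co, X, n_pairs = 500, seed = 12)
  expect_identical(r1, r2)
  expect_false(identical(r1, r3))
})

test_that("mean distance correlation is non-decreasing in k", {
  withr::local_seed(8)
  X <- matrix(rnorm(60 * 6), 60, 6)   # 1770 pairs, all used
  m <- fit_pca(X)
  r_k <- vapply(1:6, function(k)
    distance_correlation(pca_project(m, X, k), X), numeric(1))
  expect_true(all(diff(r_k) > -1e-6))
  expect_equal(r_k[6], 1, tolerance = 1e-9)
})

test_that("eigenvalues are equivariant under row permutation", {
  withr::local_seed(9)
  X <- matrix(rpois(50 * 8, 4), 50, 8)
  m1 <- fit_pca(X)
  m2 <- fit_pca(X[sample(50), ])
  expect_equal(m1$eigenvalues, m2$eigenvalues, tolerance = 1e-9)
})

test_that("a PCA model survives the JSON round trip", {
  withr::local_seed(10)
  X <- matrix(rnorm(20 * 4), 20, 4)
  m <- fit_pca(X)
  f <- withr::local_tempfile(fileext = ".json")
  write_pca_model(m, f)
  m2 <- read_pca_model(f)
  expect_equal(m2$means, m$means)
  expect_equal(m2$loadings, m$loadings)
  expect_equal(m2$eigenvalues, m$eigenvalues)
  expect_equal(pca_project(m2, X, 3), pca_project(m, X, 3))
})
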