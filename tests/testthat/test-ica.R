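test_that("discarding initial volumes shortens scans as expected", {
  scan <- subject_scan("s1", matrix(rnorm(100 * 20), 100, 20), 0)
  expect_equal(nrow(discard_initial_volumes(scan, 5)$data), 95)
  expect_identical(discard_initial_volumes(scan, 0), scan)
  scan10 <- subject_scan("s2", matrix(rnorm(10 * 4), 10, 4), 1)
  expect_equal(nrow(discard_initial_volumes(scan10, 5)$data), 5)
  expect_error(discard_initial_volumes(scan10, 10), "smaller")
})

test_that("group reduction whitens to identity covariance", {
  set.seed(11)
  scans <- lapply(1:3, function(i)
    subject_scan(sprintf("s%d", i), matrix(rnorm(20 * 50), 20, 50), 0))
  red <- group_reduce(scans, 5)
  Z <- red$whitened
  expect_equal(dim(Z), c(5L, 50L))
  expect_lt(max(abs(tcrossprod(Z) / ncol(Z) - diag(5))), 1e-6)
  # single-subject degenerate case is plain PCA whitening
  red1 <- group_reduce(scans[1], 4)
  expect_lt(max(abs(tcrossprod(red1$whitened) / 50 - diag(4))), 1e-6)
  # full order on noiseless low-rank data retains all variance
  A <- matrix(rnorm(20 * 3), 20, 3); S <- matrix(rnorm(3 * 50), 3, 50)
  lowrank <- list(subject_scan("lr", A %*% S, 0))
  redf <- suppressWarnings(group_reduce(lowrank, 3))
  expect_gt(redf$info$retained_variance, 1 - 1e-8)
  expect_error(group_reduce(list(scans[[1]],
                                 subject_scan("x", matrix(0, 5, 5), 0)), 2),
               "same dimensions")
})

test_that("fixed-point ICA recovers super-Gaussian sources", {
  set.seed(21)
  V <- 3000
  S <- matrix(rexp(3 * V) * sample(c(-1, 1), 3 * V, TRUE), 3, V)  # Laplacian
  A <- matrix(rnorm(12 * 3), 12, 3)
  scans <- list(subject_scan("m", A %*% S, 0))
  red <- suppressWarnings(group_reduce(scans, 3))
  dec <- fastica_decompose(red$whitened, 3, seed = 5)
  expect_true(dec$converged)
  expect_true(all(match_components(dec$sources, S) > 0.95))
  # self-consistency Y = W X
  expect_lt(max(abs(dec$sources - dec$unmixing %*% red$whitened)), 1e-8)
  # decorrelated unit-variance rows
  G <- tcrossprod(dec$sources) / V
  expect_lt(max(abs(G - diag(3))), 1e-2)
})

test_that("ICA on already-independent input is a signed permutation", {
  set.seed(31)
  V <- 4000
  X <- matrix(rexp(3 * V) * sample(c(-1, 1), 3 * V, TRUE), 3, V)
  X <- X - rowMeans(X)
  Z <- solve(t(chol(tcrossprod(X) / V))) %*% X   # exact whitening
  dec <- fastica_decompose(Z, 3, seed = 2)
  P <- dec$unmixing %*% t(dec$unmixing)
  expect_lt(max(abs(P - diag(3))), 1e-6)   # orthonormal rows
  M <- abs(stats::cor(t(dec$sources), t(Z)))
  expect_true(all(apply(M, 1, max) > 0.99))
})

test_that("pure Gaussian input triggers a non-convergence warning", {
  set.seed(41)
  X <- matrix(rnorm(3 * 2000), 3, 2000)
  X <- X - rowMeans(X)
  Z <- solve(t(chol(tcrossprod(X) / ncol(X)))) %*% X
  expect_warning(fastica_decompose(Z, 3, seed = 1, max_iter = 50),
                 "did not converge")
})

test_that("stability selection matches single runs and is deterministic", {
  ch <- tiny_cohort(effect_size = 0, snr = 20)
  red <- group_reduce(ch$scans, 4)
  one <- fastica_decompose(red$whitened, 4, seed = 9)
  sel1 <- stability_select(red$whitened, 4, n_restarts = 1, seed = 9)
  expect_equal(sel1$sources, one$sources)
  sel <- stability_select(red$whitened, 4, n_restarts = 5, seed = 9)
  expect_true(all(sel$stability > 0.9))
  sel_b <- stability_select(red$whitened, 4, n_restarts = 5, seed = 9)
  expect_identical(sel$sources, sel_b$sources)
})

test_that("subject time courses solve the least-squares problem", {
  set.seed(51)
  Y <- matrix(rnorm(4 * 300), 4, 300)
  A <- matrix(rnorm(30 * 4), 30, 4)
  scan <- subject_scan("s", A %*% Y, 1)
  expect_equal(subject_timecourses(scan, Y), A, tolerance = 1e-8)
  zscan <- subject_scan("z", matrix(0, 30, 300), 0)
  expect_equal(subject_timecourses(zscan, Y), matrix(0, 30, 4))
  # noisy case equals the normal-equation oracle
  X <- A %*% Y + matrix(rnorm(30 * 300), 30, 300)
  oracle <- X %*% t(Y) %*% solve(Y %*% t(Y))
  expect_equal(subject_timecourses(subject_scan("n", X, 0), Y), oracle,
               tolerance = 1e-8)
  # rank-deficient sources fall back to the pseudo-inverse with a warning
  Yr <- rbind(Y, Y[1, ])
  expect_warning(subject_timecourses(scan, Yr), "rank deficient")
})

test_that("RSN regression equals closed-form least squares and recovers B", {
  atlas <- tiny_atlas(300, 8, seed = 2)
  set.seed(61)
  # random sources: compare to the normal-equation oracle
  Y <- matrix(rnorm(5 * 300), 5, 300)
  M <- atlas$maps
  oracle <- t(solve(t(M) %*% M) %*% t(M) %*% t(Y))
  sim <- rsn_regression(Y, atlas)
  expect_equal(sim$Q, oracle, tolerance = 1e-10)
  expect_equal(sim$spatial_features, t(sim$Q))
  # zero sources give zero similarity
  expect_equal(rsn_regression(matrix(0, 2, 300), atlas)$Q, matrix(0, 2, 8))
  # exact recovery when Y lies in the atlas span
  B <- matrix(rnorm(5 * 8), 5, 8)
  Yb <- B %*% t(M)
  expect_equal(rsn_regression(Yb, atlas)$Q, B, tolerance = 1e-6)
  expect_error(rsn_regression(matrix(0, 2, 100), atlas), "voxel")
})

test_that("full extraction honours the pipeline shape contract", {
  atlas <- make_rsn_atlas(400, 90, seed = 3)
  ch <- make_cohort(4, 3, 100, 400, 17, 1, atlas, seed = 3)
  fx <- suppressWarnings(
    extract_feature_sets(ch$scans, atlas, n_components = 17, discard = 5,
                         n_restarts = 1, seed = 3, max_iter = 80))
  fs <- fx$feature_sets[[1]]
  expect_equal(dim(fs$timecourses), c(95L, 17L))
  expect_equal(dim(fs$spatial_features), c(90L, 17L))
  expect_length(fx$feature_sets, 7)
  # spatial features differ across subjects (dual regression is per subject)
  expect_false(isTRUE(all.equal(fx$feature_sets[[1]]$spatial_features,
                                fx$feature_sets[[2]]$spatial_features)))
})
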