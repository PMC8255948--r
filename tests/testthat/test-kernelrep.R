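test_that("patch features follow raster order with replicate padding", {
  # constant image: every row repeats the constant
  Fc <- extract_patch_features(matrix(3.5, 6, 6), 3)
  expect_true(all(Fc$features == 3.5))
  expect_equal(ncol(Fc$features), 9)
  # centre channel is the pixel itself
  set.seed(1)
  x <- matrix(runif(48), 6, 8)
  F <- extract_patch_features(x, 3)
  expect_equal(F$features[, 5], as.vector(x))
  # corner of a ramp image: padded entries repeat the edges
  ramp <- matrix(1:16, 4, 4)  # column-major ramp
  Fr <- extract_patch_features(ramp, 3)
  # pixel (1,1): patch rows clamp row 0 -> row 1, col 0 -> col 1
  expect_equal(Fr$features[1, ],
               c(1, 1, 5, 1, 1, 5, 2, 2, 6))
  expect_error(extract_patch_features(x, 4), "odd")
  expect_error(extract_patch_features(matrix(1, 3, 3), 5), "larger")
})

test_that("feature normalization standardizes channels and is idempotent", {
  set.seed(2)
  M <- cbind(rnorm(100, 5, 3), runif(100), rep(2, 100))
  F1 <- normalize_features(M)
  expect_lt(max(abs(colMeans(F1$features))), 1e-12)
  expect_equal(apply(F1$features[, 1:2], 2, sd), c(1, 1))
  expect_true(all(F1$features[, 3] == 0))  # constant channel to zero
  F2 <- normalize_features(F1)
  expect_equal(F2$features, F1$features, tolerance = 1e-12)
})

test_that("kernel matrix is row-stochastic with k-sparse rows", {
  set.seed(3)
  x <- matrix(runif(100), 10, 10)
  F <- normalize_features(extract_patch_features(x, 3))
  K <- build_kernel_matrix(F, k = 7)
  expect_equal(max(abs(Matrix::rowSums(K) - 1)), 0, tolerance = 1e-12)
  nnz <- diff(Matrix::t(K)@p)
  expect_true(all(nnz == 7))
  expect_true(all(Matrix::diag(K) > 0))  # self-neighbour always kept
  expect_true(all(K@x >= 0))
  expect_error(build_kernel_matrix(F, k = 101), "exceed")
})

test_that("a constant feature map yields uniform 1/k rows", {
  F <- normalize_features(extract_patch_features(matrix(1, 8, 8), 3))
  K <- build_kernel_matrix(F, k = 10)
  expect_true(all(abs(K@x - 1 / 10) < 1e-12))
})

test_that("kNN neighbour sets match an exhaustive brute-force oracle", {
  set.seed(4)
  n <- 100; C <- 5; k <- 9
  M <- matrix(rnorm(n * C), n, C)
  K <- build_kernel_matrix(M, k = k, sigma = 1)
  D2 <- as.matrix(dist(M))^2
  for (j in seq_len(n)) {
    cand <- setdiff(seq_len(n), j)
    cand <- cand[order(D2[j, cand], cand)]  # ties by lower index
    oracle <- sort(c(j, cand[seq_len(k - 1)]))
    got <- sort(which(K[j, ] > 0))
    expect_identical(got, oracle)
  }
  # weights follow the radial Gaussian before normalization
  j <- 17
  nb <- which(K[j, ] > 0)
  w <- exp(-D2[j, nb] / 2)
  expect_equal(as.numeric(K[j, nb]), unname(w / sum(w)), tolerance = 1e-12)
})

test_that("a windowed search reduces to the global one when it covers the image", {
  set.seed(11)
  x <- matrix(runif(64), 8, 8)
  F <- normalize_features(extract_patch_features(x, 3))
  Kg <- build_kernel_matrix(F, k = 5)
  Kw <- build_kernel_matrix(F, k = 5, window = 8, dims = c(8, 8))
  expect_equal(Kg, Kw, tolerance = 1e-14)
  # a tight window keeps neighbours spatially local (k = 4 so corner
  # pixels still have enough candidates)
  K1 <- build_kernel_matrix(F, k = 4, window = 1, dims = c(8, 8))
  for (j in seq_len(64)) {
    nb <- which(K1[j, ] > 0)
    r0 <- (j - 1) %% 8 + 1; c0 <- (j - 1) %/% 8 + 1
    rr <- (nb - 1) %% 8 + 1; cc <- (nb - 1) %/% 8 + 1
    expect_true(all(abs(rr - r0) <= 1 & abs(cc - c0) <= 1))
  }
  expect_error(build_kernel_matrix(F, k = 5, window = 1), "dims")
  expect_error(build_kernel_matrix(F, k = 20, window = 1, dims = c(8, 8)),
               "window too small")
})

test_that("kernel weights are invariant to channel permutation and flatten as sigma grows", {
  set.seed(5)
  M <- matrix(rnorm(60 * 4), 60, 4)
  K1 <- build_kernel_matrix(M, k = 6)
  K2 <- build_kernel_matrix(M[, c(3, 1, 4, 2)], k = 6)
  expect_equal(K1, K2, tolerance = 1e-14)
  Kinf <- build_kernel_matrix(M, k = 6, sigma = 1e6)
  expect_true(all(abs(Kinf@x - 1 / 6) < 1e-6))
})
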