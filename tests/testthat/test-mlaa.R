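test_that("noise-free data are a fixed point of every update", {
  inst <- small_instance()
  sys <- inst$sys
  ybar <- expected_counts(inst$lam, inst$mu, inst$r, sys)
  nf <- attenuation_factors(inst$mu, sys)
  lam2 <- mlem_lambda_update(inst$lam, ybar, inst$r, nf, sys)
  expect_equal(lam2, inst$lam, tolerance = 1e-12)
  mu2 <- sps_mu_update(inst$mu, ybar, inst$r, inst$lam, sys)
  expect_equal(mu2, inst$mu, tolerance = 1e-12)
  # kernel mode: y = ybar at mu = K alpha leaves alpha unchanged
  K <- random_row_stochastic(144, 5)
  alpha <- inst$mu
  muk <- matrix(as.numeric(K %*% as.vector(alpha)), 12, 12)
  ybark <- expected_counts(inst$lam, muk, inst$r, sys)
  a2 <- kernel_sps_alpha_update(alpha, ybark, inst$r, inst$lam, K, sys)
  expect_equal(a2, alpha, tolerance = 1e-12)
})

test_that("zero activity pixels stay at zero through MLEM", {
  inst <- small_instance()
  lam0 <- inst$lam; lam0[3, ] <- 0
  nf <- attenuation_factors(inst$mu, sys <- inst$sys)
  lam2 <- mlem_lambda_update(lam0, inst$y, inst$r, nf, sys)
  expect_true(all(lam2[3, ] == 0))
  expect_true(all(lam2 >= 0))
})

test_that("each update is non-decreasing in the Poisson likelihood", {
  for (seed in c(11, 12, 13)) {
    inst <- small_instance(seed)
    sys <- inst$sys
    lam <- inst$lam * 0.7  # start off the truth
    mu <- inst$mu * 1.3
    L <- function(lam, mu) log_likelihood(inst$y, lam, mu, inst$r, sys)
    L0 <- L(lam, mu)
    nf <- attenuation_factors(mu, sys)
    lam1 <- mlem_lambda_update(lam, inst$y, inst$r, nf, sys)
    L1 <- L(lam1, mu)
    expect_gte(L1, L0)
    mu1 <- sps_mu_update(mu, inst$y, inst$r, lam1, sys)
    L2 <- L(lam1, mu1)
    expect_gte(L2, L1)
    # kernelized attenuation step through a random row-stochastic K
    K <- random_row_stochastic(144, 5, seed = seed)
    alpha <- mu
    muk <- matrix(as.numeric(K %*% as.vector(alpha)), 12, 12)
    Lk0 <- L(lam1, muk)
    a1 <- kernel_sps_alpha_update(alpha, inst$y, inst$r, lam1, K, sys)
    muk1 <- matrix(as.numeric(K %*% as.vector(a1)), 12, 12)
    expect_gte(L(lam1, muk1), Lk0)
    expect_true(all(a1 >= 0))
  }
})

test_that("excess counts on rays through a pixel decrease its attenuation", {
  inst <- small_instance()
  # uniformly more counts than expected => less attenuation everywhere
  y_hi <- inst$ybar * 1.5
  mu1 <- sps_mu_update(inst$mu, y_hi, inst$r, inst$lam, inst$sys)
  expect_true(all(mu1 <= inst$mu + 1e-15))
  expect_lt(sum(mu1), sum(inst$mu))
})

test_that("reconstruction contracts hold: n_outer = 0, truth init, traces", {
  inst <- small_instance()
  sys <- inst$sys
  st0 <- mlaa_reconstruct(inst$y, inst$r, sys, inst$mu, 0,
                          init_lam = inst$lam)
  expect_identical(st0$mu, inst$mu)
  expect_identical(st0$lam, inst$lam)
  expect_length(st0$loglik_trace, 0)
  # noise-free data with truth init stays at the truth
  ybar <- expected_counts(inst$lam, inst$mu, inst$r, sys)
  st <- mlaa_reconstruct(ybar, inst$r, sys, inst$mu, 5, init_lam = inst$lam)
  expect_equal(st$mu, inst$mu, tolerance = 1e-10)
  expect_equal(st$lam, inst$lam, tolerance = 1e-10)
  # noisy run: monotone trace, nonnegative images
  st2 <- mlaa_reconstruct(inst$y, inst$r, sys, inst$mu * 1.2, 30)
  expect_true(all(diff(st2$loglik_trace) >= 0))
  expect_true(all(st2$mu >= 0) && all(st2$lam >= 0))
})

test_that("kernel MLAA with the identity matches standard MLAA bitwise", {
  inst <- small_instance()
  sys <- inst$sys
  st_std <- mlaa_reconstruct(inst$y, inst$r, sys, inst$mu * 1.2, 15,
                             snapshot_iters = c(5, 15))
  st_id <- kernel_mlaa_reconstruct(inst$y, inst$r, sys,
                                   Matrix::Diagonal(144), inst$mu * 1.2, 15,
                                   snapshot_iters = c(5, 15))
  expect_identical(st_id$mu, st_std$mu)
  expect_identical(st_id$lam, st_std$lam)
  expect_identical(st_id$loglik_trace, st_std$loglik_trace)
  expect_identical(st_id$snapshots, st_std$snapshots)
})

test_that("kernel MLAA returns mu = K alpha and a monotone trace", {
  inst <- small_instance()
  K <- random_row_stochastic(144, 6, seed = 21)
  st <- kernel_mlaa_reconstruct(inst$y, inst$r, inst$sys, K,
                                inst$mu * 1.2, 25)
  expect_lt(max(abs(as.vector(st$mu) -
                    as.numeric(K %*% as.vector(st$alpha)))), 1e-12)
  expect_true(all(diff(st$loglik_trace) >= 0))
  expect_true(all(st$alpha >= 0))
})
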