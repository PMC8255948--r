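test_that("an axis-aligned ray collects one pixel length per pixel", {
  g <- image_grid(8, 8, 0.5)
  geom <- scanner_geometry(1, 8, 0.5, n_tof = 1, tof_fwhm = 5)
  sys <- build_system(g, geom)
  # every ray crosses one full row of pixels
  for (i in seq_len(8)) {
    row <- sys$A[i, ]
    expect_equal(sum(row > 0), 8)
    expect_equal(unname(row[row > 0]), rep(0.5, 8))
  }
})

test_that("no intersection length exceeds the pixel diagonal", {
  sys <- small_system()
  expect_true(all(sys$A@x <= small_grid()$pixel_size * sqrt(2) + 1e-12))
  expect_true(all(sys$A@x > 0))
  expect_true(all(sys$G@x > 0))
})

test_that("TOF bins partition the non-TOF projector", {
  sys <- small_system()
  nd <- sys$geom$n_det
  Gsum <- Reduce(`+`, lapply(seq_len(sys$geom$n_tof), function(m)
    sys$G[(m - 1) * nd + seq_len(nd), ]))
  expect_lt(max(abs(Gsum - sys$A)), 1e-10)
})

test_that("projector adjoint identity holds to 1e-10 on a 16x16 grid", {
  g <- image_grid(16, 16, 0.4)
  geom <- scanner_geometry(12, 20, 0.4, n_tof = 3, tof_fwhm = 3)
  sys <- build_system(g, geom)
  set.seed(5)
  for (trial in 1:5) {
    u <- runif(g$n_pix)
    v <- runif(nrow(sys$G))
    lhs <- sum(as.numeric(sys$G %*% u) * v)
    rhs <- sum(u * as.numeric(Matrix::crossprod(sys$G, v)))
    expect_lt(abs(lhs - rhs) / abs(lhs), 1e-10)
    va <- runif(nrow(sys$A))
    lhs_a <- sum(as.numeric(sys$A %*% u) * va)
    rhs_a <- sum(u * as.numeric(Matrix::crossprod(sys$A, va)))
    expect_lt(abs(lhs_a - rhs_a) / abs(lhs_a), 1e-10)
  }
})

test_that("attenuation factors follow the exponential line integral", {
  g <- image_grid(8, 8, 0.5)
  geom <- scanner_geometry(1, 8, 0.5, n_tof = 1, tof_fwhm = 5)
  sys <- build_system(g, geom)
  expect_true(all(attenuation_factors(matrix(0, 8, 8), sys) == 1))
  # one attenuating pixel crossed over the full pixel width
  mu <- matrix(0, 8, 8); mu[3, 5] <- 0.7
  n <- attenuation_factors(mu, sys)
  expect_equal(n[3, 1], exp(-0.7 * 0.5))
  expect_true(all(n[-3, 1] == 1))
  # doubling mu squares the factors (c = 1)
  expect_equal(as.vector(attenuation_factors(2 * mu, sys)),
               as.vector(n)^2)
  expect_error(attenuation_factors(-mu, sys), "nonnegative")
})

test_that("attenuation factors are monotone non-increasing in every pixel", {
  sys <- small_system()
  set.seed(8)
  mu <- matrix(runif(144, 0, 0.1), 12, 12)
  n0 <- attenuation_factors(mu, sys)
  mu2 <- mu; mu2[5, 7] <- mu2[5, 7] + 0.3
  n1 <- attenuation_factors(mu2, sys)
  expect_true(all(n1 <= n0 + 1e-15))
})

test_that("expected counts follow the affine Poisson model", {
  sys <- small_system()
  r <- matrix(0.3, sys$geom$n_det, sys$geom$n_tof)
  lam0 <- matrix(0, 12, 12)
  expect_equal(expected_counts(lam0, matrix(0.01, 12, 12), r, sys), r)
  set.seed(2)
  lam <- matrix(runif(144), 12, 12); mu <- matrix(runif(144, 0, 0.05), 12, 12)
  y1 <- expected_counts(lam, mu, r, sys)
  y2 <- expected_counts(2 * lam, mu, r, sys)
  expect_equal(y2 - r, 2 * (y1 - r))
  expect_error(expected_counts(lam, mu, r[, 1, drop = FALSE], sys), "shape")
})

test_that("log-likelihood is maximized at ybar = y and sums per bin", {
  sys <- small_system()
  inst <- small_instance()
  # per-bin concavity: the saturated value dominates
  L_sat <- sum(ifelse(inst$y > 0, inst$y * log(inst$y), 0)) - sum(inst$y)
  Lhat <- gctrecon:::.loglik_from_ybar(inst$y, inst$y + 0)
  expect_equal(Lhat, L_sat)
  expect_lt(gctrecon:::.loglik_from_ybar(inst$y, inst$y * 1.07), L_sat)
  # all-zero counts
  expect_equal(gctrecon:::.loglik_from_ybar(inst$y * 0, inst$ybar),
               -sum(inst$ybar))
  # three-bin toy against a hand sum
  y3 <- c(2, 0, 5); yb3 <- c(1.5, 0.2, 6)
  expect_equal(gctrecon:::.loglik_from_ybar(y3, yb3),
               2 * log(1.5) - 1.5 - 0.2 + 5 * log(6) - 6)
  # impossible datum
  expect_error(gctrecon:::.loglik_from_ybar(c(1, 0), c(0, 1)), "zero")
  # zero bins with zero counts contribute nothing
  expect_equal(gctrecon:::.loglik_from_ybar(c(y3, 0), c(yb3, 0)),
               gctrecon:::.loglik_from_ybar(y3, yb3))
})

test_that("simulated scans meet the count budget and background fraction", {
  ph <- make_phantom(image_grid(48, 48, 0.35), seed = 4)
  geom <- scanner_geometry(20, 48, 0.35, n_tof = 3, tof_fwhm = 8.25)
  sys <- build_system(ph$grid, geom)
  scan <- simulate_scan(ph, sys, total_events = 1e5, seed = 9)
  expect_equal(sum(scan$ybar), 1e5)
  expect_equal(sum(scan$r$values) / sum(scan$ybar), 0.4)
  expect_identical(scan$y$values,
                   simulate_scan(ph, sys, 1e5, seed = 9)$y$values)
  expect_false(identical(scan$y$values,
                         simulate_scan(ph, sys, 1e5, seed = 10)$y$values))
  # trues-relative background reading
  scan2 <- simulate_scan(ph, sys, 1e5, seed = 9,
                         background_relative_to = "trues")
  trues <- sum(scan2$ybar) - sum(scan2$r$values)
  expect_equal(sum(scan2$r$values) / trues, 0.4)
})

test_that("Poisson draws match their expectation over replicates", {
  ph <- make_phantom(image_grid(48, 48, 0.35), seed = 4)
  geom <- scanner_geometry(8, 24, 0.7, n_tof = 3, tof_fwhm = 8.25)
  sys <- build_system(ph$grid, geom)
  scan0 <- simulate_scan(ph, sys, 2e4, seed = 1)
  bin <- which.max(scan0$ybar)  # the hottest bin
  draws <- vapply(1:200, function(s)
    simulate_scan(ph, sys, 2e4, seed = s)$y$values[bin], 0)
  se <- sqrt(scan0$ybar[bin] / 200)
  expect_lt(abs(mean(draws) - scan0$ybar[bin]), 5 * se)
})
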