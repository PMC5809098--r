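test_that("Chernoff distance of identical Gaussians is zero", {
  g <- gaussian_summary(c(1, -2), diag(c(2, 0.5)))
  cd <- chernoff_distance(g, g)
  expect_lt(cd$psi, 1e-10)
})

test_that("equal covariances give the quadratic closed form at lambda = 1/2", {
  C <- matrix(c(2, 0.3, 0.3, 1), 2)
  mu0 <- c(0, 0); mu1 <- c(1.2, -0.7)
  cd <- chernoff_distance(gaussian_summary(mu0, C), gaussian_summary(mu1, C))
  d2 <- drop(t(mu1 - mu0) %*% solve(C) %*% (mu1 - mu0))
  expect_equal(cd$psi, d2 / 8, tolerance = 1e-6)
  expect_equal(cd$lambda_star, 0.5, tolerance = 1e-3)
  # identity covariance special case: psi = |dmu|^2 / 8
  gI0 <- gaussian_summary(c(0, 0, 0), diag(3))
  gI1 <- gaussian_summary(c(2, 0, 0), diag(3))
  expect_equal(chernoff_distance(gI0, gI1)$psi, 4 / 8, tolerance = 1e-6)
})

test_that("closed form matches numeric quadrature and a lambda grid in 1-D", {
  # unequal variances: the optimum is interior and not at 1/2
  g0 <- gaussian_summary(0, matrix(1))
  g1 <- gaussian_summary(0, matrix(4))
  cd <- chernoff_distance(g0, g1)
  lam_grid <- seq(0.002, 0.998, length.out = 200)
  grid_best <- max(vapply(lam_grid, chernoff_quad_1d, numeric(1),
                          m0 = 0, s0 = 1, m1 = 0, s1 = 2))
  expect_lt(abs(cd$psi - grid_best), 1e-6)
})

test_that("closed-form objective equals the quadrature oracle on random 1-D instances", {
  set.seed(21)
  for (k in 1:10) {
    m0 <- rnorm(1); m1 <- rnorm(1)
    s0 <- runif(1, 0.5, 2); s1 <- runif(1, 0.5, 2)
    lam <- runif(1, 0.05, 0.95)
    closed <- loopgain:::chernoff_objective(
      lam, gaussian_summary(m0, matrix(s0^2)),
      gaussian_summary(m1, matrix(s1^2)),
      log(s0^2), log(s1^2))
    expect_equal(closed, chernoff_quad_1d(lam, m0, s0, m1, s1),
                 tolerance = 1e-6)
  }
})

test_that("closed-form objective equals a 2-D quadrature oracle", {
  set.seed(22)
  for (k in 1:5) {
    A0 <- matrix(rnorm(4), 2); C0 <- crossprod(A0) + diag(2) * 0.5
    A1 <- matrix(rnorm(4), 2); C1 <- crossprod(A1) + diag(2) * 0.5
    mu0 <- rnorm(2, sd = 0.5); mu1 <- rnorm(2, sd = 0.5)
    lam <- runif(1, 0.2, 0.8)
    g0 <- gaussian_summary(mu0, C0); g1 <- gaussian_summary(mu1, C1)
    d0 <- function(x, y) {
      z0 <- cbind(x - mu0[1], y - mu0[2]); z1 <- cbind(x - mu1[1], y - mu1[2])
      q0 <- rowSums((z0 %*% solve(C0)) * z0)
      q1 <- rowSums((z1 %*% solve(C1)) * z1)
      p0 <- exp(-q0 / 2) / (2 * pi * sqrt(det(C0)))
      p1 <- exp(-q1 / 2) / (2 * pi * sqrt(det(C1)))
      p1^lam * p0^(1 - lam)
    }
    # midpoint-rule Riemann sum on a dense grid (smooth, rapidly decaying
    # integrand: error is negligible at this resolution)
    gx <- seq(-16, 16, length.out = 1201)
    h <- gx[2] - gx[1]
    xy <- expand.grid(x = gx, y = gx)
    quad <- sum(d0(xy$x, xy$y)) * h^2
    closed <- loopgain:::chernoff_objective(
      lam, g0, g1, determinant(C0)$modulus[1], determinant(C1)$modulus[1])
    expect_lt(abs(closed + log(quad)), 1e-4)
  }
})

test_that("distance is symmetric and monotone in mean separation", {
  set.seed(23)
  A0 <- matrix(rnorm(9), 3); C0 <- crossprod(A0) + diag(3)
  A1 <- matrix(rnorm(9), 3); C1 <- crossprod(A1) + diag(3)
  g0 <- gaussian_summary(c(0, 0, 0), C0)
  dmu <- c(1, -0.5, 0.25)
  g1 <- gaussian_summary(dmu, C1)
  cd_a <- chernoff_distance(g0, g1)
  cd_b <- chernoff_distance(g1, g0)
  expect_equal(cd_a$psi, cd_b$psi, tolerance = 1e-6)
  expect_equal(cd_a$lambda_star, 1 - cd_b$lambda_star, tolerance = 1e-3)
  # scaling the separation never decreases the distance; the maximized
  # distance is never below the Bhattacharyya point lambda = 1/2
  psis <- vapply(c(1, 1.5, 2, 3), function(s)
    chernoff_distance(g0, gaussian_summary(s * dmu, C1))$psi, numeric(1))
  expect_true(all(diff(psis) > 0))
  obj_half <- loopgain:::chernoff_objective(
    0.5, g0, g1, determinant(C0)$modulus[1], determinant(C1)$modulus[1])
  expect_gte(cd_a$psi, obj_half - 1e-10)
  # with equal covariances the optimum sits exactly at 1/2
  gE0 <- gaussian_summary(c(0, 0, 0), C0)
  gE1 <- gaussian_summary(dmu, C0)
  ldet <- determinant(C0)$modulus[1]
  expect_equal(chernoff_distance(gE0, gE1)$psi,
               loopgain:::chernoff_objective(0.5, gE0, gE1, ldet, ldet),
               tolerance = 1e-8)
})

test_that("fit_gaussian estimates moments and guards degeneracy", {
  set.seed(24)
  s <- matrix(rnorm(4000, mean = 3), ncol = 2)
  g <- fit_gaussian(s)
  expect_equal(g$mu, c(3, 3), tolerance = 0.1)
  expect_equal(g$C, diag(2), tolerance = 0.15)
  # constant samples survive via the ridge
  gc <- fit_gaussian(matrix(5, 50, 2), epsilon = 1e-6)
  expect_equal(gc$mu, c(5, 5))
  expect_true(all(eigen(gc$C)$values > 0))
  expect_error(fit_gaussian(matrix(rnorm(4), 2, 2)), "samples")
})

test_that("discriminability timecourse is near zero for exchangeable ensembles", {
  set.seed(25)
  arr0 <- array(rnorm(100 * 5 * 11), c(100, 5, 11))
  arr1 <- array(rnorm(100 * 5 * 11), c(100, 5, 11))
  tc <- discriminability_timecourse(arr1, arr0, times_ms = seq(0, 1000, 100),
                                    step_ms = 100, seed = 1)
  expect_true(all(tc$psi >= 0))
  expect_lt(discriminability_index(tc), 0.2)
  expect_true(all(tc$lambda_star > 0 & tc$lambda_star < 1))
  # a mean shift in one condition is detected
  arr2 <- arr1 + 1.5
  tc2 <- discriminability_timecourse(arr2, arr0, times_ms = seq(0, 1000, 100),
                                     step_ms = 100, seed = 1)
  expect_gt(discriminability_index(tc2), 5 * discriminability_index(tc))
  expect_error(
    discriminability_timecourse(arr1[1:10, , ], arr0,
                                times_ms = seq(0, 1000, 100), seed = 1),
    "ensemble")
})
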