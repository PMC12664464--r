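# Synthetic acquisition generator: phantom rasterization, coil maps,
# covariance structure and the noise model.

test_that("Shepp-Logan rasterization matches a brute-force ellipse oracle", {
  n <- 64
  ph <- make_phantom(n, n, "shepp_logan")
  # independent oracle: evaluate every ellipse inequality at pixel centers
  ell <- matrix(c(
     2.00, 0.6900, 0.9200,  0.00,  0.0000,   0,
    -0.98, 0.6624, 0.8740,  0.00, -0.0184,   0,
    -0.02, 0.1100, 0.3100,  0.22,  0.0000, -18,
    -0.02, 0.1600, 0.4100, -0.22,  0.0000,  18,
     0.01, 0.2100, 0.2500,  0.00,  0.3500,   0,
     0.01, 0.0460, 0.0460,  0.00,  0.1000,   0,
     0.01, 0.0460, 0.0460,  0.00, -0.1000,   0,
     0.01, 0.0460, 0.0230, -0.08, -0.6050,   0,
     0.01, 0.0230, 0.0230,  0.00, -0.6060,   0,
     0.01, 0.0230, 0.0460,  0.06, -0.6050,   0), ncol = 6, byrow = TRUE)
  expected <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    x <- (2 * j - n - 1) / n
    y <- -(2 * i - n - 1) / n
    for (k in seq_len(nrow(ell))) {
      phi <- ell[k, 6] * pi / 180
      u <- (x - ell[k, 4]) * cos(phi) + (y - ell[k, 5]) * sin(phi)
      v <- -(x - ell[k, 4]) * sin(phi) + (y - ell[k, 5]) * cos(phi)
      if ((u / ell[k, 2])^2 + (v / ell[k, 3])^2 <= 1)
        expected[i, j] <- expected[i, j] + ell[k, 1]
    }
  }
  expect_equal(Re(ph$pixels), expected, tolerance = 1e-12)
  expect_identical(ph$pixels[1, 1], 0 + 0i)   # background is exactly zero
  expect_identical(ph$pixels, make_phantom(n, n, "shepp_logan")$pixels)
})

test_that("blocks phantom is piecewise constant with zero background", {
  ph <- make_phantom(32, 32, "blocks")
  v <- Re(ph$pixels)
  expect_lt(length(unique(round(as.vector(v), 10))), 12)
  expect_identical(v[1, 1], 0)
  expect_true(any(v > 0))
  expect_error(make_phantom(8, 32), "at least 16")
})

test_that("coil sensitivities satisfy support and peak contracts", {
  su <- make_coil_sensitivities(1, 32, 32, "uniform")
  expect_true(all(su$maps == 1 + 0i))
  s <- make_coil_sensitivities(8, 32, 32, "gaussian_ring")
  rss <- sqrt(apply(abs(s$maps)^2, c(2, 3), sum))
  expect_true(all(rss > 0))
  # each coil attains the configured peak magnitude at its own center pixel
  for (c_ in 1:8)
    expect_equal(max(abs(s$maps[c_, , ])), 1.0, tolerance = 1e-12)
  expect_error(make_coil_sensitivities(0, 32, 32), ">= 1")
})

test_that("noise covariance is Hermitian, unit-diagonal and positive definite", {
  expect_equal(make_noise_covariance(4, 0, 1)$psi, diag(4) + 0i)
  cov <- make_noise_covariance(20, 0.3, 7)
  expect_identical(cov$psi, Conj(t(cov$psi)))
  expect_equal(Re(diag(cov$psi)), rep(1, 20))
  ev <- eigen(cov$psi, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
  # nearest-neighbor correlation magnitude equals the requested value
  expect_equal(abs(cov$psi[1, 2]), 0.3, tolerance = 1e-12)
  expect_error(make_noise_covariance(4, 1.0, 1), "offdiag")
})

test_that("noiseless acquisition inverts to the coil images exactly", {
  ph <- make_phantom(32, 32)
  s <- make_coil_sensitivities(4, 32, 32)
  ks <- simulate_acquisition(ph, s, NULL, 0)
  ci <- fix_coil_images(ph, s)
  worst <- max(vapply(1:4, function(c_)
    max(abs(ifft2c(ks$data[c_, , ]) - ci[c_, , ])), numeric(1)))
  expect_lt(worst / max(abs(ci)), 1e-10)
})

test_that("acquisition noise has the stated per-sample variance", {
  ph <- make_phantom(320, 320)  # ~1e5 k-samples on one coil
  s <- make_coil_sensitivities(1, 320, 320, "uniform")
  cov <- make_noise_covariance(1, 0, 1)
  ks0 <- simulate_acquisition(ph, s, cov, 0)
  ks1 <- simulate_acquisition(ph, s, cov, 1, seed = 9)
  dv <- ks1$data - ks0$data
  expect_equal(mean(abs(dv)^2), 1, tolerance = 0.05)
  # determinism
  ks1b <- simulate_acquisition(ph, s, cov, 1, seed = 9)
  expect_identical(ks1$data, ks1b$data)
})

test_that("noise scan covariance round trip converges like 1/sqrt(n)", {
  cov <- make_noise_covariance(4, 0.3, 7)
  errs <- vapply(c(2000, 32000), function(n) {
    est <- estimate_noise_covariance(simulate_noise_scan(cov, n, seed = 3))
    max(abs(est$psi - cov$psi))
  }, numeric(1))
  expect_lt(errs[2], errs[1])      # error decays with n
  expect_lt(errs[2], 0.05)         # and is small at 3.2e4 samples
  # determinism of the scan
  a <- simulate_noise_scan(cov, 100, seed = 5)
  b <- simulate_noise_scan(cov, 100, seed = 5)
  expect_identical(a$samples, b$samples)
  expect_error(simulate_noise_scan(cov, 1), "n_samples")
})
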