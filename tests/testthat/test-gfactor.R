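# Noise covariance estimation, synthesis and pseudo-replica g-factors.

test_that("the covariance estimator matches its hand-computed form", {
  # 2 coils, 2 samples, computed by hand: psi = (1/n) N N^H
  N <- matrix(c(1 + 0i, 0 + 1i, 2 + 0i, 0 - 1i), 2, 2)
  ns <- structure(list(samples = N), class = "noise_samples")
  psi <- estimate_noise_covariance(ns)$psi
  expect_equal(psi, (N %*% Conj(t(N))) / 2)
  expect_equal(psi[1, 1], 5 / 2 + 0i)
  expect_equal(psi[2, 1], Conj(psi[1, 2]))
  # single coil, constant value c: psi = |c|^2
  cns <- structure(list(samples = matrix(3 - 4i, 1, 10)),
                   class = "noise_samples")
  expect_equal(estimate_noise_covariance(cns)$psi[1, 1], 25 + 0i)
  # mean subtraction zeroes a constant signal
  expect_equal(abs(estimate_noise_covariance(cns, mean_subtract = TRUE)
                   $psi[1, 1]), 0)
  expect_error(estimate_noise_covariance(
    structure(list(samples = matrix(1i, 2, 1)), class = "noise_samples")),
    "two")
})

test_that("the complex Cholesky factor reproduces the covariance", {
  idn <- structure(list(psi = diag(3) + 0i), class = "noise_covariance")
  expect_equal(covariance_sqrt(idn), diag(3) + 0i)
  dg <- structure(list(psi = diag(c(4, 9)) + 0i), class = "noise_covariance")
  expect_equal(covariance_sqrt(dg), diag(c(2, 3)) + 0i)
  cov <- make_noise_covariance(20, 0.3, 7)
  L <- covariance_sqrt(cov)
  expect_lt(max(abs(L %*% Conj(t(L)) - cov$psi)), 1e-12)
  expect_true(all(abs(L[upper.tri(L)]) == 0))
  bad <- structure(list(psi = matrix(c(1, 2, 2, 1) + 0i, 2, 2)),
                   class = "noise_covariance")
  expect_error(covariance_sqrt(bad), "positive semi-definite")
})

test_that("synthesized noise has the requested covariance and is seeded", {
  cov <- make_noise_covariance(6, 0.3, 7)
  z <- synthesize_noise(cov, c(6, 1e5), seed = 2)
  emp <- (z %*% Conj(t(z))) / ncol(z)
  expect_lt(max(abs(emp - cov$psi)), 0.05)
  expect_identical(synthesize_noise(cov, c(6, 10), seed = 2),
                   synthesize_noise(cov, c(6, 10), seed = 2))
})

test_that("replica sigma matches linear noise propagation", {
  # single coil on an 8x8 grid; the matched-filter combine is an explicit
  # unitary linear map A = IFFT, so the replica std must match the closed
  # form sqrt(diag(A Psi A^H) / 2): Psi is the complex covariance and the
  # division by 2 projects circular complex noise onto the real output
  n <- 8
  px <- matrix(5, n, n) + 0i
  ks <- multicoil_kspace(array(fft2c(px), c(1, n, n)))
  cov <- make_noise_covariance(1, 0, 1)
  su <- make_coil_sensitivities(1, n, n, "uniform")
  opl <- op_matched_filter(su)
  cfg <- replica_config(2000, seed = 11, noise_scale = 0.01)
  sm <- pseudo_replica_std(opl, ks, NULL, cov, cfg)
  closed <- sqrt(0.5) * 0.01   # unitary A, psi = 1
  expect_lt(max(abs(sm$sigma / closed - 1)), 0.05)
  # noise_scale = 0 gives exactly zero sigma
  sm0 <- pseudo_replica_std(opl, ks, NULL, cov,
                            replica_config(10, 1, 0))
  expect_true(all(sm0$sigma == 0))
  # doubling the noise scale doubles sigma exactly (same seeds, linear op)
  cfg2 <- replica_config(50, seed = 11, noise_scale = 0.02)
  cfg1 <- replica_config(50, seed = 11, noise_scale = 0.01)
  s1 <- pseudo_replica_std(opl, ks, NULL, cov, cfg1)
  s2 <- pseudo_replica_std(opl, ks, NULL, cov, cfg2)
  expect_lt(max(abs(s2$sigma / s1$sigma - 2)), 1e-6)
})

test_that("the g map follows its definition and flags zero denominators", {
  mk <- function(sig, role) structure(
    list(sigma = matrix(sig, 2, 2), n_replicas = 10, role = role),
    class = "std_map")
  g <- gfactor_map(mk(2, "accelerated"), mk(1, "normal"), R = 4)
  expect_equal(g$g, matrix(1, 2, 2))
  g1 <- gfactor_map(mk(3, "accelerated"), mk(3, "normal"), R = 1)
  expect_equal(g1$g, matrix(1, 2, 2))
  nz <- mk(1, "normal"); nz$sigma[1, 1] <- 0
  gz <- gfactor_map(mk(1, "accelerated"), nz, R = 1)
  expect_true(is.na(gz$g[1, 1]))
  expect_true(gz$invalid[1, 1])
  expect_false(any(is.infinite(gz$g), na.rm = TRUE))
})

test_that("g is invariant to the noise scale for linear operators", {
  n <- 8
  px <- matrix(5, n, n) + 0i
  ks <- multicoil_kspace(array(fft2c(px), c(1, n, n)))
  cov <- make_noise_covariance(1, 0, 1)
  su <- make_coil_sensitivities(1, n, n, "uniform")
  opl <- op_matched_filter(su)
  msk <- regular_mask(n, 2)
  # both arms through the linear operator: g then cancels the scale
  # exactly (the pipeline's normal arm is the magnitude RSS
  # reconstruction, which is linear only to first order in SNR)
  g_at <- function(scale_) {
    acc <- pseudo_replica_std(opl, ks, msk, cov,
                              replica_config(60, 21, scale_))
    nor <- pseudo_replica_std(opl, ks, NULL, cov,
                              replica_config(60, 22, scale_))
    nor$role <- "normal"
    gfactor_map(acc, nor, R = effective_acceleration(msk))$g
  }
  ga <- g_at(1); gb <- g_at(2)
  expect_lt(max(abs(ga / gb - 1), na.rm = TRUE), 1e-6)
})

test_that("the g estimate tightens like 1/sqrt(n_replicas)", {
  n <- 8
  px <- matrix(5, n, n) + 0i
  ks <- multicoil_kspace(array(fft2c(px), c(1, n, n)))
  cov <- make_noise_covariance(1, 0, 1)
  su <- make_coil_sensitivities(1, n, n, "uniform")
  opl <- op_matched_filter(su)
  full <- sampling_mask(rep(TRUE, n))
  spread <- function(n_w) {
    gs <- vapply(1:8, function(k) {
      cfg <- replica_config(n_w, seed = 100 + k, noise_scale = 0.01)
      stats::median(gfactor_pipeline(opl, ks, full, cov, cfg)$g,
                    na.rm = TRUE)
    }, numeric(1))
    stats::sd(gs)
  }
  s250 <- spread(250); s1000 <- spread(1000)
  # expected ratio 2; allow a generous Monte-Carlo band
  expect_gt(s250 / s1000, 1.2)
  expect_lt(s250 / s1000, 3.5)
})
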