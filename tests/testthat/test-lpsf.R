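# LPSF computation, profile interpolation and main-lobe width measurement.

test_that("perturbation amplitudes follow the coil signal levels", {
  f <- fix_single64()
  pert <- build_perturbation(f$coil_imgs, c(32, 32), 0.001)
  expect_equal(pert$b, 0.001 * max(abs(f$phantom$pixels)))
  expect_equal(abs(pert$coil_amplitudes), pert$b)  # single uniform coil
  # two coils with signals (3, 4): amplitudes proportional, norm b
  ci <- array(0i, c(2, 16, 16))
  ci[1, , ] <- 3; ci[2, , ] <- 4
  p2 <- build_perturbation(ci, c(8, 8), 0.001)
  expect_equal(abs(p2$coil_amplitudes), c(0.6, 0.8) * p2$b)
  expect_error(build_perturbation(array(0i, c(1, 16, 16)), c(8, 8)),
               "degenerate")
})

test_that("the full-sampling LPSF is the shifted band-limited kernel", {
  f <- fix_single64()
  pert <- build_perturbation(f$coil_imgs, c(30, 35))
  l <- compute_lpsf(op_rss(), f$coil_imgs, NULL, pert)
  pk <- which(abs(l$response) == max(abs(l$response)), arr.ind = TRUE)
  expect_equal(as.integer(pk), c(30L, 35L))
  prof <- extract_profile(l, "horizontal")
  expect_length(prof$values, 64)
  expect_identical(prof$center_index, 35L)
  expect_gte(prof$values[35], max(prof$values[-35]))
  vprof <- extract_profile(l, "vertical")
  expect_length(vprof$values, 64)
  expect_identical(vprof$center_index, 30L)
})

test_that("Fourier interpolation is exact for band-limited signals", {
  n <- 32
  t_ <- seq_len(n) - 1
  v <- 1.5 + cos(2 * pi * 3 * t_ / n + 0.4)
  p <- structure(list(values = v, center_index = 1L, step = 1),
                 class = "profile1d")
  expect_identical(fourier_interpolate(p, 1), p)
  p5 <- fourier_interpolate(p, 5)
  expect_length(p5$values, 5 * n)
  t5 <- (seq_len(5 * n) - 1) / 5
  expect_lt(max(abs(p5$values - (1.5 + cos(2 * pi * 3 * t5 / n + 0.4)))),
            1e-10)
  # original samples preserved at stride 5
  expect_lt(max(abs(p5$values[seq(1, 5 * n, 5)] - v)), 1e-12)
  expect_equal(p5$step, 1 / 5)
})

test_that("main-lobe width measures the band-limited kernel and dilations", {
  # periodic sinc (Dirichlet) profile on the unit-pixel grid
  n <- 64
  dirichlet <- function(x) ifelse(abs(x) < 1e-12, 1,
                                  sin(pi * x) / (n * sin(pi * x / n)))
  grid <- (seq_len(n) - 1) - n / 2
  p <- structure(list(values = abs(dirichlet(grid)),
                      center_index = n / 2 + 1L, step = 1),
                 class = "profile1d")
  w <- mainlobe_width(fourier_interpolate(p, 5))
  expect_equal(w, 1.0, tolerance = 0.02)
  # stretching the kernel by 2 doubles the width
  p2 <- structure(list(values = abs(dirichlet(grid / 2)),
                       center_index = n / 2 + 1L, step = 1),
                  class = "profile1d")
  expect_equal(mainlobe_width(fourier_interpolate(p2, 5)), 2.0,
               tolerance = 0.04)
  # degenerate profiles are flagged, not guessed
  flatp <- structure(list(values = rep(1, n), center_index = 32L, step = 1),
                     class = "profile1d")
  expect_true(is.nan(mainlobe_width(flatp)))
  zerop <- structure(list(values = rep(0, n), center_index = 32L, step = 1),
                     class = "profile1d")
  expect_true(is.nan(mainlobe_width(zerop)))
})

test_that("linear operators give amplitude-invariant LPSFs", {
  n <- 32
  ph <- make_phantom(n, n)
  s <- fix_unit_rss(make_coil_sensitivities(4, n, n))
  ci <- fix_coil_images(ph, s)
  msk <- regular_mask(n, 4)
  op <- op_matched_filter(s)
  rep_ <- check_linearity(op, ci, msk, c(16, 18),
                          amplitudes = c(0.001, 0.0005, 0.01))
  expect_lt(rep_$max_discrepancy, 1e-6)
  expect_true(rep_$pass)
  expect_error(check_linearity(op, ci, msk, c(16, 18), amplitudes = 0.001),
               "two")
})

test_that("appending a blur to an operator never shrinks the width", {
  n <- 32
  ph <- make_phantom(n, n)
  su <- make_coil_sensitivities(1, n, n, "uniform")
  ci <- fix_coil_images(ph, su)
  gauss_blur_op <- function(fwhm_px) {
    # blur via k-space apodization appended to the direct reconstruction
    recon_operator(function(ks, mask) {
      img <- rss_ifft_recon(ks)
      if (fwhm_px == 0) return(img)
      sig_k <- n / (pi * fwhm_px) * sqrt(log(2) / 2) * 2  # k-space sigma
      fr <- (seq_len(n) - 1) - floor(n / 2)
      w <- exp(-(outer(fr^2, fr^2, "+")) / (2 * sig_k^2))
      abs(ifft2c(fft2c(img) * w))
    }, name = sprintf("blur%g", fwhm_px))
  }
  widths <- vapply(c(0, 1, 2, 4), function(fw) {
    pert <- build_perturbation(ci, c(16, 16))
    l <- compute_lpsf(gauss_blur_op(fw), ci, NULL, pert)
    mainlobe_width(fourier_interpolate(extract_profile(l, "horizontal"), 5))
  }, numeric(1))
  expect_true(all(diff(widths) >= -1e-9))
  expect_gt(widths[4], widths[1])
})

test_that("resolution maps respect pixel subsets and record failures", {
  n <- 32
  ph <- make_phantom(n, n)
  su <- make_coil_sensitivities(1, n, n, "uniform")
  ci <- fix_coil_images(ph, su)
  sub <- matrix(FALSE, n, n)
  pts <- cbind(c(14, 16, 18, 20, 15, 17, 19, 16, 18, 17),
               c(16, 14, 18, 16, 15, 19, 17, 18, 14, 16))
  sub[pts] <- TRUE
  rm_ <- resolution_map(op_rss(), ci, NULL, "horizontal", pixels = sub)
  expect_identical(sum(!is.na(rm_$widths)) + sum(rm_$invalid), 10L)
  expect_true(all(is.na(rm_$widths[!sub])))
  got <- rm_$widths[pts]
  expect_true(all(abs(got[!is.na(got)] - 1) < 0.02))
})
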