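# Shared fixtures, built once per test run and cached. All fixtures are
# generated in code; nothing is read from disk.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# sensitivity-weighted coil images for a phantom
fix_coil_images <- function(phantom, sens) {
  d <- dim(sens$maps)
  out <- array(0i, dim = d)
  for (c_ in seq_len(d[1]))
    out[c_, , ] <- sens$maps[c_, , ] * phantom$pixels
  out
}

# unit-RSS version of a set of sensitivity maps
fix_unit_rss <- function(sens) {
  d <- dim(sens$maps)
  rss <- matrix(0, d[2], d[3])
  for (c_ in seq_len(d[1])) rss <- rss + abs(sens$maps[c_, , ])^2
  rss <- sqrt(rss)
  out <- sens
  for (c_ in seq_len(d[1])) out$maps[c_, , ] <- sens$maps[c_, , ] / rss
  out
}

nrmse_to <- function(x, ref) sqrt(sum((x - ref)^2) / sum(ref^2))

# 48x48 8-coil study fixture shared by the qualitative acceptance checks
fix_study <- function() fixture("study48", function() {
  n <- 48
  ph <- make_phantom(n, n, "shepp_logan")
  sens <- make_coil_sensitivities(8, n, n, "gaussian_ring")
  ks <- simulate_acquisition(ph, sens, NULL, 0)
  cov <- make_noise_covariance(8, 0.2, 7)
  gm <- grappa_masks(n, 4, 0.25)
  kern <- grappa_calibrate(apply_mask(ks, gm$calibration),
                           kernel_kx = 5, kernel_sampled_lines = 2, R = 4)
  cs_mask <- random_mask(n, 4, 0.125, 1)
  a <- acs_range(n, 0.125)
  cal_cols <- rep(FALSE, n); cal_cols[a[1]:a[2]] <- TRUE
  sens_est <- estimate_sensitivities(
    apply_mask(ks, sampling_mask(cal_cols, a)))
  gt <- abs(ph$pixels)
  # homogeneous-region pixels: 5x5-flat neighborhoods of the ground truth
  flat <- matrix(FALSE, n, n)
  for (i in 3:(n - 2)) for (j in 3:(n - 2)) {
    w <- gt[(i - 2):(i + 2), (j - 2):(j + 2)]
    if (max(w) - min(w) < 1e-9 && gt[i, j] > 0.5) flat[i, j] <- TRUE
  }
  idx <- which(flat, arr.ind = TRUE)
  set.seed(2)
  flat_sub <- idx[sample(nrow(idx), 24), , drop = FALSE]
  list(n = n, phantom = ph, sens = sens, kspace = ks, cov = cov,
       coil_imgs = fix_coil_images(ph, sens),
       grappa = gm, kernel = kern, cs_mask = cs_mask,
       sens_est = sens_est, gt = gt,
       ref = rss_ifft_recon(ks), flat_sub = flat_sub,
       cs_cfg = cs_config(lambda_tv = 0.04, n_iter = 40, cg_iter = 6),
       cs_cfg_fast = cs_config(lambda_tv = 0.04, n_iter = 25, cg_iter = 5))
})

# 64x64 single uniform-coil noiseless fixture for ideal-resolution checks
fix_single64 <- function() fixture("single64", function() {
  ph <- make_phantom(64, 64, "shepp_logan")
  sens <- make_coil_sensitivities(1, 64, 64, "uniform")
  list(phantom = ph, sens = sens,
       coil_imgs = fix_coil_images(ph, sens),
       kspace = simulate_acquisition(ph, sens, NULL, 0))
})
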