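# reconqa

Spatially resolved quality assessment for MRI reconstruction methods.

Modern reconstructions of undersampled MRI data — parallel imaging,
regularized inverse problems, learned methods — are neither linear nor
shift-invariant, so their sharpness and noise behavior vary across the
image and a single global score (RMSE, SSIM) cannot say *where* an image
can be trusted. `reconqa` computes two per-pixel instruments for any
reconstruction operator:

* **Local point-spread-function (LPSF) resolution maps.** The LPSF at
  pixel *a* is the finite difference
  `LPSF(T, O, a) = (T(O + b e_a) − T(O)) / b` of the reconstruction
  operator *T* under a small single-pixel perturbation `b e_a` of the
  object *O*. The width *w* of the main lobe of a 1D profile through the
  LPSF, measured at 2/π (≈ 64%) of its peak after 5-fold Fourier
  interpolation, is the minimal separation at which two points remain
  resolvable (Rayleigh criterion, band-limited PSF): *w* = 1 pixel is
  the fully sampled ideal, *w* > 1 is local blurring. Maps are computed
  per pixel and per direction (horizontal = undersampled phase-encode
  direction).

* **Pseudo multiple-replica g-factor maps.** Synthetic correlated coil
  noise (covariance Ψ estimated from an RF-free noise scan, colored via
  its Cholesky factor) is added to the k-space data over many replicas;
  the per-pixel standard deviations of the accelerated and the directly
  reconstructed arms give
  `g(x, y) = σ_acc(x, y) / (σ_normal(x, y) √R)`,
  the noise amplification beyond the unavoidable √R penalty of an
  R-fold accelerated scan. g > 1 amplifies noise, g < 1 suppresses it.

The package also ships everything needed to run both instruments with no
external data: a multi-coil synthetic acquisition generator (Shepp-Logan
and blocks phantoms, smooth complex coil maps, correlated Gaussian
noise, noise-only scans), the four Cartesian undersampling mask families
(regular, GRAPPA calibration/reconstruction pair, random with ACS,
equispaced with alternating 4/5-line gaps), reference reconstruction
operators (RSS inverse FFT, zero-filled, GRAPPA, TV-regularized
compressed sensing via ADMM), and reporting tools (anatomy masking,
percentile / cumulative-frequency curves, quartile summaries, ggplot2
`autoplot()` methods). External reconstructions plug in through the
single operator contract `(k-space, mask) → image`.

## Worked example

```r
library(reconqa)

ph   <- make_phantom(48, 48, "shepp_logan")
sens <- make_coil_sensitivities(8, 48, 48)
cov  <- make_noise_covariance(8, 0.2, seed = 7)
ks   <- simulate_acquisition(ph, sens, cov, noise_scale = 0, seed = 1)

gm   <- grappa_masks(48, R = 4, acs_fraction = 0.25)
kern <- grappa_calibrate(apply_mask(ks, gm$calibration),
                         kernel_kx = 5, kernel_sampled_lines = 2, R = 4)

gmap <- gfactor_pipeline(op_grappa(kern), ks, gm$reconstruction, cov,
                         replica_config(250, seed = 5, noise_scale = 0.02))
gmap
#> <gfactor_map R = 4.00, median g 2.783, 0 invalid pixels>

summarize_map(gmap$g, anatomy_mask(rss_ifft_recon(ks)))
#>        q25      q50      q75 frac_above_1 n_valid n_invalid
#> 1 3.434508 4.269631 5.730794            1      1152         0
```

Read: over the anatomy, GRAPPA at R = 4 amplifies noise in essentially
every pixel (median g ≈ 4.3 under these 8-coil synthetic conditions) —
the classical parallel-imaging noise penalty, spatially resolved. The
same pipeline with `op_tv_cs()` instead gives median g far below 1
(denoising), at the price of resolution maps with widths above 1 pixel
in homogeneous regions; the test suite checks exactly these orderings.

A command-line front end wrapping the same functions is installed at
`inst/cli/reconqa.R` (subcommands `simulate`, `mask`, `recon`,
`lpsf-map`, `gfactor`, `cfa`; CSV containers throughout).

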