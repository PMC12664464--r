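# Synthetic multi-coil acquisition generator: numerical phantom, smooth
# complex coil sensitivities, correlated coil noise and a noise-only scan.
# Together these emulate a Cartesian 2D brain acquisition closely enough to
# exercise resolution and g-factor mapping end-to-end with no external data.

# Classic 10-ellipse head phantom parameterization:
# columns: additive intensity, semi-axis a (x), semi-axis b (y),
# center x0, center y0, rotation angle phi (degrees, counter-clockwise).
shepp_logan_ellipses <- function() {
  matrix(c(
     2.00, 0.6900, 0.9200,  0.00,  0.0000,   0,
    -0.98, 0.6624, 0.8740,  0.00, -0.0184,   0,
    -0.02, 0.1100, 0.3100,  0.22,  0.0000, -18,
    -0.02, 0.1600, 0.4100, -0.22,  0.0000,  18,
     0.01, 0.2100, 0.2500,  0.00,  0.3500,   0,
     0.01, 0.0460, 0.0460,  0.00,  0.1000,   0,
     0.01, 0.0460, 0.0460,  0.00, -0.1000,   0,
     0.01, 0.0460, 0.0230, -0.08, -0.6050,   0,
     0.01, 0.0230, 0.0230,  0.00, -0.6060,   0,
     0.01, 0.0230, 0.0460,  0.06, -0.6050,   0),
    ncol = 6, byrow = TRUE,
    dimnames = list(NULL, c("intensity", "a", "b", "x0", "y0", "phi")))
}

#' Pixel-center coordinate grids on [-1, 1]
#'
#' Row index maps to y (down = negative y, as in the usual image display),
#' column index maps to x. Pixel j of n has center (2*j - n - 1)/n.
#' @noRd
pixel_grid <- function(n_rows, n_cols) {
  x <- (2 * seq_len(n_cols) - n_cols - 1) / n_cols
  y <- -(2 * seq_len(n_rows) - n_rows - 1) / n_rows
  list(x = matrix(x, n_rows, n_cols, byrow = TRUE),
       y = matrix(y, n_rows, n_cols))
}

#' Generate a deterministic 2D numerical phantom
#'
#' @param n_rows,n_cols image dimensions in pixels (at least 16 each).
#' @param kind `"shepp_logan"` for the classic 10-ellipse head phantom
#'   rasterized at pixel centers (piecewise smooth, zero outside the
#'   outermost ellipse), or `"blocks"` for a piecewise-constant pattern of
#'   nested rectangles (well suited to total-variation reconstruction
#'   tests).
#' @param phase_ramp if `TRUE`, multiply by a smooth linear phase ramp so
#'   complex handling of downstream operators can be exercised; default
#'   `FALSE` (real non-negative phantom).
#' @return a `phantom_image`: list with `pixels` (complex matrix) and
#'   `spacing` (isotropic, pixel units).
#' @examples
#' ph <- make_phantom(64, 64, "shepp_logan")
#' range(Re(ph$pixels))
#' @export
make_phantom <- function(n_rows, n_cols, kind = c("shepp_logan", "blocks"),
                         phase_ramp = FALSE) {
  kind <- match.arg(kind)
  if (n_rows < 16 || n_cols < 16)
    stop("phantom dimensions must be at least 16 x 16")
  g <- pixel_grid(n_rows, n_cols)
  img <- matrix(0, n_rows, n_cols)
  if (kind == "shepp_logan") {
    ell <- shepp_logan_ellipses()
    for (k in seq_len(nrow(ell))) {
      phi <- ell[k, "phi"] * pi / 180
      dx <- g$x - ell[k, "x0"]
      dy <- g$y - ell[k, "y0"]
      u <- dx * cos(phi) + dy * sin(phi)
      v <- -dx * sin(phi) + dy * cos(phi)
      inside <- (u / ell[k, "a"])^2 + (v / ell[k, "b"])^2 <= 1
      img[inside] <- img[inside] + ell[k, "intensity"]
    }
  } else {
    # nested axis-aligned rectangles on a zero background
    rects <- matrix(c(
      # x_lo, x_hi, y_lo, y_hi, value (added)
      -0.80, 0.80, -0.80, 0.80, 0.60,
      -0.55, 0.20, -0.50, 0.55, 0.50,
       0.30, 0.65, -0.60, 0.00, 0.40,
      -0.35, -0.05, -0.25, 0.30, -0.45,
       0.05, 0.45,  0.25, 0.65, 0.35), ncol = 5, byrow = TRUE)
    for (k in seq_len(nrow(rects))) {
      inside <- g$x >= rects[k, 1] & g$x <= rects[k, 2] &
        g$y >= rects[k, 3] & g$y <= rects[k, 4]
      img[inside] <- img[inside] + rects[k, 5]
    }
  }
  px <- img + 0i
  if (phase_ramp)
    px <- px * exp(1i * pi / 4 * (g$x + 0.5 * g$y))
  structure(list(pixels = px, spacing = 1), class = "phantom_image")
}

#' Generate smooth complex coil-sensitivity maps
#'
#' @param n_coils number of receiver coils (>= 1).
#' @param n_rows,n_cols map dimensions.
#' @param profile `"gaussian_ring"` places the coil centers evenly on a
#'   circle around the field of view, each with a smooth Gaussian magnitude
#'   falloff and a gentle coil-specific linear phase; `"uniform"` returns
#'   all-ones maps (the single-coil limit).
#' @param peak magnitude of each coil map at its own center pixel
#'   (default 1).
#' @return a `coil_sensitivities`: list with `maps`, a complex array
#'   `[coil, row, col]`. The root sum of squares over coils is strictly
#'   positive everywhere (Gaussians never vanish).
#' @export
make_coil_sensitivities <- function(n_coils, n_rows, n_cols,
                                    profile = c("gaussian_ring", "uniform"),
                                    peak = 1) {
  profile <- match.arg(profile)
  if (n_coils < 1) stop("n_coils must be >= 1")
  maps <- array(0i, dim = c(n_coils, n_rows, n_cols))
  if (profile == "uniform") {
    maps[] <- 1 + 0i
  } else {
    g <- pixel_grid(n_rows, n_cols)
    # centers on a circle of radius 0.75 (inside the FOV corners), snapped
    # to the nearest pixel center so the peak is attained exactly there
    sigma <- 0.9
    for (c_ in seq_len(n_coils)) {
      theta <- 2 * pi * (c_ - 1) / n_coils
      cx <- 0.75 * cos(theta)
      cy <- 0.75 * sin(theta)
      jc <- round((cx * n_cols + n_cols + 1) / 2)
      ic <- round((n_rows + 1 - cy * n_rows) / 2)
      jc <- min(max(jc, 1), n_cols)
      ic <- min(max(ic, 1), n_rows)
      cx <- g$x[1, jc]; cy <- g$y[ic, 1]
      d2 <- (g$x - cx)^2 + (g$y - cy)^2
      mag <- peak * exp(-d2 / (2 * sigma^2))
      # smooth coil-specific linear phase, zero at the coil center
      ph <- 0.6 * pi * ((g$x - cx) * cos(theta + pi / 3) +
                          (g$y - cy) * sin(theta + pi / 3))
      maps[c_, , ] <- mag * exp(1i * ph)
    }
  }
  structure(list(maps = maps), class = "coil_sensitivities")
}

#' Construct a coil noise-covariance matrix
#'
#' Builds a Hermitian positive-definite matrix with unit diagonal and
#' nearest-neighbor correlation magnitude `offdiag`, decaying
#' geometrically with coil separation (a complex Kac-Murdock-Szego
#' structure, positive definite for any `0 <= offdiag < 1`). The
#' inter-coil correlation phase is drawn reproducibly from `seed`.
#'
#' @param n_coils number of coils.
#' @param offdiag nearest-neighbor correlation magnitude in `[0, 1)`.
#' @param seed integer seed for the correlation phase.
#' @return a `noise_covariance`: list with `psi`, a complex Hermitian
#'   `n_coils x n_coils` matrix.
#' @export
make_noise_covariance <- function(n_coils, offdiag, seed = 1L) {
  if (offdiag < 0 || offdiag >= 1) stop("offdiag must lie in [0, 1)")
  theta <- if (n_coils > 1) with_seed(seed, stats::runif(1, -pi, pi)) else 0
  idx <- seq_len(n_coils)
  dd <- outer(idx, idx, "-")
  psi <- offdiag^abs(dd) * exp(1i * theta * dd)
  psi <- (psi + Conj(t(psi))) / 2
  ev <- eigen(psi, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    # geometric-decay structure is PD by construction; floor defensively
    floor_ <- 1e-8 * max(ev)
    psi <- psi + diag(floor_ - min(ev), n_coils)
    psi <- psi / max(Re(diag(psi)))
    message("noise covariance eigenvalue floor applied")
  }
  structure(list(psi = psi), class = "noise_covariance")
}

#' Simulate a noise-only acquisition
#'
#' Emulates a calibration scan acquired with no RF excitation: i.i.d.
#' complex Gaussian samples per time point with coil covariance `cov`.
#'
#' @param cov a `noise_covariance`.
#' @param n_samples number of complex samples per coil (>= 2).
#' @param seed integer seed.
#' @return a `noise_samples`: list with `samples`, complex
#'   `[coil, sample]`.
#' @export
simulate_noise_scan <- function(cov, n_samples, seed = 1L) {
  stopifnot(inherits(cov, "noise_covariance"))
  if (n_samples < 2) stop("n_samples must be >= 2")
  nc <- nrow(cov$psi)
  L <- covariance_sqrt(cov)
  z <- with_seed(seed, matrix(rcnorm(nc * n_samples), nc, n_samples))
  structure(list(samples = L %*% z), class = "noise_samples")
}

#' Simulate a multi-coil Cartesian k-space acquisition
#'
#' Coil images are the phantom weighted by the sensitivity maps; each coil
#' image is taken to k-space with the centered orthonormal FFT and
#' correlated complex Gaussian noise (coil covariance `cov`, scaled by
#' `noise_scale`) is added to every k-space sample.
#'
#' @param phantom a `phantom_image`.
#' @param sens a `coil_sensitivities` with matching dimensions.
#' @param cov a `noise_covariance` with matching coil count.
#' @param noise_scale standard-deviation multiplier for the synthetic
#'   noise; 0 gives a noiseless acquisition.
#' @param seed integer seed.
#' @return a `multicoil_kspace`: list with `data`, complex
#'   `[coil, row, col]`, and `mask` (NULL; attached by [apply_mask()]).
#' @export
simulate_acquisition <- function(phantom, sens, cov, noise_scale = 0,
                                 seed = 1L) {
  stopifnot(inherits(phantom, "phantom_image"),
            inherits(sens, "coil_sensitivities"))
  if (noise_scale < 0) stop("noise_scale must be >= 0")
  dm <- dim(sens$maps)
  if (!all(dim(phantom$pixels) == dm[2:3]))
    stop("phantom and sensitivity dimensions disagree")
  ks <- array(0i, dim = dm)
  for (c_ in seq_len(dm[1]))
    ks[c_, , ] <- fft2c(sens$maps[c_, , ] * phantom$pixels)
  if (noise_scale > 0) {
    stopifnot(inherits(cov, "noise_covariance"), nrow(cov$psi) == dm[1])
    ks <- ks + noise_scale * synthesize_noise(cov, dm, seed)
  }
  structure(list(data = ks, mask = NULL), class = "multicoil_kspace")
}

#' Wrap a raw complex array as multi-coil k-space
#' @param data complex array `[coil, row, col]`.
#' @param mask optional `sampling_mask` describing how it was sampled.
#' @export
multicoil_kspace <- function(data, mask = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  structure(list(data = data, mask = mask), class = "multicoil_kspace")
}

#' Coil images for a simulated acquisition (sensitivity-weighted phantom)
#' @noRd
coil_images <- function(phantom, sens) {
  dm <- dim(sens$maps)
  out <- array(0i, dim = dm)
  for (c_ in seq_len(dm[1]))
    out[c_, , ] <- sens$maps[c_, , ] * phantom$pixels
  out
}

#' @export
print.phantom_image <- function(x, ...) {
  cat(sprintf("<phantom_image %d x %d, max |value| %.3g>\n",
              nrow(x$pixels), ncol(x$pixels), max(abs(x$pixels))))
  invisible(x)
}

#' @export
print.multicoil_kspace <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<multicoil_kspace %d coils, %d x %d%s>\n", d[1], d[2], d[3],
              if (is.null(x$mask)) "" else ", masked"))
  invisible(x)
}
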