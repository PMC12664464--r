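# Local point-spread functions. The LPSF of a reconstruction operator T
# at pixel a of object O is the finite difference
#     LPSF(T, O, a) = (T(O + b e_a) - T(O)) / b
# for a small single-pixel perturbation of amplitude b. For linear T it
# reduces to the ordinary (shift-dependent) point-spread function; for
# nonlinear operators it is measured per pixel by reconstructing the
# perturbed and unperturbed data. The width of the main lobe of a 1D
# profile through the LPSF, at 2/pi (~64%) of its peak after Fourier
# interpolation, is the minimal distance at which two points remain
# separable under the Rayleigh criterion; widths above 1 pixel indicate a
# local loss of resolution.

#' Build a single-pixel perturbation matched to the coil signals
#'
#' The perturbation amplitude is `rel_amplitude` times the maximum of the
#' root-sum-of-squares image (default 0.1%, small enough that tested
#' operators respond linearly). Per coil, the amplitude is proportional
#' to that coil's signal at the perturbed pixel and carries the coil's
#' own phase there, so the perturbation is added coherently with the
#' underlying signal; the per-coil amplitudes have joint norm `b`.
#' At zero-signal pixels the perturbation falls back to uniform coil
#' weighting with zero phase.
#'
#' @param coil_imgs complex array `[coil, row, col]` of coil images.
#' @param a pixel `c(row, col)` to perturb.
#' @param rel_amplitude perturbation amplitude relative to the maximum
#'   RSS value (default 0.001).
#' @return a `perturbation`: list with `a`, `b` and complex
#'   `coil_amplitudes`.
#' @export
build_perturbation <- function(coil_imgs, a, rel_amplitude = 0.001) {
  stopifnot(length(dim(coil_imgs)) == 3, length(a) == 2)
  d <- dim(coil_imgs)
  if (a[1] < 1 || a[1] > d[2] || a[2] < 1 || a[2] > d[3])
    stop("perturbation pixel outside the image")
  rss <- matrix(0, d[2], d[3])
  for (c_ in seq_len(d[1])) rss <- rss + abs(coil_imgs[c_, , ])^2
  rss <- sqrt(rss)
  mx <- max(rss)
  if (mx == 0) stop("degenerate input: RSS image is identically zero")
  b <- rel_amplitude * mx
  s <- coil_imgs[, a[1], a[2]]
  rss_a <- sqrt(sum(abs(s)^2))
  amps <- if (rss_a > 1e-12 * mx) b * s / rss_a
          else rep(b / sqrt(d[1]), d[1]) + 0i
  structure(list(a = as.integer(a), b = b, coil_amplitudes = amps),
            class = "perturbation")
}

#' Compute a local point-spread function
#'
#' Adds the perturbation to the coil images at its pixel, transforms both
#' the perturbed and unperturbed coil images to k-space, applies the
#' sampling mask, reconstructs both with the operator, and returns the
#' signed difference divided by the perturbation amplitude.
#'
#' @param op a [recon_operator()] (deterministic, or seeded identically
#'   across the two runs).
#' @param coil_imgs complex array `[coil, row, col]`.
#' @param mask a `sampling_mask` or NULL for full sampling.
#' @param pert a [build_perturbation()] result.
#' @param baseline optional precomputed unperturbed reconstruction (the
#'   per-pixel map loop reuses it; it must come from the same `op`,
#'   `coil_imgs` and `mask`).
#' @return an `lpsf2d`: list with `response` (matrix, signal change per
#'   unit perturbation), `a` and `b`.
#' @export
compute_lpsf <- function(op, coil_imgs, mask, pert, baseline = NULL) {
  stopifnot(inherits(pert, "perturbation"))
  d <- dim(coil_imgs)
  to_kspace <- function(imgs) {
    k <- array(0i, dim = d)
    for (c_ in seq_len(d[1])) k[c_, , ] <- fft2c(imgs[c_, , ])
    ks <- multicoil_kspace(k)
    if (!is.null(mask)) ks <- apply_mask(ks, mask)
    ks
  }
  if (is.null(baseline)) baseline <- op(to_kspace(coil_imgs), mask)
  perturbed <- coil_imgs
  perturbed[, pert$a[1], pert$a[2]] <-
    perturbed[, pert$a[1], pert$a[2]] + pert$coil_amplitudes
  rec1 <- op(to_kspace(perturbed), mask)
  structure(list(response = (rec1 - baseline) / pert$b,
                 a = pert$a, b = pert$b),
            class = "lpsf2d")
}

#' Check local linearity of an operator at a pixel
#'
#' Recomputes the LPSF at several perturbation amplitudes and reports the
#' largest pairwise relative discrepancy; for an operator that responds
#' linearly the LPSF is independent of the amplitude. Should be checked
#' for every new operator and input before trusting resolution maps.
#'
#' @param op,coil_imgs,mask as in [compute_lpsf()].
#' @param a pixel `c(row, col)`.
#' @param amplitudes numeric vector (length >= 2) of relative amplitudes.
#' @param tolerance pass threshold on the relative discrepancy
#'   (default 0.05).
#' @return list with `max_discrepancy`, `pass`, and the amplitudes used.
#' @export
check_linearity <- function(op, coil_imgs, mask, a,
                            amplitudes = c(0.001, 0.0005),
                            tolerance = 0.05) {
  if (length(amplitudes) < 2)
    stop("at least two perturbation amplitudes are required")
  resp <- lapply(amplitudes, function(ra)
    compute_lpsf(op, coil_imgs, mask,
                 build_perturbation(coil_imgs, a, ra))$response)
  worst <- 0
  for (i in seq_along(resp)) for (j in seq_along(resp)) {
    if (i >= j) next
    ref <- max(abs(resp[[j]]))
    worst <- max(worst, max(abs(resp[[i]] - resp[[j]])) / ref)
  }
  list(max_discrepancy = worst, pass = worst <= tolerance,
       amplitudes = amplitudes)
}

#' Extract a 1D profile through an LPSF
#'
#' Takes the row through the perturbed pixel (axis `"horizontal"`: values
#' vary along columns, the phase-encode/undersampled direction) or the
#' column (axis `"vertical"`). Profile values are the magnitude of the
#' response, which is invariant to the global phase ambiguity of
#' magnitude-output reconstructions.
#'
#' @param lpsf an `lpsf2d`.
#' @param axis `"horizontal"` or `"vertical"`.
#' @return a `profile1d`: list with `values`, `center_index` (position of
#'   the perturbed pixel along the profile) and `step` (pixel units per
#'   sample, 1 before interpolation).
#' @export
extract_profile <- function(lpsf, axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  stopifnot(inherits(lpsf, "lpsf2d"))
  v <- if (axis == "horizontal") lpsf$response[lpsf$a[1], ]
       else lpsf$response[, lpsf$a[2]]
  ci <- if (axis == "horizontal") lpsf$a[2] else lpsf$a[1]
  structure(list(values = abs(v), center_index = ci, step = 1),
            class = "profile1d")
}

#' Fourier (zero-padded spectrum) interpolation of a profile
#'
#' Band-limited interpolation: the DFT of the profile is zero-padded to
#' `factor` times its length (splitting the Nyquist bin for even lengths)
#' and transformed back, so original samples are preserved exactly at
#' stride `factor` and the sample step shrinks accordingly.
#'
#' @param p a `profile1d`.
#' @param factor integer interpolation factor >= 1 (default 5).
#' @return a `profile1d` of length `factor * length(p$values)`.
#' @export
fourier_interpolate <- function(p, factor = 5L) {
  stopifnot(inherits(p, "profile1d"), factor >= 1)
  factor <- as.integer(factor)
  if (factor == 1L) return(p)
  n <- length(p$values)
  N <- factor * n
  X <- stats::fft(p$values)
  Y <- complex(real = rep(0, N))
  h <- floor(n / 2)
  Y[1:(h + 1)] <- X[1:(h + 1)]
  if (n > 1) Y[(N - (n - h - 1) + 1):N] <- X[(h + 2):n]
  if (n %% 2 == 0) {
    # split the Nyquist bin so real inputs stay real and original
    # samples are reproduced exactly
    Y[h + 1] <- X[h + 1] / 2
    Y[N - h + 1] <- X[h + 1] / 2
  }
  vals <- Re(stats::fft(Y, inverse = TRUE)) / n
  structure(list(values = vals,
                 center_index = (p$center_index - 1) * factor + 1,
                 step = p$step / factor),
            class = "profile1d")
}

#' Width of the main lobe of a profile at a fractional threshold
#'
#' The peak is the largest profile value within a search window of a
#' quarter of the (original-units) profile length around the center,
#' which prevents locking onto far-field response lobes. The width is
#' the distance, in original pixel units, between the first crossings
#' below `threshold * peak` on each side of the peak, refined by linear
#' interpolation between samples. Returns `NaN` when a side never
#' crosses the threshold.
#'
#' @param p a `profile1d` (typically after [fourier_interpolate()]).
#' @param threshold fraction of the peak (default `2/pi`, the level at
#'   which a one-pixel separation of two band-limited points is exactly
#'   resolvable; 64% and 65% are common rounded statements).
#' @return main-lobe width in pixel units, or `NaN`.
#' @export
mainlobe_width <- function(p, threshold = 2 / pi) {
  stopifnot(inherits(p, "profile1d"), threshold > 0, threshold < 1)
  v <- p$values
  n <- length(v)
  if (all(v == 0)) return(NaN)
  halfwin <- max(1L, floor(n / 4))
  lo <- max(1L, p$center_index - halfwin)
  hi <- min(n, p$center_index + halfwin)
  pk_i <- lo + which.max(v[lo:hi]) - 1L
  pk <- v[pk_i]
  if (pk <= 0) return(NaN)
  thr <- threshold * pk
  cross <- function(idx_seq) {
    prev <- pk_i
    for (i in idx_seq) {
      if (v[i] < thr) {
        # linear interpolation between the last sample above and this one
        frac <- (v[prev] - thr) / (v[prev] - v[i])
        return(abs(prev - pk_i) + frac * abs(i - prev))
      }
      prev <- i
    }
    NA_real_
  }
  left <- if (pk_i > 1) cross((pk_i - 1):1) else NA_real_
  right <- if (pk_i < n) cross((pk_i + 1):n) else NA_real_
  if (is.na(left) || is.na(right)) return(NaN)
  (left + right) * p$step
}

#' Per-pixel directional resolution map
#'
#' For each requested pixel: compute the LPSF, extract the directional
#' profile, Fourier-interpolate it, and measure the main-lobe width.
#' Results are independent of the evaluation order; per-pixel failures
#' are flagged in `invalid` rather than aborting the map.
#'
#' @param op a [recon_operator()].
#' @param coil_imgs complex array `[coil, row, col]`.
#' @param mask a `sampling_mask` or NULL.
#' @param axis `"horizontal"` (undersampled direction) or `"vertical"`.
#' @param pixels logical matrix selecting pixels, or NULL for the default
#'   anatomy mask of the RSS image (see [anatomy_mask()]).
#' @param rel_amplitude perturbation amplitude (default 0.001).
#' @param interp_factor Fourier interpolation factor (default 5).
#' @param threshold width threshold (default `2/pi`).
#' @param progress message every `progress` pixels (0 = silent).
#' @return a `resolution_map`: list with `widths` (matrix, NA where not
#'   evaluated), `invalid` (logical matrix: evaluated but undefined),
#'   `axis`.
#' @export
resolution_map <- function(op, coil_imgs, mask,
                           axis = c("horizontal", "vertical"),
                           pixels = NULL, rel_amplitude = 0.001,
                           interp_factor = 5L, threshold = 2 / pi,
                           progress = 0) {
  axis <- match.arg(axis)
  d <- dim(coil_imgs)
  if (is.null(pixels)) {
    rss <- matrix(0, d[2], d[3])
    for (c_ in seq_len(d[1])) rss <- rss + abs(coil_imgs[c_, , ])^2
    pixels <- anatomy_mask(sqrt(rss))
  }
  stopifnot(is.logical(pixels), all(dim(pixels) == d[2:3]))
  to_kspace <- function(imgs) {
    k <- array(0i, dim = d)
    for (c_ in seq_len(d[1])) k[c_, , ] <- fft2c(imgs[c_, , ])
    ks <- multicoil_kspace(k)
    if (!is.null(mask)) ks <- apply_mask(ks, mask)
    ks
  }
  baseline <- op(to_kspace(coil_imgs), mask)
  widths <- matrix(NA_real_, d[2], d[3])
  invalid <- matrix(FALSE, d[2], d[3])
  todo <- which(pixels, arr.ind = TRUE)
  for (k in seq_len(nrow(todo))) {
    a <- todo[k, ]
    w <- tryCatch({
      pert <- build_perturbation(coil_imgs, a, rel_amplitude)
      l <- compute_lpsf(op, coil_imgs, mask, pert, baseline = baseline)
      prof <- fourier_interpolate(extract_profile(l, axis), interp_factor)
      mainlobe_width(prof, threshold)
    }, error = function(e) NaN)
    if (is.nan(w)) invalid[a[1], a[2]] <- TRUE else widths[a[1], a[2]] <- w
    if (progress > 0 && k %% progress == 0)
      message(sprintf("resolution_map: %d / %d pixels", k, nrow(todo)))
  }
  structure(list(widths = widths, invalid = invalid, axis = axis),
            class = "resolution_map")
}

#' @export
print.resolution_map <- function(x, ...) {
  w <- x$widths[!is.na(x$widths)]
  cat(sprintf(
    "<resolution_map (%s) %d pixels, median width %.3f, %d invalid>\n",
    x$axis, length(w), stats::median(w), sum(x$invalid)))
  invisible(x)
}
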