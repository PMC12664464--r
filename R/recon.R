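# Reconstruction-operator contract and the direct reference operators.
# A reconstruction operator is a function (multicoil_kspace, sampling_mask
# or NULL) -> real non-negative matrix (magnitude image), tagged with a
# name and a determinism flag so the mapping machinery can schedule it.

#' Wrap a function as a reconstruction operator
#'
#' @param fn function of `(kspace, mask)` returning a real, non-negative
#'   matrix with the slice dimensions of the input.
#' @param name short display name.
#' @param deterministic `TRUE` if repeated calls on identical input give
#'   identical output (required by the LPSF and replica machinery unless
#'   the caller seeds the operator).
#' @return a `recon_operator` (a classed function).
#' @export
recon_operator <- function(fn, name, deterministic = TRUE) {
  stopifnot(is.function(fn))
  structure(fn, name = name, deterministic = deterministic,
            class = c("recon_operator", "function"))
}

#' @export
print.recon_operator <- function(x, ...) {
  cat(sprintf("<recon_operator '%s'%s>\n", attr(x, "name"),
              if (attr(x, "deterministic")) "" else " (stochastic)"))
  invisible(x)
}

#' Root-sum-of-squares inverse-FFT reconstruction
#'
#' The direct reconstruction of fully sampled data: per-coil centered
#' orthonormal inverse FFT followed by the pixel-wise root sum of squares
#' over coils. Any attached mask is ignored (the data are used as given).
#'
#' @param kspace a `multicoil_kspace`.
#' @return real non-negative matrix (magnitude image).
#' @export
rss_ifft_recon <- function(kspace) {
  stopifnot(inherits(kspace, "multicoil_kspace"))
  d <- dim(kspace$data)
  acc <- matrix(0, d[2], d[3])
  for (c_ in seq_len(d[1]))
    acc <- acc + abs(ifft2c(kspace$data[c_, , ]))^2
  sqrt(acc)
}

#' Zero-filled reconstruction
#'
#' Applies the sampling mask (zeroing unacquired lines) and reconstructs
#' directly with [rss_ifft_recon()]; the baseline showing raw aliasing.
#'
#' @param kspace a `multicoil_kspace`.
#' @param mask a `sampling_mask` (NULL leaves the data untouched).
#' @return real non-negative matrix.
#' @export
zero_filled_recon <- function(kspace, mask = NULL) {
  if (!is.null(mask)) kspace <- apply_mask(kspace, mask)
  rss_ifft_recon(kspace)
}

#' @rdname rss_ifft_recon
#' @export
op_rss <- function() {
  recon_operator(function(kspace, mask = NULL) rss_ifft_recon(kspace),
                 name = "rss_ifft")
}

#' @rdname zero_filled_recon
#' @export
op_zero_filled <- function() {
  recon_operator(function(kspace, mask = NULL) zero_filled_recon(kspace, mask),
                 name = "zero_filled")
}

#' Rescale an image to best match a reference in least squares
#'
#' Reconstruction outputs are scaled arbitrarily; before computing error
#' maps against a reference the image is multiplied by the scalar
#' `a = <image, reference> / <image, image>` minimizing the l2 difference.
#'
#' @param image,reference real matrices of equal shape; `image` must not
#'   be identically zero.
#' @return `a * image`.
#' @export
rescale_to_reference <- function(image, reference) {
  stopifnot(all(dim(image) == dim(reference)))
  ss <- sum(image * image)
  if (ss == 0) stop("cannot rescale an identically zero image")
  (sum(image * reference) / ss) * image
}

#' Linear matched-filter coil combination
#'
#' The conjugate-sensitivity-weighted sum of the per-coil inverse FFTs,
#' returning the signed real part. Unlike the magnitude-output
#' operators this map is exactly linear in the complex k-space data,
#' which makes it the reference operator for linearity diagnostics
#' (LPSF amplitude scaling, object-independence) where the magnitude
#' nonlinearity would otherwise contribute O(b/signal) deviations.
#'
#' @param sens a `coil_sensitivities` (ideally unit-RSS maps).
#' @return a [recon_operator()].
#' @export
op_matched_filter <- function(sens) {
  recon_operator(function(kspace, mask = NULL) {
    d <- dim(kspace$data)
    out <- matrix(0i, d[2], d[3])
    for (c_ in seq_len(d[1]))
      out <- out + Conj(sens$maps[c_, , ]) * ifft2c(kspace$data[c_, , ])
    Re(out)
  }, name = "matched_filter")
}
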