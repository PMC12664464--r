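#' @keywords internal
"_PACKAGE"

#' Circularly shift a matrix so the DC sample moves to the array center
#'
#' Standard fftshift: element (1,1) of the unshifted spectrum (the DC
#' component of `stats::fft`) ends up at `(floor(n/2)+1, floor(m/2)+1)`.
#'
#' @param x a matrix.
#' @return a matrix of the same shape.
#' @keywords internal
#' @noRd
fftshift2 <- function(x) {
  n <- nrow(x); m <- ncol(x)
  ir <- c(seq_len(ceiling(n / 2)) + floor(n / 2), seq_len(floor(n / 2)))
  ic <- c(seq_len(ceiling(m / 2)) + floor(m / 2), seq_len(floor(m / 2)))
  x[order(ir), order(ic), drop = FALSE]
}

#' @noRd
ifftshift2 <- function(x) {
  n <- nrow(x); m <- ncol(x)
  ir <- c(seq_len(floor(n / 2)) + ceiling(n / 2), seq_len(ceiling(n / 2)))
  ic <- c(seq_len(floor(m / 2)) + ceiling(m / 2), seq_len(ceiling(m / 2)))
  x[order(ir), order(ic), drop = FALSE]
}

#' Centered orthonormal 2D Fourier transforms
#'
#' The project-wide Fourier convention: the DC sample sits at the array
#' center (`floor(n/2)+1` along each axis) in both domains, and the
#' transform is unitary (scaled by `1/sqrt(n*m)`), so white noise keeps its
#' variance between image space and k-space.
#'
#' @param x complex (or real) matrix, an image or a k-space slice.
#' @return complex matrix of the same shape.
#' @export
fft2c <- function(x) {
  fftshift2(stats::fft(ifftshift2(x))) / sqrt(length(x))
}

#' @rdname fft2c
#' @export
ifft2c <- function(x) {
  fftshift2(stats::fft(ifftshift2(x), inverse = TRUE)) / sqrt(length(x))
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so library internals never disturb the
#' caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a deterministic stream of sub-seeds from a base seed
#'
#' Used to give every pseudo-replica (and every arm of the g-factor
#' pipeline) an independent, reproducible RNG stream.
#' @noRd
spawn_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Standard complex Gaussian deviates
#'
#' Unit-variance complex noise: variance 1/2 in each of the real and
#' imaginary components, so `E|z|^2 = 1`.
#' @noRd
rcnorm <- function(n) {
  complex(real = stats::rnorm(n, sd = sqrt(0.5)),
          imaginary = stats::rnorm(n, sd = sqrt(0.5)))
}

#' @noRd
nrmse <- function(x, ref) {
  sqrt(sum(abs(x - ref)^2) / sum(abs(ref)^2))
}
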