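# Plain-text serialization of acquisitions: a long-format CSV table for
# complex k-space (one row per coil/row/col sample), a companion CSV for
# the noise-only scan, and CSV matrices for covariances.

#' Write a simulated acquisition to a CSV container
#'
#' Writes `<path>` with columns `coil,row,col,re,im` for the k-space data
#' and, when `noise` is given, `<path base>_noise.csv` with columns
#' `coil,sample,re,im`.
#'
#' @param kspace a `multicoil_kspace`.
#' @param path output CSV path.
#' @param noise optional `noise_samples` from the same session.
#' @return `path`, invisibly.
#' @export
write_kspace_csv <- function(kspace, path, noise = NULL) {
  stopifnot(inherits(kspace, "multicoil_kspace"))
  d <- dim(kspace$data)
  idx <- expand.grid(coil = seq_len(d[1]), row = seq_len(d[2]),
                     col = seq_len(d[3]))
  v <- as.vector(kspace$data)
  utils::write.csv(cbind(idx, re = Re(v), im = Im(v)), path,
                   row.names = FALSE)
  if (!is.null(noise)) {
    stopifnot(inherits(noise, "noise_samples"))
    np <- sub("\\.csv$", "_noise.csv", path)
    dn <- dim(noise$samples)
    idx <- expand.grid(coil = seq_len(dn[1]), sample = seq_len(dn[2]))
    v <- as.vector(noise$samples)
    utils::write.csv(cbind(idx, re = Re(v), im = Im(v)), np,
                     row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_kspace_csv
#' @export
read_kspace_csv <- function(path) {
  d <- utils::read.csv(path)
  dims <- c(max(d$coil), max(d$row), max(d$col))
  arr <- array(0i, dim = dims)
  arr[cbind(d$coil, d$row, d$col)] <- complex(real = d$re, imaginary = d$im)
  multicoil_kspace(arr)
}

#' @rdname write_kspace_csv
#' @export
read_noise_csv <- function(path) {
  d <- utils::read.csv(path)
  m <- matrix(0i, max(d$coil), max(d$sample))
  m[cbind(d$coil, d$sample)] <- complex(real = d$re, imaginary = d$im)
  structure(list(samples = m), class = "noise_samples")
}

#' Write / read a noise covariance as a CSV matrix (re and im blocks)
#'
#' The complex matrix is stored as two stacked real blocks: rows `1..n`
#' hold the real part, rows `n+1..2n` the imaginary part.
#' @param cov a `noise_covariance`.
#' @param path file path.
#' @export
write_covariance_csv <- function(cov, path) {
  stopifnot(inherits(cov, "noise_covariance"))
  m <- rbind(Re(cov$psi), Im(cov$psi))
  utils::write.table(m, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_covariance_csv
#' @export
read_covariance_csv <- function(path) {
  m <- unname(as.matrix(utils::read.table(path, sep = ",")))
  n <- nrow(m) / 2
  structure(list(psi = m[1:n, , drop = FALSE] +
                   1i * m[(n + 1):(2 * n), , drop = FALSE]),
            class = "noise_covariance")
}
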