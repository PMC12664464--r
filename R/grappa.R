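# GRAPPA parallel-imaging reconstruction. Missing phase-encode lines
# (k-space columns) are interpolated per coil by a convolution kernel in
# k-space, calibrated by least squares on the fully sampled ACS band.
# Geometry: kernel_sampled_lines acquired columns spaced R apart times
# kernel_kx readout-row neighbors, over all source coils; boundary
# handling is circular in both k-space axes.

#' GRAPPA kernel geometry: source offsets
#'
#' Column multipliers place the missing target between the two central
#' source lines; row offsets are centered on the target row.
#' @noRd
grappa_geometry <- function(kernel_kx, kernel_sampled_lines, R) {
  if (kernel_kx %% 2 != 1) stop("kernel_kx must be odd")
  if (kernel_sampled_lines < 1) stop("kernel_sampled_lines must be >= 1")
  list(mult = seq_len(kernel_sampled_lines) -
         floor(kernel_sampled_lines / 2),  # e.g. 4 lines -> -1,0,1,2
       dxs = seq_len(kernel_kx) - (kernel_kx + 1) / 2)
}

circ_index <- function(i, n) ((i - 1) %% n) + 1L

#' Feature matrix for one base column: all rows at once
#'
#' Rows of the returned matrix index k-space rows; columns index features
#' ordered with source coil fastest, then source line (column multiplier),
#' then readout offset.
#' @noRd
grappa_features <- function(data, base_col, geom, R) {
  d <- dim(data)
  n_rows <- d[2]; n_cols <- d[3]
  cols <- circ_index(base_col + geom$mult * R, n_cols)
  nfeat <- d[1] * length(geom$mult) * length(geom$dxs)
  A <- matrix(0i, n_rows, nfeat)
  f <- 1L
  for (dx in geom$dxs) {
    ridx <- circ_index(seq_len(n_rows) + dx, n_rows)
    for (j in seq_along(cols)) {
      for (c_ in seq_len(d[1])) {
        A[, f] <- data[c_, ridx, cols[j]]
        f <- f + 1L
      }
    }
  }
  A
}

#' Calibrate a GRAPPA kernel on autocalibration data
#'
#' Fits, for every missing-line offset `1..R-1` and every target coil, the
#' complex weights expressing the missing sample as a linear combination
#' of `kernel_sampled_lines x kernel_kx` acquired neighbors over all
#' coils, by Tikhonov-regularized least squares over the ACS band.
#'
#' @param calib a `multicoil_kspace` holding calibration data. If a mask
#'   is attached, its sampled columns define the calibration band;
#'   otherwise every column is used.
#' @param kernel_kx odd number of readout-direction neighbors (default 5).
#' @param kernel_sampled_lines number of acquired lines feeding each
#'   interpolated sample (default 4).
#' @param R acceleration factor of the mask the kernel will be applied to.
#' @param tikhonov regularization weight, scaled by the mean diagonal of
#'   the normal matrix (default 1e-4).
#' @param base_stride stride between successive base columns of the
#'   sliding calibration placements. The default 1 uses every position in
#'   the calibration band (all lattice phases, the usual choice for a
#'   fully sampled ACS); `R` restricts placements to a single lattice
#'   phase anchored at the first valid base, which is exact when the
#'   calibration data itself lies on the acquisition lattice.
#' @return a `grappa_kernel`: per-offset weight matrices `[feature,
#'   target coil]`, plus the geometry. Feature index runs over source
#'   coil (fastest), then source line, then readout offset.
#' @export
grappa_calibrate <- function(calib, kernel_kx = 5, kernel_sampled_lines = 4,
                             R = 4, tikhonov = 1e-4, base_stride = 1L) {
  stopifnot(inherits(calib, "multicoil_kspace"))
  geom <- grappa_geometry(kernel_kx, kernel_sampled_lines, R)
  d <- dim(calib$data)
  avail <- if (!is.null(calib$mask)) which(calib$mask$sampled)
           else seq_len(d[3])
  span <- (max(geom$mult) - min(geom$mult)) * R
  if (length(avail) < span + 1)
    stop("ACS band narrower than the kernel extent")
  weights <- vector("list", R - 1)
  for (o in seq_len(R - 1)) {
    bases <- avail
    if (base_stride > 1) {
      ok <- vapply(avail, function(b)
        all((b + geom$mult * R) %in% avail) && (b + o) %in% avail,
        logical(1))
      if (any(ok))
        bases <- avail[ok][seq(1, sum(ok), by = base_stride)]
    }
    A_list <- list(); B_list <- list()
    for (b in bases) {
      src <- b + geom$mult * R
      tgt <- b + o
      if (all(src %in% avail) && tgt %in% avail) {
        A_list[[length(A_list) + 1L]] <- grappa_features(calib$data, b, geom, R)
        B_list[[length(B_list) + 1L]] <-
          t(matrix(calib$data[, , tgt], nrow = d[1]))
      }
    }
    if (!length(A_list))
      stop("ACS band too small: no complete kernel placements for offset ", o)
    A <- do.call(rbind, A_list)
    B <- do.call(rbind, B_list)
    AhA <- Conj(t(A)) %*% A
    AhB <- Conj(t(A)) %*% B
    lam <- tikhonov * mean(Re(diag(AhA)))
    w <- NULL
    repeat {
      w <- tryCatch(solve(AhA + diag(lam, ncol(A)), AhB),
                    error = function(e) NULL)
      if (!is.null(w)) break
      lam <- max(lam, 1e-12 * mean(Re(diag(AhA)))) * 100
      warning("singular calibration system; regularization increased to ",
              signif(lam, 3))
    }
    weights[[o]] <- w
  }
  structure(list(weights = weights, kernel_kx = kernel_kx,
                 kernel_sampled_lines = kernel_sampled_lines, R = R),
            class = "grappa_kernel")
}

#' Reconstruct undersampled k-space with a calibrated GRAPPA kernel
#'
#' Fills every missing phase-encode line from its acquired neighbors by
#' the kernel (circular boundaries in both axes), keeps acquired lines
#' verbatim, and returns the RSS inverse-FFT image.
#'
#' @param undersampled a `multicoil_kspace` (already masked).
#' @param mask the regular `sampling_mask` used, spacing equal to the
#'   kernel's `R`.
#' @param kernel a `grappa_kernel` from [grappa_calibrate()].
#' @return real non-negative matrix (magnitude image).
#' @export
grappa_reconstruct <- function(undersampled, mask, kernel) {
  stopifnot(inherits(undersampled, "multicoil_kspace"),
            inherits(mask, "sampling_mask"),
            inherits(kernel, "grappa_kernel"))
  d <- dim(undersampled$data)
  n_cols <- d[3]
  sc <- which(mask$sampled)
  R <- kernel$R
  if (length(sc) > 1 && !all(diff(sc) == R))
    stop("mask is not regular with the kernel's acceleration R = ", R)
  if (n_cols %% R != 0)
    warning("number of lines not divisible by R; circular wrap crosses ",
            "a non-uniform gap")
  geom <- grappa_geometry(kernel$kernel_kx, kernel$kernel_sampled_lines, R)
  filled <- undersampled$data
  for (b in sc) {
    A <- NULL
    for (o in seq_len(R - 1)) {
      tgt <- circ_index(b + o, n_cols)
      if (mask$sampled[tgt]) next  # acquired lines kept verbatim
      if (is.null(A)) A <- grappa_features(undersampled$data, b, geom, R)
      filled[, , tgt] <- t(A %*% kernel$weights[[o]])
    }
  }
  rss_ifft_recon(multicoil_kspace(filled))
}

#' @rdname grappa_reconstruct
#' @param ... passed to the underlying reconstruction.
#' @export
op_grappa <- function(kernel, ...) {
  recon_operator(function(kspace, mask)
    grappa_reconstruct(kspace, mask, kernel, ...),
    name = "grappa")
}

#' @export
print.grappa_kernel <- function(x, ...) {
  cat(sprintf("<grappa_kernel R = %d, %d x %d neighborhood, %d offsets>\n",
              x$R, x$kernel_sampled_lines, x$kernel_kx,
              length(x$weights)))
  invisible(x)
}
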