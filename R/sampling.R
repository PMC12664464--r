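# Cartesian undersampling along the phase-encode direction. Phase-encode
# lines are k-space COLUMNS (undersampling aliases along the horizontal
# image direction); the row (readout) direction is always fully sampled.

round_half_up <- function(x) floor(x + 0.5)

#' Construct a sampling mask object
#'
#' @param sampled logical vector over phase-encode lines (columns).
#' @param acs integer vector `c(first, last)` of the autocalibration (ACS)
#'   line range (1-based, inclusive), or `NULL` if no ACS region.
#' @param nominal_R the nominal acceleration the pattern was built for.
#' @return a `sampling_mask`.
#' @export
sampling_mask <- function(sampled, acs = NULL, nominal_R = 1) {
  stopifnot(is.logical(sampled), length(sampled) >= 1)
  if (!any(sampled)) stop("a sampling mask must sample at least one line")
  if (!is.null(acs)) {
    stopifnot(length(acs) == 2, acs[1] >= 1, acs[2] <= length(sampled))
    if (!all(sampled[acs[1]:acs[2]]))
      stop("ACS lines must all be sampled")
  }
  structure(list(sampled = sampled, acs = acs, nominal_R = nominal_R),
            class = "sampling_mask")
}

#' Centered autocalibration line range
#'
#' The fully sampled central band covers `round(acs_fraction * n_lines)`
#' lines centered in k-space; when that count is odd the extra line is
#' placed on the low-index side.
#'
#' @param n_lines number of phase-encode lines.
#' @param acs_fraction fraction of lines in the ACS band, in (0, 1).
#' @return integer vector `c(first, last)` (1-based, inclusive).
#' @export
acs_range <- function(n_lines, acs_fraction) {
  if (acs_fraction <= 0 || acs_fraction >= 1)
    stop("acs_fraction must lie in (0, 1)")
  w <- as.integer(round_half_up(acs_fraction * n_lines))
  if (w < 1) stop("ACS width rounds to zero lines")
  first <- as.integer(floor((n_lines - w) / 2)) + 1L
  c(first, first + w - 1L)
}

#' Regular (equispaced) undersampling mask
#'
#' Samples lines `1, 1+R, 1+2R, ...` with no ACS region.
#' @param n_lines number of phase-encode lines.
#' @param R integer acceleration factor.
#' @return a `sampling_mask`.
#' @export
regular_mask <- function(n_lines, R) {
  if (R < 1) stop("R must be >= 1")
  if (R > n_lines) stop("R exceeds the number of lines")
  s <- rep(FALSE, n_lines)
  s[seq(1L, n_lines, by = R)] <- TRUE
  sampling_mask(s, acs = NULL, nominal_R = R)
}

#' GRAPPA calibration/reconstruction mask pair
#'
#' The kernel is calibrated on the fully sampled central ACS band alone;
#' the reconstruction is then applied to a purely regular mask with no ACS
#' lines added, so the effective acceleration of the reconstructed data is
#' exactly `R` (when `R` divides `n_lines`).
#'
#' @inheritParams regular_mask
#' @param acs_fraction fraction of lines in the calibration band.
#' @return list with elements `calibration` and `reconstruction`, both
#'   `sampling_mask` objects.
#' @export
grappa_masks <- function(n_lines, R, acs_fraction = 0.08) {
  acs <- acs_range(n_lines, acs_fraction)
  cal <- rep(FALSE, n_lines)
  cal[acs[1]:acs[2]] <- TRUE
  list(calibration = sampling_mask(cal, acs = acs, nominal_R = 1),
       reconstruction = regular_mask(n_lines, R))
}

#' Random undersampling mask with ACS region
#'
#' All ACS lines are sampled; the remaining budget (total sampled =
#' `round(n_lines / R)`) is drawn uniformly without replacement from the
#' non-ACS lines, reproducibly from `seed`.
#'
#' @inheritParams grappa_masks
#' @param seed integer seed.
#' @return a `sampling_mask`.
#' @export
random_mask <- function(n_lines, R, acs_fraction = 0.08, seed = 1L) {
  acs <- acs_range(n_lines, acs_fraction)
  target <- round_half_up(n_lines / R)
  n_acs <- acs[2] - acs[1] + 1L
  extra <- target - n_acs
  if (extra < 0) stop("ACS region alone exceeds the sampling budget")
  pool <- setdiff(seq_len(n_lines), acs[1]:acs[2])
  if (extra > length(pool)) stop("sampling budget infeasible")
  s <- rep(FALSE, n_lines)
  s[acs[1]:acs[2]] <- TRUE
  s[with_seed(seed, sample(pool, extra))] <- TRUE
  sampling_mask(s, acs = acs, nominal_R = R)
}

#' Equispaced mask with alternating gaps and ACS region
#'
#' Outside the ACS band, sampled lines alternate between gaps of 4 and 5
#' missing lines (strides +5, +6), anchored at line 1, so the base pattern
#' averages acceleration 5.5 and the added ACS band brings the overall
#' density near R = 4. This mirrors the pattern data-driven fastMRI-style
#' reconstructions are trained on.
#'
#' @param n_lines number of phase-encode lines (>= 12).
#' @param acs_fraction fraction of lines in the ACS band; 0 disables it.
#' @return a `sampling_mask`.
#' @export
equispaced_alternating_mask <- function(n_lines, acs_fraction = 0.08) {
  if (n_lines < 12) stop("n_lines must be >= 12")
  s <- rep(FALSE, n_lines)
  pos <- 1L
  stride <- 5L
  while (pos <= n_lines) {
    s[pos] <- TRUE
    pos <- pos + stride
    stride <- if (stride == 5L) 6L else 5L
  }
  acs <- NULL
  if (acs_fraction > 0) {
    acs <- acs_range(n_lines, acs_fraction)
    s[acs[1]:acs[2]] <- TRUE
  }
  sampling_mask(s, acs = acs, nominal_R = 4)
}

#' Zero out unsampled phase-encode lines
#'
#' @param kspace a `multicoil_kspace`.
#' @param mask a `sampling_mask` whose length equals the number of
#'   k-space columns.
#' @return a `multicoil_kspace` with unsampled columns zeroed in every
#'   coil and the mask attached.
#' @export
apply_mask <- function(kspace, mask) {
  stopifnot(inherits(kspace, "multicoil_kspace"),
            inherits(mask, "sampling_mask"))
  if (length(mask$sampled) != dim(kspace$data)[3])
    stop("mask length must equal the number of phase-encode lines (columns)")
  out <- kspace$data
  out[, , !mask$sampled] <- 0i
  multicoil_kspace(out, mask = mask)
}

#' Effective acceleration of a mask
#'
#' Total lines divided by sampled lines.
#' @param mask a `sampling_mask`.
#' @return a single number.
#' @export
effective_acceleration <- function(mask) {
  stopifnot(inherits(mask, "sampling_mask"))
  length(mask$sampled) / sum(mask$sampled)
}

#' @export
print.sampling_mask <- function(x, ...) {
  cat(sprintf(
    "<sampling_mask %d lines, %d sampled (R_eff = %.2f)%s>\n",
    length(x$sampled), sum(x$sampled), effective_acceleration(x),
    if (is.null(x$acs)) "" else
      sprintf(", ACS %d..%d", x$acs[1], x$acs[2])))
  invisible(x)
}

#' Write / read a mask as a one-column CSV of 0/1 per line
#' @param mask a `sampling_mask`.
#' @param path file path.
#' @export
write_mask_csv <- function(mask, path) {
  utils::write.csv(data.frame(sampled = as.integer(mask$sampled)),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mask_csv
#' @export
read_mask_csv <- function(path) {
  d <- utils::read.csv(path)
  sampling_mask(d$sampled != 0)
}
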