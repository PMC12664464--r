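# Pseudo multiple-replica noise analysis. Repeated synthetic-noise
# realizations, colored by the measured coil covariance, are added to the
# k-space data; the per-pixel standard deviation of the resulting
# reconstructions for an accelerated arm and a directly reconstructed
# fully sampled arm gives the g-factor map
#     g(x, y) = sigma_acc(x, y) / (sigma_normal(x, y) * sqrt(R)),
# the noise amplification beyond the unavoidable sqrt(R) penalty of the
# shortened acquisition.

#' Estimate the coil noise covariance from a noise-only scan
#'
#' The estimator is `Psi[i, j] = (1/n) * sum_k N[i, k] * Conj(N[j, k])`,
#' i.e. the raw second moment without mean subtraction (receiver noise is
#' zero-mean by construction); Hermitian by construction.
#'
#' @param noise a `noise_samples` (complex `[coil, sample]`, n >= 2).
#' @param mean_subtract subtract the per-coil sample mean first
#'   (default FALSE, the raw-moment form).
#' @return a `noise_covariance`.
#' @export
estimate_noise_covariance <- function(noise, mean_subtract = FALSE) {
  stopifnot(inherits(noise, "noise_samples"))
  N <- noise$samples
  n <- ncol(N)
  if (n < 2) stop("at least two noise samples are required")
  if (mean_subtract) N <- N - rowMeans(N)
  psi <- (N %*% Conj(t(N))) / n
  psi <- (psi + Conj(t(psi))) / 2
  structure(list(psi = psi), class = "noise_covariance")
}

#' Matrix square root of a noise covariance (complex Cholesky)
#'
#' Returns the lower-triangular factor `L` with `L %*% Conj(t(L)) == psi`.
#' Any factor `B` with `B B^H = Psi` produces the same noise law; the
#' Cholesky factor is used for its determinism and cost.
#'
#' @param cov a `noise_covariance` (Hermitian positive semi-definite).
#' @return complex lower-triangular matrix.
#' @export
covariance_sqrt <- function(cov) {
  stopifnot(inherits(cov, "noise_covariance"))
  psi <- cov$psi
  n <- nrow(psi)
  tol <- 1e-12 * max(Re(diag(psi)), 1e-300)
  L <- matrix(0i, n, n)
  for (j in seq_len(n)) {
    s <- Re(psi[j, j]) - sum(abs(L[j, seq_len(j - 1)])^2)
    if (s < -tol) {
      ev <- eigen(psi, symmetric = TRUE, only.values = TRUE)$values
      stop(sprintf("covariance not positive semi-definite (min eigenvalue %.3g)",
                   min(ev)))
    }
    L[j, j] <- sqrt(max(s, 0))
    if (j < n) {
      for (i in (j + 1):n) {
        acc <- psi[i, j]
        if (j > 1) acc <- acc - sum(L[i, 1:(j - 1)] * Conj(L[j, 1:(j - 1)]))
        L[i, j] <- if (Re(L[j, j]) > 0) acc / L[j, j] else 0i
      }
    }
  }
  L
}

#' Synthesize correlated complex Gaussian coil noise
#'
#' Draws i.i.d. standard complex Gaussian deviates (variance 1/2 per
#' real/imaginary component) for every coil and sample and mixes them
#' with the Cholesky factor of the covariance, reproducibly from `seed`.
#'
#' @param cov a `noise_covariance`.
#' @param shape integer dims, first entry = coil count (e.g.
#'   `dim(kspace$data)`), or a sample count for a `[coil, n]` matrix.
#' @param seed integer seed.
#' @return complex array of dimension `shape`.
#' @export
synthesize_noise <- function(cov, shape, seed = 1L) {
  stopifnot(inherits(cov, "noise_covariance"))
  nc <- nrow(cov$psi)
  if (length(shape) == 1) shape <- c(nc, shape)
  stopifnot(shape[1] == nc)
  L <- covariance_sqrt(cov)
  n_other <- prod(shape[-1])
  z <- with_seed(seed, matrix(rcnorm(nc * n_other), nc, n_other))
  array(L %*% z, dim = shape)
}

#' Replica-ensemble configuration
#'
#' @param n_replicas number of pseudo-replicas (default 1000).
#' @param seed base seed; per-replica streams are derived from it.
#' @param noise_scale standard-deviation multiplier of the added noise.
#' @export
replica_config <- function(n_replicas = 1000, seed = 1L, noise_scale = 1) {
  stopifnot(n_replicas >= 2, noise_scale >= 0)
  structure(list(n_replicas = as.integer(n_replicas), seed = seed,
                 noise_scale = noise_scale), class = "replica_config")
}

#' Per-pixel standard deviation over pseudo-replicas
#'
#' For each replica, fresh synthetic noise (coil covariance `cov`, scaled
#' by `cfg$noise_scale`) is added to every sample of the full k-space
#' grid, the mask (if any) is applied, and the data are reconstructed by
#' `op`; the sample standard deviation (denominator n-1) of the
#' reconstructions is returned per pixel. Replica seeds are spawned
#' deterministically from `cfg$seed`.
#'
#' @param op a [recon_operator()] (deterministic given its input).
#' @param kspace a `multicoil_kspace` (full grid).
#' @param mask a `sampling_mask`, or NULL for the non-accelerated arm.
#' @param cov a `noise_covariance`.
#' @param cfg a [replica_config()].
#' @return a `std_map`: list with `sigma` (matrix), `n_replicas`, `role`.
#' @export
pseudo_replica_std <- function(op, kspace, mask, cov, cfg) {
  stopifnot(inherits(kspace, "multicoil_kspace"),
            inherits(cfg, "replica_config"))
  d <- dim(kspace$data)
  seeds <- spawn_seeds(cfg$seed, cfg$n_replicas)
  s1 <- matrix(0, d[2], d[3]); s2 <- matrix(0, d[2], d[3])
  ref <- NULL  # first replica; shifting by it avoids the catastrophic
               # cancellation of accumulating squares of signal >> noise
  for (r in seq_len(cfg$n_replicas)) {
    ks <- kspace$data
    if (cfg$noise_scale > 0)
      ks <- ks + cfg$noise_scale * synthesize_noise(cov, d, seeds[r])
    rep_ks <- multicoil_kspace(ks)
    if (!is.null(mask)) rep_ks <- apply_mask(rep_ks, mask)
    img <- tryCatch(op(rep_ks, mask), error = function(e)
      stop("reconstruction failed on replica ", r, ": ",
           conditionMessage(e)))
    if (is.null(ref)) ref <- img
    img <- img - ref
    s1 <- s1 + img
    s2 <- s2 + img^2
  }
  n <- cfg$n_replicas
  var_ <- pmax((s2 - s1^2 / n) / (n - 1), 0)
  structure(list(sigma = sqrt(var_), n_replicas = n,
                 role = if (is.null(mask)) "normal" else "accelerated"),
            class = "std_map")
}

#' g-factor map from accelerated and normal standard-deviation maps
#'
#' Pixels where the normal-arm sigma falls below `floor_rel` times its
#' median are flagged invalid instead of producing huge ratios.
#'
#' @param acc `std_map` of the accelerated arm.
#' @param normal `std_map` of the directly reconstructed arm.
#' @param R acceleration factor of the sampling.
#' @param floor_rel relative denominator floor (default 1e-3).
#' @return a `gfactor_map`: list with `g` (matrix, NA where invalid),
#'   `invalid`, `R`.
#' @export
gfactor_map <- function(acc, normal, R, floor_rel = 1e-3) {
  stopifnot(inherits(acc, "std_map"), inherits(normal, "std_map"),
            all(dim(acc$sigma) == dim(normal$sigma)))
  if (acc$role != "accelerated" || normal$role != "normal")
    warning("std_map roles do not match the accelerated/normal convention")
  floor_ <- floor_rel * stats::median(normal$sigma)
  invalid <- normal$sigma <= floor_
  g <- acc$sigma / (normal$sigma * sqrt(R))
  g[invalid] <- NA_real_
  structure(list(g = g, invalid = invalid, R = R), class = "gfactor_map")
}

#' Full pseudo multiple-replica g-factor pipeline
#'
#' The normal arm reconstructs fully sampled replicas directly (inverse
#' FFT and RSS coil combination); the accelerated arm applies `mask` and
#' reconstructs with `op_acc`. The two arms use independent noise
#' streams; `R` is the effective acceleration of the mask.
#'
#' @param op_acc accelerated-arm [recon_operator()].
#' @param kspace full-grid `multicoil_kspace`.
#' @param mask `sampling_mask` for the accelerated arm.
#' @param cov `noise_covariance`.
#' @param cfg [replica_config()].
#' @return a `gfactor_map`.
#' @export
gfactor_pipeline <- function(op_acc, kspace, mask, cov, cfg) {
  arm_seeds <- spawn_seeds(cfg$seed, 2L)
  cfg_acc <- replica_config(cfg$n_replicas, arm_seeds[1], cfg$noise_scale)
  cfg_norm <- replica_config(cfg$n_replicas, arm_seeds[2], cfg$noise_scale)
  acc <- pseudo_replica_std(op_acc, kspace, mask, cov, cfg_acc)
  normal <- pseudo_replica_std(op_rss(), kspace, NULL, cov, cfg_norm)
  gfactor_map(acc, normal, effective_acceleration(mask))
}

#' @export
print.gfactor_map <- function(x, ...) {
  g <- x$g[!is.na(x$g)]
  cat(sprintf("<gfactor_map R = %.2f, median g %.3f, %d invalid pixels>\n",
              x$R, stats::median(g), sum(x$invalid)))
  invisible(x)
}

#' @export
print.noise_covariance <- function(x, ...) {
  cat(sprintf("<noise_covariance %d coils, mean |offdiag| %.3f>\n",
              nrow(x$psi),
              mean(abs(x$psi[upper.tri(x$psi)]))))
  invisible(x)
}
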