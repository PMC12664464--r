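# TV-regularized compressed-sensing reconstruction solved with ADMM, and
# the ACS-based coil-sensitivity estimate its SENSE-style forward model
# uses. The model is
#   min_x  1/2 || M F S x - y ||^2 + lambda * TV(x)
# with isotropic total variation on the complex image x; the split
# variable z = Dx is updated by group soft-thresholding and the x-update
# is solved by conjugate gradients.

#' Estimate coil sensitivities from the autocalibration band
#'
#' Takes apodized (Hann-windowed) low-resolution per-coil images from the
#' ACS phase-encode lines and normalizes them by their root sum of
#' squares, so the estimated maps have unit RSS on the image support.
#' Pixels whose low-resolution RSS falls below `rel_threshold` times its
#' maximum are flagged invalid and set to zero.
#'
#' @param calib a `multicoil_kspace` whose attached mask (or nonzero
#'   columns) identifies the ACS lines.
#' @param rel_threshold support threshold relative to the maximum
#'   low-resolution RSS (default 0.05).
#' @return a `coil_sensitivities` with an additional logical `valid`
#'   matrix marking pixels where the estimate is trustworthy.
#' @export
estimate_sensitivities <- function(calib, rel_threshold = 0.05) {
  stopifnot(inherits(calib, "multicoil_kspace"))
  d <- dim(calib$data)
  cols <- if (!is.null(calib$mask)) which(calib$mask$sampled)
          else which(apply(abs(calib$data), 3, sum) > 0)
  if (!length(cols)) stop("no ACS lines present")
  # Hann apodization across the ACS band suppresses Gibbs ringing in the
  # low-resolution images
  w <- rep(0, d[3])
  nw <- length(cols)
  w[cols] <- if (nw == 1) 1 else
    0.5 * (1 - cos(2 * pi * (seq_len(nw) - 1) / (nw - 1)))
  lowres <- array(0i, dim = d)
  for (c_ in seq_len(d[1]))
    lowres[c_, , ] <- ifft2c(sweep(calib$data[c_, , , drop = TRUE],
                                   2, w, `*`))
  if (d[1] == 1) dim(lowres) <- d
  rss <- matrix(0, d[2], d[3])
  for (c_ in seq_len(d[1])) rss <- rss + abs(lowres[c_, , ])^2
  rss <- sqrt(rss)
  valid <- rss >= rel_threshold * max(rss)
  maps <- array(0i, dim = d)
  for (c_ in seq_len(d[1])) {
    m <- lowres[c_, , ]
    m[valid] <- m[valid] / rss[valid]
    m[!valid] <- 0i
    maps[c_, , ] <- m
  }
  out <- structure(list(maps = maps, valid = valid),
                   class = "coil_sensitivities")
  out
}

#' Configuration for the TV-CS solver
#'
#' @param lambda_tv non-negative total-variation weight (in units of the
#'   data; scale with the signal level).
#' @param n_iter number of ADMM iterations (default 100).
#' @param rho ADMM penalty parameter (> 0, default 1).
#' @param cg_iter conjugate-gradient iterations per x-update (default 10).
#' @param tol residual tolerance for the convergence warning.
#' @return a `cs_config`.
#' @export
cs_config <- function(lambda_tv = 0.005, n_iter = 100, rho = 1,
                      cg_iter = 10, tol = 1e-3) {
  stopifnot(lambda_tv >= 0, n_iter >= 1, rho > 0)
  structure(list(lambda_tv = lambda_tv, n_iter = n_iter, rho = rho,
                 cg_iter = cg_iter, tol = tol), class = "cs_config")
}

grad2 <- function(x) {
  n <- nrow(x); m <- ncol(x)
  list(gx = x[, c(2:m, 1), drop = FALSE] - x,
       gy = x[c(2:n, 1), , drop = FALSE] - x)
}

grad2T <- function(gx, gy) {
  n <- nrow(gx); m <- ncol(gx)
  (gx[, c(m, 1:(m - 1)), drop = FALSE] - gx) +
    (gy[c(n, 1:(n - 1)), , drop = FALSE] - gy)
}

#' TV-regularized compressed-sensing reconstruction (ADMM)
#'
#' @param undersampled a `multicoil_kspace` (masked data y).
#' @param mask the `sampling_mask` used.
#' @param sens a `coil_sensitivities` for the SENSE-style forward model;
#'   maps should have unit RSS on the support (see
#'   [estimate_sensitivities()]).
#' @param cfg a [cs_config()].
#' @return real non-negative matrix: the magnitude of the complex
#'   solution, with an attribute `history` (data.frame of objective and
#'   primal/dual residuals per iteration).
#' @export
tv_cs_recon <- function(undersampled, mask, sens,
                        cfg = cs_config()) {
  stopifnot(inherits(undersampled, "multicoil_kspace"),
            inherits(sens, "coil_sensitivities"),
            inherits(cfg, "cs_config"))
  d <- dim(undersampled$data)
  stopifnot(all(dim(sens$maps) == d))
  msk <- if (!is.null(mask)) {
    stopifnot(length(mask$sampled) == d[3])
    mask$sampled
  } else rep(TRUE, d[3])
  y <- undersampled$data
  y[, , !msk] <- 0i
  nc <- d[1]
  Eforward <- function(x) {
    out <- array(0i, dim = d)
    for (c_ in seq_len(nc)) {
      k <- fft2c(sens$maps[c_, , ] * x)
      k[, !msk] <- 0i
      out[c_, , ] <- k
    }
    out
  }
  Eadjoint <- function(k) {
    out <- matrix(0i, d[2], d[3])
    for (c_ in seq_len(nc)) {
      kk <- k[c_, , ]
      kk[, !msk] <- 0i
      out <- out + Conj(sens$maps[c_, , ]) * ifft2c(kk)
    }
    out
  }
  EhE <- function(x) Eadjoint(Eforward(x))
  Ehy <- Eadjoint(y)

  cdot <- function(a, b) sum(Re(Conj(a) * b))
  # normal operator of the x-update; grad2T is D^H, so D^H D x =
  # -grad2T(grad2(x)) with these sign conventions
  Hop <- function(x) {
    g <- grad2(x)
    EhE(x) + cfg$rho * grad2T(g$gx, g$gy)
  }
  cg_solve <- function(rhs, x0, n_it) {
    x <- x0
    r <- rhs - Hop(x)
    p <- r
    rs <- cdot(r, r)
    if (rs == 0) return(x)
    for (it in seq_len(n_it)) {
      Hp <- Hop(p)
      alpha <- rs / cdot(p, Hp)
      x <- x + alpha * p
      r <- r - alpha * Hp
      rs_new <- cdot(r, r)
      if (rs_new < 1e-24) break
      p <- r + (rs_new / rs) * p
      rs <- rs_new
    }
    x
  }

  x <- Eadjoint(y)
  g <- grad2(x)
  zx <- g$gx; zy <- g$gy
  ux <- zx * 0; uy <- zy * 0
  hist <- data.frame(iter = integer(), objective = numeric(),
                     primal = numeric(), dual = numeric())
  for (it in seq_len(cfg$n_iter)) {
    rhs <- Ehy + cfg$rho * grad2T(zx - ux, zy - uy)
    x <- cg_solve(rhs, x, cfg$cg_iter)
    g <- grad2(x)
    vx <- g$gx + ux; vy <- g$gy + uy
    mag <- sqrt(abs(vx)^2 + abs(vy)^2)
    shr <- pmax(0, 1 - (cfg$lambda_tv / cfg$rho) / pmax(mag, 1e-30))
    zx_new <- vx * shr; zy_new <- vy * shr
    dual <- cfg$rho * sqrt(sum(abs(zx_new - zx)^2 + abs(zy_new - zy)^2))
    zx <- zx_new; zy <- zy_new
    ux <- vx - zx; uy <- vy - zy
    primal <- sqrt(sum(abs(g$gx - zx)^2 + abs(g$gy - zy)^2))
    obj <- 0.5 * sum(abs(Eforward(x) - y)^2) +
      cfg$lambda_tv * sum(sqrt(abs(g$gx)^2 + abs(g$gy)^2))
    hist <- rbind(hist, data.frame(iter = it, objective = obj,
                                   primal = primal, dual = dual))
  }
  scale_ <- sqrt(sum(abs(y)^2)) + 1e-30
  if (nrow(hist) && (hist$primal[nrow(hist)] > cfg$tol * scale_))
    warning(sprintf(
      "TV-CS ADMM not converged after %d iterations (primal residual %.3g)",
      cfg$n_iter, hist$primal[nrow(hist)]))
  out <- abs(x)
  attr(out, "history") <- hist
  out
}

#' @rdname tv_cs_recon
#' @export
op_tv_cs <- function(sens, cfg = cs_config()) {
  recon_operator(function(kspace, mask) {
    img <- tv_cs_recon(kspace, mask, sens, cfg)
    attr(img, "history") <- NULL
    img
  }, name = "tv_cs")
}
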