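# synthesize k-space whose missing lines follow a planted kernel exactly
planted_data <- function(nc, nr, nl, R, kx, ksl, seed = 5) {
  set.seed(seed)
  geom <- reconqa:::grappa_geometry(kx, ksl, R)
  nfeat <- nc * ksl * kx
  W <- lapply(seq_len(R - 1), function(o)
    matrix(complex(real = rnorm(nfeat * nc),
                   imaginary = rnorm(nfeat * nc)), nfeat, nc) / nfeat)
  data <- array(0i, c(nc, nr, nl))
  sc <- seq(1, nl, by = R)
  data[, , sc] <- complex(real = rnorm(nc * nr * length(sc)),
                          imaginary = rnorm(nc * nr * length(sc)))
  for (b in sc) for (o in seq_len(R - 1)) {
    tgt <- ((b - 1 + o) %% nl) + 1
    A <- reconqa:::grappa_features(data, b, geom, R)
    data[, , tgt] <- t(A %*% W[[o]])
  }
  list(data = data, W = W)
}
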