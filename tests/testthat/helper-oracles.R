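# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the package's own code paths.

# Pearson correlation from the direct covariance/sd formula.
pearson_oracle <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Diffusion map embedding via dense eigendecomposition of the (generally
# non-symmetric) Markov operator P itself.
embed_oracle <- function(W, alpha = 0.5, n_components = 10) {
  d <- rowSums(W)
  Wp <- W / outer(d^alpha, d^alpha)
  dp <- rowSums(Wp)
  P <- Wp / dp
  e <- eigen(P)
  ord <- order(Re(e$values), decreasing = TRUE)
  lam <- Re(e$values)[ord]
  V <- Re(e$vectors)[, ord, drop = FALSE]
  psi <- V / V[, 1L]          # constant trivial eigenvector -> uniform scale
  keep <- seq(2L, n_components + 1L)
  sweep(psi[, keep, drop = FALSE], 2L, lam[keep] / (1 - lam[keep]), "*")
}

# All-pairs loop variogram.
variogram_oracle <- function(x, d, n_bins, cutoff) {
  breaks <- seq(0, cutoff, length.out = n_bins + 1L)
  sums <- numeric(n_bins); counts <- integer(n_bins)
  n <- length(x)
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    if (!is.finite(x[i]) || !is.finite(x[j])) next
    dij <- d[i, j]
    if (dij > cutoff) next
    b <- max(1L, min(n_bins, findInterval(dij, breaks, rightmost.closed = TRUE,
                                          left.open = TRUE)))
    sums[b] <- sums[b] + 0.5 * (x[i] - x[j])^2
    counts[b] <- counts[b] + 1L
  }
  g <- sums / counts
  g[counts == 0L] <- NA_real_
  list(gamma = g, counts = counts)
}

# Linear-interpolation percentile, written from the order-statistic
# definition rather than via stats::quantile.
percentile_oracle <- function(x, pct) {
  s <- sort(x)
  h <- 1 + (length(s) - 1) * pct / 100
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Small deterministic test geometry.
tiny_geometry <- function(n_seeds = 60, n_parcels = 12, seed = 1,
                          noise_sd = 1, ...) {
  make_geometry(synth_config(n_seeds = n_seeds, n_parcels = n_parcels,
                             rng_seed = seed, noise_sd = noise_sd, ...))
}

# A seed space on a small integer grid with identity-scaled affine.
grid_seed_space <- function(n = 27) {
  side <- ceiling(n^(1 / 3))
  idx <- as.matrix(expand.grid(i = 1:side, j = 1:side, k = 1:side))[1:n, ]
  seed_space(idx, dim = c(side, side, side),
             affine = diag(4), voxel_size = 1)
}
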