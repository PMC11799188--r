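#' Pairwise Euclidean distances between seeds
#'
#' @param seeds A [seed_space()] or an `n x 3` coordinate matrix (mm).
#' @return Symmetric `n x n` distance matrix (mm) with zero diagonal.
#' @export
pairwise_distances <- function(seeds) {
  coords <- if (inherits(seeds, "seed_space")) seeds$coords else as.matrix(seeds)
  as.matrix(stats::dist(coords))
}

#' Empirical variogram of a scalar seed map
#'
#' Semivariance `gamma(h) = mean over pairs at distance ~h of
#' 0.5 * (x_i - x_j)^2`, the fingerprint of a map's spatial autocorrelation.
#' Pairs `(i < j)` are assigned to `n_bins` equal-width distance bins up to
#' a cutoff (default: the lower 70% of the distance range); empty bins are
#' kept with `pair_counts = 0` and `gamma = NA`, not silently dropped.
#' Absent map values are excluded pairwise.
#'
#' @param map Scalar seed map (numeric vector, `NA` = absent; at least 2
#'   present values).
#' @param d Distance matrix from [pairwise_distances()].
#' @param n_bins Number of distance bins.
#' @param cutoff Maximum pair distance used; default `0.7 * max(d)`.
#' @return An object of class `variogram` with `bin_centers` (mm,
#'   increasing), `gamma` (squared map units), `pair_counts`.
#' @export
empirical_variogram <- function(map, d, n_bins = 25, cutoff = NULL) {
  x <- as.numeric(map)
  ok <- is.finite(x)
  if (sum(ok) < 2) stop("variogram needs at least 2 present values", call. = FALSE)
  if (!all(ok)) {
    x <- x[ok]
    d <- d[ok, ok, drop = FALSE]
  }
  des <- variogram_design(d, n_bins, cutoff)
  g <- variogram_gamma(x, des)
  structure(list(bin_centers = des$centers, gamma = g,
                 pair_counts = des$counts, cutoff = des$cutoff),
            class = "variogram")
}

# Precompute pair indices, bin assignment and a sparse bin-averaging
# operator so many variograms over the same geometry are cheap.
variogram_design <- function(d, n_bins = 25, cutoff = NULL) {
  cutoff <- cutoff %||% (0.7 * max(d))
  ut <- which(upper.tri(d))
  dv <- d[ut]
  keep <- dv <= cutoff
  ut <- ut[keep]; dv <- dv[keep]
  n <- nrow(d)
  jj <- ((ut - 1L) %/% n) + 1L
  ii <- ut - (jj - 1L) * n
  breaks <- seq(0, cutoff, length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(dv, breaks, rightmost.closed = TRUE,
                                left.open = TRUE), 1L), n_bins)
  counts <- tabulate(bin, n_bins)
  nz <- counts > 0L
  B <- Matrix::sparseMatrix(i = bin, j = seq_along(bin),
                            x = 1 / counts[bin],
                            dims = c(n_bins, length(bin)))
  list(ii = ii, jj = jj, bin = bin, counts = counts, nonempty = nz,
       centers = (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2,
       cutoff = cutoff, B = B, n = n)
}

# gamma per bin for one map (or one column per map if x is a matrix)
variogram_gamma <- function(x, des) {
  x <- as.matrix(x)
  sq <- 0.5 * (x[des$ii, , drop = FALSE] - x[des$jj, , drop = FALSE])^2
  g <- as.matrix(des$B %*% sq)
  g[!des$nonempty, ] <- NA_real_
  if (ncol(g) == 1L) as.numeric(g) else g
}

#' Variogram-matched surrogate maps
#'
#' Generates `n_surr` randomized versions of a spatial map that preserve its
#' spatial autocorrelation, for use as a null distribution.  The generator
#' family is Gaussian-kernel random fields: spatially permuting the map
#' gives (spatial) white noise, and smoothing that permutation with a
#' row-normalized Gaussian kernel of bandwidth `h` gives a random field of
#' smoothness `h`, so the family spans everything from near-white maps to
#' trend-like maps.  The bandwidth, a smoothness scale and a white-noise
#' nugget are fitted once per ensemble by least squares between the map's
#' empirical variogram and the closed-form expected variogram of a smoothed
#' permutation (for smoother `K`, `E gamma(i,j) = 0.5 var(x) *
#' ||K_i - K_j||^2`), choosing the candidate bandwidth with minimal SSE;
#' scale and nugget are clamped at zero from below.  Each surrogate is then
#' `sqrt(scale) * K permuted(x) + sqrt(nugget) * white noise`, and, when
#' `resample` is on (default), is rank-mapped onto the original value set so
#' each surrogate's sorted values equal the original's exactly.
#'
#' @param map Scalar seed map with no absent values among the seeds used.
#' @param d Distance matrix (mm) from [pairwise_distances()].
#' @param n_surr Number of surrogates (`>= 1`).
#' @param seed Integer RNG seed governing the whole ensemble.
#' @param resample Preserve the value multiset exactly via rank mapping.
#' @param bw_frac Candidate Gaussian bandwidths as fractions of the maximum
#'   pairwise distance.
#' @param n_bins,cutoff Variogram settings, as [empirical_variogram()].
#' @return A `surrogate_ensemble`: `maps` (`n_surr x n_seeds`) and
#'   `generator_params` (candidate bandwidth grid in mm, the selected
#'   bandwidth, fitted scale and nugget, resample flag, seed).
#' @export
variogram_surrogates <- function(map, d, n_surr, seed = 1L, resample = TRUE,
                                 bw_frac = c(0.05, 0.1, 0.175, 0.25, 0.35,
                                             0.5, 0.7),
                                 n_bins = 25, cutoff = NULL) {
  x <- as.numeric(map)
  if (anyNA(x)) stop("surrogate generation requires a complete map", call. = FALSE)
  if (n_surr < 1) stop("n_surr must be >= 1", call. = FALSE)
  gen <- surrogate_generator(d, bw_frac = bw_frac, n_bins = n_bins,
                             cutoff = cutoff)
  fit <- fit_surrogate_model(x, gen)
  n <- gen$n
  K <- gen$smoothers[[fit$idx]]
  x_sorted <- sort(x)
  maps <- matrix(NA_real_, n_surr, n)
  with_seed(seed, {
    for (s in seq_len(n_surr)) {
      sm <- as.numeric(K %*% x[sample.int(n)])
      surr <- sqrt(fit$scale) * (sm - mean(sm)) +
        sqrt(fit$nugget) * stats::rnorm(n)
      if (resample) surr <- x_sorted[rank(surr, ties.method = "first")]
      maps[s, ] <- surr
    }
  })
  structure(list(maps = maps,
                 generator_params = list(bw_grid = gen$bws,
                                         bandwidth = gen$bws[fit$idx],
                                         scale = fit$scale,
                                         nugget = fit$nugget,
                                         resample = resample,
                                         rng_seed = seed)),
            class = "surrogate_ensemble")
}

# Geometry-dependent precomputation shared by all surrogates over one
# distance matrix: row-normalized Gaussian smoothing operators, their
# closed-form expected variograms under permutation (up to the map's
# variance), and the variogram design.
surrogate_generator <- function(d, bw_frac = c(0.05, 0.1, 0.175, 0.25, 0.35,
                                               0.5, 0.7),
                                n_bins = 25, cutoff = NULL) {
  n <- nrow(d)
  if (n < 10) stop("too few seeds for surrogate generation", call. = FALSE)
  bws <- sort(unique(bw_frac)) * max(d)
  smoothers <- lapply(bws, function(h) {
    K <- exp(-d^2 / (2 * h^2))
    K / rowSums(K)
  })
  des <- variogram_design(d, n_bins, cutoff)
  gam_theory <- vapply(smoothers, function(K) {
    S <- tcrossprod(K)
    v <- diag(S)
    pair <- 0.5 * (v[des$ii] + v[des$jj] - 2 * S[cbind(des$ii, des$jj)])
    as.numeric(des$B %*% pair)
  }, numeric(n_bins))
  list(n = n, bws = bws, smoothers = smoothers, des = des,
       gam_theory = gam_theory)
}

# Least-squares fit of bandwidth, scale and nugget against the empirical
# variogram; one fit serves the whole ensemble.
fit_surrogate_model <- function(x, gen) {
  g_emp <- variogram_gamma(x, gen$des)
  nz <- gen$des$nonempty & is.finite(g_emp)
  ge <- g_emp[nz]
  vx <- stats::var(x)
  best <- NULL
  for (idx in seq_along(gen$bws)) {
    gt <- vx * gen$gam_theory[nz, idx]
    fit <- stats::lm.fit(cbind(1, gt), ge)
    sse <- sum(fit$residuals^2)
    if (is.null(best) || sse < best$sse)
      best <- list(sse = sse, idx = idx,
                   nugget = max(fit$coefficients[[1L]], 0),
                   scale = max(fit$coefficients[[2L]], 0))
  }
  best
}

#' Spatial-autocorrelation-corrected correlation test
#'
#' Pearson correlation between two scalar seed maps with a permutation-style
#' p-value against variogram-matched surrogates: the first map (by
#' convention the derived gradient) is surrogated `n_surr` times, each
#' surrogate is correlated with the second (fixed reference) map, and the
#' two-sided p-value with add-one correction is
#' `p_sa = (1 + #\{|r_null| >= |r_obs|\}) / (1 + n_surr)`, bounded below by
#' `1 / (n_surr + 1)`.
#'
#' @param x Scalar seed map to be surrogated (the predictor/gradient).
#' @param y Fixed reference scalar seed map (same length).
#' @param d Distance matrix (mm); rows/columns follow the maps' seed order.
#' @param n_surr Number of surrogate maps.
#' @param seed Integer RNG seed for the surrogate ensemble.
#' @param ... Passed to [variogram_surrogates()].
#' @return An `sa_test` object: `r_obs`, `p_sa`, `n_surrogates`,
#'   `null_distribution`, and the surrogate `generator_params`.
#' @export
sa_corrected_correlation <- function(x, y, d, n_surr = 1000, seed = 1L, ...) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("maps must have the same length", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 10)
    stop("need at least 10 pairwise-complete values", call. = FALSE)
  if (!all(ok)) {
    tc_log("sa test: excluding %d absent pairs", sum(!ok))
    x <- x[ok]; y <- y[ok]; d <- d[ok, ok, drop = FALSE]
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y", call. = FALSE)
  r_obs <- stats::cor(x, y)
  ens <- variogram_surrogates(x, d, n_surr, seed = seed, ...)
  null_r <- as.numeric(stats::cor(t(ens$maps), y))
  p_sa <- (1 + sum(abs(null_r) >= abs(r_obs))) / (1 + n_surr)
  structure(list(r_obs = r_obs, p_sa = p_sa, n_surrogates = n_surr,
                 null_distribution = null_r,
                 generator_params = ens$generator_params),
            class = "sa_test")
}

#' @export
print.sa_test <- function(x, ...) {
  cat(sprintf("<sa_test> r = %.3f, p_SA = %.4g (%d variogram-matched surrogates)\n",
              x$r_obs, x$p_sa, x$n_surrogates))
  invisible(x)
}
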