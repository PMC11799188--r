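test_that("pairwise distances are Euclidean, symmetric, and metric", {
  d <- pairwise_distances(rbind(c(0, 0, 0), c(3, 4, 0), c(0, 0, 0)))
  expect_equal(d[1, 2], 5)
  expect_equal(d[1, 3], 0)
  set.seed(31)
  co <- matrix(rnorm(30), 10, 3)
  d2 <- pairwise_distances(co)
  expect_equal(d2, t(d2))
  expect_equal(unname(diag(d2)), rep(0, 10))
  for (i in 1:10) for (j in 1:10) for (k in 1:10)
    expect_lte(d2[i, j], d2[i, k] + d2[k, j] + 1e-12)
})

test_that("empirical variograms equal the all-pairs loop oracle", {
  co <- matrix(rnorm(45), 15, 3)
  d <- pairwise_distances(co)
  expect_equal(unique(empirical_variogram(rep(2, 15), d)$gamma[
    empirical_variogram(rep(2, 15), d)$pair_counts > 0]), 0)

  d2 <- pairwise_distances(rbind(c(0, 0, 0), c(4, 0, 0)))
  vg2 <- empirical_variogram(c(0, 2), d2, n_bins = 4, cutoff = 4)
  expect_equal(vg2$gamma[vg2$pair_counts > 0], 2)   # 0.5 * (2)^2

  set.seed(32)
  x <- rnorm(15)
  vg <- empirical_variogram(x, d, n_bins = 10)
  orc <- variogram_oracle(x, d, 10, 0.7 * max(d))
  expect_equal(vg$gamma, orc$gamma, tolerance = 1e-12)
  expect_equal(vg$pair_counts, orc$counts)
  expect_true(all(diff(vg$bin_centers) > 0))
  expect_error(empirical_variogram(c(NA, NA, 1), pairwise_distances(co[1:3, ])),
               "2 present")
})

test_that("surrogates preserve the value multiset and reproduce exactly", {
  geom <- tiny_geometry(80, 10, seed = 33)
  d <- pairwise_distances(geom$seeds)
  x <- random_smooth_map(geom$seeds, 6, seed = 5)
  ens <- variogram_surrogates(x, d, 20, seed = 9)
  for (s in 1:20)
    expect_identical(sort(ens$maps[s, ]), sort(x))
  ens2 <- variogram_surrogates(x, d, 20, seed = 9)
  expect_identical(ens$maps, ens2$maps)
  ens3 <- variogram_surrogates(x, d, 5, seed = 10, resample = FALSE)
  expect_false(identical(sort(ens3$maps[1, ]), sort(x)))
  expect_error(variogram_surrogates(c(x[-1], NA), d, 5), "complete")
})

test_that("the SA-corrected test behaves like an add-one permutation test", {
  geom <- tiny_geometry(80, 10, seed = 34)
  d <- pairwise_distances(geom$seeds)
  x <- random_smooth_map(geom$seeds, 6, seed = 11)
  tt <- sa_corrected_correlation(x, x, d, n_surr = 100, seed = 3)
  expect_equal(tt$r_obs, 1)
  expect_true(all(tt$null_distribution < 1))   # no surrogate equals x
  expect_equal(tt$p_sa, 1 / 101)
  expect_gte(tt$p_sa, 1 / (tt$n_surrogates + 1))
  expect_equal(length(tt$null_distribution), 100)

  expect_error(sa_corrected_correlation(x[1:5], x[1:5], d[1:5, 1:5], 10),
               "at least 10")
  expect_error(sa_corrected_correlation(rep(1, 80), x, d, 10), "zero variance")
  expect_error(sa_corrected_correlation(x, x[1:10], d, 10), "same length")
})

test_that("white-noise maps give decisions agreeing with the parametric test", {
  geom <- tiny_geometry(100, 10, seed = 35)
  d <- pairwise_distances(geom$seeds)
  agree <- 0
  nrep <- 200
  for (i in seq_len(nrep)) {
    set.seed(7000 + i)
    x <- rnorm(100); y <- rnorm(100)
    tt <- sa_corrected_correlation(x, y, d, n_surr = 100, seed = i)
    pp <- stats::cor.test(x, y)$p.value
    agree <- agree + ((tt$p_sa < 0.05) == (pp < 0.05))
  }
  expect_gte(agree / nrep, 0.9)
})

test_that("absent values are excluded pairwise from the SA test", {
  geom <- tiny_geometry(80, 10, seed = 36)
  d <- pairwise_distances(geom$seeds)
  x <- random_smooth_map(geom$seeds, 6, seed = 21)
  y <- 0.5 * x + 0.5 * random_smooth_map(geom$seeds, 6, seed = 22)
  xm <- x; xm[1:5] <- NA
  tt <- sa_corrected_correlation(xm, y, d, n_surr = 50, seed = 1)
  expect_equal(tt$r_obs, pearson_oracle(xm, y), tolerance = 1e-12)
})
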