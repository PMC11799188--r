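test_that("normalized-angle kernel maps cosine geometry into [0, 1]", {
  p <- rbind(c(1, 2, 2), c(2, 4, 4),        # parallel
             c(1, 0, 0), c(0, 1, 0),        # orthogonal
             c(3, 0, 0), c(-3, 0, 0))       # antiparallel
  a <- normalized_angle_affinity(p)
  expect_equal(a[1, 2], 1)
  expect_equal(a[3, 4], 0.5)
  expect_equal(a[5, 6], 0)
  expect_true(all(a >= 0 & a <= 1))
  expect_equal(a, t(a))
  expect_equal(unname(diag(a)), rep(1, 6))

  # scale invariance: positive row rescaling leaves the kernel unchanged
  expect_equal(normalized_angle_affinity(p * c(1, 7, 0.1, 2, 5, 3)), a)

  pz <- rbind(c(1, 1, 0), c(0, 0, 0))
  expect_error(normalized_angle_affinity(pz), "seed")
  ap <- normalized_angle_affinity(pz, on_zero = "permissive")
  expect_equal(ap[1, 2], 0.5)
})

test_that("diffusion map embedding matches a dense Markov-operator oracle", {
  for (s in 1:5) {
    set.seed(s)
    B <- matrix(runif(50 * 50), 50)
    W <- (B + t(B)) / 2
    g <- diffusion_map_embed(W, alpha = 0.5, n_components = 5)
    orc <- embed_oracle(W, alpha = 0.5, n_components = 5)
    for (k in 1:5)
      expect_gte(abs(pearson_oracle(g$loadings[, k], orc[, k])), 0.999)
    expect_true(all(g$eigenvalues > 0 & g$eigenvalues < 1))
    expect_true(all(diff(g$eigenvalues) <= 1e-12))
  }
})

test_that("a two-block affinity yields an antisymmetric first gradient", {
  W <- matrix(0.01, 4, 4)
  W[1:2, 1:2] <- 1; W[3:4, 3:4] <- 1
  g <- diffusion_map_embed(W, alpha = 0.5, n_components = 2)
  g1 <- g$loadings[, 1]
  expect_lt(g1[1] * g1[3], 0)               # blocks on opposite sides
  expect_equal(abs(g1[1]), abs(g1[2]), tolerance = 1e-10)
  expect_equal(abs(g1[3]), abs(g1[4]), tolerance = 1e-10)
})

test_that("embedding is equivariant under seed permutation", {
  set.seed(11)
  B <- matrix(runif(30 * 30), 30)
  W <- (B + t(B)) / 2
  perm <- sample(30)
  g <- diffusion_map_embed(W, n_components = 3)
  gp <- diffusion_map_embed(W[perm, perm], n_components = 3)
  for (k in 1:3)
    expect_equal(abs(pearson_oracle(gp$loadings[, k], g$loadings[perm, k])),
                 1, tolerance = 1e-6)
})

test_that("embedding rejects invalid affinities with useful messages", {
  W <- diag(1, 6)
  W[1:3, 1:3] <- 0.9; W[4:6, 4:6] <- 0.9   # two components
  expect_error(diffusion_map_embed(W, n_components = 2), "component sizes: 3, 3")
  expect_error(diffusion_map_embed(matrix(c(0, 1, 1, 0), 2), n_components = 5),
               "n_components")
  M <- matrix(runif(16), 4); M[1, 2] <- 5
  expect_error(diffusion_map_embed(M, n_components = 2), "symmetric")
  expect_error(diffusion_map_embed(-(diag(4) + 1), n_components = 2),
               "non-negative")
})

test_that("explained variance normalizes the retained spectrum", {
  expect_equal(explained_variance(c(0.5, 0.25, 0.25)), c(0.5, 0.25, 0.25))
  expect_equal(explained_variance(c(2, 1, 1)), c(0.5, 0.25, 0.25))
  set.seed(12)
  ev <- sort(runif(10), decreasing = TRUE)
  expect_equal(sum(explained_variance(ev)), 1, tolerance = 1e-12)
  expect_error(explained_variance(c(1, -0.1)), "positive")
  expect_error(explained_variance(c(0.1, 0.5)), "non-increasing")
})

test_that("sign alignment is deterministic and idempotent", {
  set.seed(13)
  L <- matrix(rnorm(40), 20, 2)
  ref <- L[, 1] + rnorm(20, sd = 0.1)
  a1 <- align_sign(L, ref)
  a2 <- align_sign(-L, ref)
  expect_equal(a1, a2)
  expect_gte(stats::cor(a1[, 1], ref), 0)
  expect_equal(align_sign(a1, ref), a1)
  # no reference: largest-magnitude entry positive
  b <- align_sign(L)
  for (k in 1:2) expect_gt(b[which.max(abs(b[, k])), k], 0)
  Lz <- cbind(L[, 1], 0)
  expect_warning(az <- align_sign(Lz), "zero variance")
  expect_equal(az[, 2], Lz[, 2])
})

test_that("affinity embeddings are invariant to profile row scaling", {
  set.seed(14)
  prof <- matrix(rexp(40 * 10), 40, 10)
  g1 <- connectivity_gradients(prof, 0, n_components = 3)
  g2 <- connectivity_gradients(prof * runif(40, 0.5, 2), 0, n_components = 3)
  for (k in 1:3)
    expect_equal(abs(pearson_oracle(g1$loadings[, k], g2$loadings[, k])), 1,
                 tolerance = 1e-6)
})
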