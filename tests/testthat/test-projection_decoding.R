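test_that("gradient projection is per-column Pearson correlation", {
  set.seed(41)
  g <- rnorm(50)
  m <- cbind(3 * g + 2, -g, matrix(rnorm(50 * 5), 50))
  cm <- project_gradient(g, m)
  expect_equal(unname(cm[1]), 1)
  expect_equal(unname(cm[2]), -1)
  for (j in 1:7)
    expect_equal(unname(cm[j]), pearson_oracle(g, m[, j]), tolerance = 1e-12)

  mz <- cbind(m[, 1:2], 0)
  expect_warning(cz <- project_gradient(g, mz), "zero-variance")
  expect_true(is.na(cz[3]))
  expect_error(project_gradient(rep(1, 50), m), "zero-variance gradient")
  expect_error(project_gradient(g[1:10], m), "length")
})

test_that("community decoding averages and orders ascending", {
  gs <- decode_by_communities(c(1, 3, 2, 4), c("A", "A", "B", "B"))
  expect_equal(gs$labels, c("A", "B"))
  expect_equal(gs$statistic, c(2, 3))
  # singleton community
  gs2 <- decode_by_communities(c(5, 1, 2), c("X", "Y", "Y"))
  expect_equal(gs2$statistic[gs2$labels == "X"], 5)

  set.seed(42)
  vals <- rnorm(70)
  labs <- sample(paste0("C", 1:7), 70, replace = TRUE)
  gs3 <- decode_by_communities(vals, labs)
  manual <- sort(vapply(split(vals, labs), mean, numeric(1)))
  expect_equal(gs3$labels, names(manual))
  expect_equal(gs3$statistic, unname(manual))
  # ties break lexicographically
  gt <- decode_by_communities(c(1, 1), c("B", "A"))
  expect_equal(gt$labels, c("A", "B"))
})

test_that("nucleus decoding orders by median with quartile export", {
  gs <- decode_by_nuclei(c(0, 0, 10), c("A", "A", "B"))
  expect_equal(gs$labels, c("A", "B"))
  expect_equal(gs$statistic, c(0, 10))
  expect_equal(decode_by_nuclei(c(1, 9, 5), rep("N", 3))$statistic, 5)

  set.seed(43)
  vals <- rnorm(110)
  labs <- sample(paste0("N", sprintf("%02d", 1:11)), 110, replace = TRUE)
  gs2 <- decode_by_nuclei(vals, labs)
  manual <- sort(vapply(split(vals, labs), stats::median, numeric(1)))
  expect_equal(gs2$labels, names(manual))
  expect_equal(gs2$statistic, unname(manual))
  expect_equal(colnames(gs2$quartiles), c("q25", "q50", "q75"))
  expect_equal(unname(gs2$quartiles[, "q50"]), gs2$statistic)

  labs[1:10] <- NA
  gs3 <- decode_by_nuclei(vals, labs)
  expect_equal(sum(lengths(gs3$groups)), 100)
})

test_that("gradient-space tables carry every seed and the overlays", {
  g1 <- rnorm(20); g2 <- rnorm(20)
  tab <- gradient_space_table(g1, g2,
                              overlays = list(qt1 = rnorm(20),
                                              nucleus = sample(letters[1:3], 20,
                                                               replace = TRUE)))
  expect_equal(nrow(tab), 20)
  expect_equal(names(tab), c("seed_id", "g1", "g2", "qt1", "nucleus"))
  path <- tempfile(fileext = ".tsv")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- utils::read.delim(path)
  expect_equal(back$g1, g1, tolerance = 1e-12)
  expect_error(gradient_space_table(g1, g2[1:3]), "length")
  expect_error(gradient_space_table(g1, g2, overlays = list(x = 1:3)),
               "overlay")
})

test_that("map consistency is per-individual correlation with the group map", {
  set.seed(44)
  grp <- rnorm(30)
  inds <- list(grp, -grp, grp + rnorm(30))
  r <- map_consistency(inds, grp)
  expect_equal(r[1], 1)
  expect_equal(r[2], -1)
  expect_equal(r[3], pearson_oracle(inds[[3]], grp), tolerance = 1e-12)
  expect_warning(rz <- map_consistency(list(rep(1, 30)), grp), "variance")
  expect_true(is.na(rz[1]))
})

test_that("projected gradients echo the parcel anchors' axis positions", {
  cfg <- synth_config(n_seeds = 300, n_parcels = 60, rng_seed = 2)
  geom <- make_geometry(cfg)
  nrm <- normalize_columns_max(simulate_sc_counts(geom))
  g <- align_sign(connectivity_gradients(nrm, 75, n_components = 5),
                  reference = geom$u1)
  cortical <- project_gradient(g$loadings[, 1], nrm)
  expect_gte(abs(pearson_oracle(cortical, geom$anchors[, 1])), 0.8)
})
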