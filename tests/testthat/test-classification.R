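test_that("PCA reduction hits the variance target and handles degeneracies", {
  set.seed(20)
  base <- rnorm(100)
  # two perfectly correlated features collapse to one component
  x <- cbind(a = base, b = 2 * base + 3)
  red <- reduce_features_pca(x)
  expect_equal(ncol(red$scores), 1)
  # retained explained variance >= 0.90, verified from the spectrum
  x2 <- matrix(rnorm(200 * 8), 200, 8) %*% diag(c(4, 3, 2, 1, rep(0.2, 4)))
  red2 <- reduce_features_pca(x2, var_target = 0.90)
  expect_gte(sum(red2$explained[seq_len(ncol(red2$scores))]), 0.90)
  # reconstruction through the retained basis captures >= 90% of variance
  xs <- scale(x2)
  recon <- red2$scores %*% t(red2$rotation)
  expect_gte(1 - sum((xs - recon)^2) / sum(xs^2), 0.90)
  # zero-variance features dropped with a warning
  expect_warning(reduce_features_pca(cbind(x2, 0)), "zero-variance")
  # more features than cells: components bounded by n - 1
  wide <- matrix(rnorm(5 * 20), 5, 20)
  expect_lte(ncol(reduce_features_pca(wide, var_target = 1)$scores), 4)
})

blobs3 <- function(n_per = 300, seed = 1) {
  set.seed(seed)
  centres <- rbind(c(0, 0), c(10, 0), c(0, 10))
  x <- do.call(rbind, lapply(1:3, function(k)
    cbind(rnorm(n_per, centres[k, 1], 0.5), rnorm(n_per, centres[k, 2], 0.5))))
  list(x = x, truth = rep(1:3, each = n_per))
}

test_that("mini-batch k-means recovers planted blobs and tracks the full-batch oracle", {
  b <- blobs3()
  expect_error(cluster_minibatch_kmeans(b$x, 5000), "k exceeds")
  one <- cluster_minibatch_kmeans(b$x, 1, seed = 2)
  expect_equal(unique(one$labels), 1)
  km <- cluster_minibatch_kmeans(b$x, 3, seed = 2)
  expect_gte(mclust::adjustedRandIndex(km$labels, b$truth), 0.99)
  expect_identical(km$labels, cluster_minibatch_kmeans(b$x, 3, seed = 2)$labels)
  # inertia within 5% of full-batch k-means on 2000 points
  set.seed(21)
  centres8 <- matrix(rnorm(8 * 4, 0, 6), 8, 4)
  assign8 <- sample(1:8, 2000, TRUE)
  x2k <- centres8[assign8, ] + matrix(rnorm(2000 * 4, 0, 0.8), 2000, 4)
  mb <- cluster_minibatch_kmeans(x2k, 8, seed = 3)
  full <- stats::kmeans(x2k, 8, nstart = 10, iter.max = 100)
  expect_lte(mb$inertia, 1.05 * full$tot.withinss)
})

test_that("reclassification builds nested tiers that partition their parent", {
  b <- blobs3(150, seed = 4)
  # one parent tier holding two planted subpopulations
  tiers <- cluster_tiers("CD68", ifelse(b$truth == 3, 2, 1))
  sub <- reclassify_cluster(tiers, b$x, "1", k_sub = 2, seed = 5)
  in_parent <- b$truth != 3
  expect_true(all(startsWith(sub$paths[in_parent], "1.")))
  expect_identical(sub$paths[!in_parent], tiers$paths[!in_parent])
  expect_gte(mclust::adjustedRandIndex(sub$paths[in_parent],
                                       b$truth[in_parent]), 0.95)
  # k_sub = 1 keeps the membership, as a single child
  sub1 <- reclassify_cluster(tiers, b$x, "2", k_sub = 1, seed = 5)
  expect_true(all(sub1$paths[b$truth == 3] == "2.1"))
  # repeated reclassification nests paths and preserves the partition
  sub2 <- reclassify_cluster(sub, b$x, "1.1", k_sub = 2, seed = 6)
  expect_true(any(grepl("^1\\.1\\.[12]$", sub2$paths)))
  expect_equal(length(sub2$paths), length(tiers$paths))
  expect_error(reclassify_cluster(tiers, b$x, "9", 2), "empty parent")
  expect_error(reclassify_cluster(tiers, b$x, "2", 10^6), "k_sub exceeds")
})

test_that("the GMM path agrees with the fast path on separated populations", {
  b <- blobs3(250, seed = 7)
  # all fixtures here are far below the 50k sampling cap, so the
  # scaled-down-model-count warning is expected throughout
  gm <- suppressWarnings(cluster_gmm_alternative(b$x, k_final = 3, seed = 8))
  expect_gte(mclust::adjustedRandIndex(gm$labels, b$truth), 0.95)
  km <- cluster_minibatch_kmeans(reduce_features_pca(b$x, 0.9)$scores, 3,
                                 seed = 8)
  expect_gte(mclust::adjustedRandIndex(gm$labels, km$labels), 0.95)
  # n < 50000: degenerate single-batch branch still fits >= 1 model
  expect_warning(
    gm2 <- cluster_gmm_alternative(b$x[1:600, ], 3, seed = 9,
                                   n_sample = 50000),
    "scaled down")
  expect_gte(gm2$n_models, 1)
  # label structure stable across seeds on strongly separated data
  gm3 <- suppressWarnings(cluster_gmm_alternative(b$x, 3, seed = 99))
  expect_gte(mclust::adjustedRandIndex(gm$labels, gm3$labels), 0.9)
  expect_error(cluster_gmm_alternative(b$x[1:2, ], 3), "fewer cells")
})

test_that("binarization respects tier descent, permutation and overrides", {
  paths <- c("1", "2", "2.1", "2.2", "3")
  tiers <- cluster_tiers("CD3", c(1, 2, 2, 3, 3))
  tiers$paths <- c("1", "2.1", "2.2", "3", "3")
  none <- apply_binarization(tiers, binarization_decision("CD3"))
  expect_false(any(none))
  pos2 <- apply_binarization(tiers,
                             binarization_decision("CD3", positive_paths = "2"))
  expect_equal(pos2, c(FALSE, TRUE, TRUE, FALSE, FALSE))
  expect_error(apply_binarization(tiers,
    binarization_decision("CD3", positive_paths = "7")), "unknown tier")
  ov <- binarization_decision("CD3", positive_paths = "2",
                              overrides = data.frame(cell = 5, positive = TRUE))
  expect_true(apply_binarization(tiers, ov)[5])
  # calls are invariant to cluster label permutation
  set.seed(22)
  labs <- sample(1:4, 200, TRUE)
  perm <- sample(4)
  t1 <- cluster_tiers("m", labs)
  t2 <- cluster_tiers("m", perm[labs])
  c1 <- apply_binarization(t1, binarization_decision("m", positive_paths = "2"))
  c2 <- apply_binarization(t2, binarization_decision(
    "m", positive_paths = as.character(perm[2])))
  expect_identical(c1, c2)
})

test_that("top-tier selection recovers a planted positive population", {
  set.seed(23)
  n <- 2000; prev <- 0.2
  truth <- runif(n) < prev
  # chromogen-driven features: positives high chromogen OD
  chrom <- ifelse(truth, rnorm(n, 0.7, 0.08), rnorm(n, 0.05, 0.04))
  x <- cbind(chrom, chrom + rnorm(n, 0, 0.05), rnorm(n), rnorm(n))
  red <- reduce_features_pca(x, 0.9)
  km <- cluster_minibatch_kmeans(red$scores, 20, seed = 24)
  tiers <- cluster_tiers("m", km$labels)
  sel <- select_top_tiers(tiers, chrom, target_count = sum(truth))
  call <- apply_binarization(tiers,
    binarization_decision("m", positive_paths = sel$positive))
  precision <- sum(call & truth) / sum(call)
  recall <- sum(call & truth) / sum(truth)
  expect_gte(precision, 0.95)
  expect_gte(recall, 0.95)
})
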