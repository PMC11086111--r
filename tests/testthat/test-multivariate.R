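test_that("covariance PCA recovers a diagonal structure and stays orthonormal", {
  set.seed(21)
  x <- cbind(rnorm(4000, 0, 3), rnorm(4000, 0, 1))
  res <- run_pca(x, scaling = "none")
  expect_equal(res$variance_ratio, c(0.9, 0.1), tolerance = 0.05)
  gram <- crossprod(res$loadings)
  expect_equal(gram, diag(ncol(x)), tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(res$variance_ratio) <= 1e-12))
  expect_lte(sum(res$variance_ratio), 1 + 1e-9)

  # deterministic sign convention: largest-magnitude loading positive
  expect_true(all(apply(res$loadings, 2, function(v) v[which.max(abs(v))] > 0)))
  expect_error(run_pca(rbind(c(1, NA), c(2, 3), c(0, 1))), class = "posturekit_completeness_error")
})

test_that("isotropic data spreads variance evenly and reconstruction is lossless", {
  set.seed(22)
  x <- matrix(rnorm(2000 * 5), 2000, 5)
  res <- run_pca(x)
  expect_true(all(res$variance_ratio > 0.15 & res$variance_ratio < 0.25))
  recon <- res$scores %*% t(res$loadings)
  recon <- sweep(recon, 2, res$center, `+`)
  expect_lt(max(abs(recon - x)), 1e-8)
})

test_that("component selection honours the retention threshold", {
  expect_equal(select_components(c(0.815, 0.093, 0.060, 0.032), 0.90), 2)
  expect_equal(select_components(c(1.0), 0.9), 1)
  expect_equal(select_components(c(0.4, 0.3, 0.2, 0.1), 1.0), 4)
  expect_error(select_components(c(0.5, 0.5), 0), class = "posturekit_invalid_input")
})

test_that("all five clustering methods separate well-split blobs identically", {
  set.seed(31)
  x <- rbind(
    matrix(rnorm(60 * 2, 0, 1), ncol = 2),
    matrix(rnorm(60 * 2, 15, 1), ncol = 2) # ~10+ SDs apart
  )
  truth <- rep(1:2, each = 60)
  for (m in c("kmeans", "meanshift", "ward", "complete", "average")) {
    res <- cluster_scores(x, method = m, k = 2)
    expect_equal(res$n_clusters, 2, info = m)
    expect_equal(adjusted_rand(res$labels, truth), 1, info = m)
    expect_gt(res$silhouette, 0.5)
  }
})

test_that("degenerate inputs give one mean-shift cluster or an infeasible-k error", {
  x <- matrix(1, 10, 2)
  ms <- cluster_scores(x, method = "meanshift")
  expect_equal(ms$n_clusters, 1)
  expect_true(is.na(ms$silhouette))
  expect_error(cluster_scores(x, method = "kmeans", k = 2), class = "posturekit_infeasible_k")
  expect_error(
    cluster_scores(matrix(rnorm(8), 4, 2), method = "ward", k = 5),
    class = "posturekit_infeasible_k"
  )
})

test_that("k-means with a fixed seed is bit-reproducible and leaves the RNG alone", {
  set.seed(55)
  x <- matrix(rnorm(200), 100, 2)
  r1 <- cluster_scores(x, "kmeans", k = 3, seed = 99)
  state <- .Random.seed
  r2 <- cluster_scores(x, "kmeans", k = 3, seed = 99)
  expect_identical(r1$labels, r2$labels)
  expect_identical(state, .Random.seed)
})

test_that("hierarchical linkages agree with a brute-force agglomeration oracle", {
  set.seed(41)
  for (rep in 1:5) {
    x <- matrix(rnorm(20), 10, 2)
    for (linkage in c("ward", "complete", "average")) {
      for (k in 2:3) {
        ours <- cluster_scores(x, method = linkage, k = k)$labels
        oracle <- agglomerate_bruteforce(x, k, linkage)
        expect_equal(adjusted_rand(ours, oracle), 1,
          info = sprintf("%s k=%d rep=%d", linkage, k, rep)
        )
      }
    }
  }
})

test_that("silhouette matches hand values, the oracle, and cluster::silhouette", {
  # two singletons score 0 by the singleton convention
  x2 <- rbind(c(0, 0), c(1, 0))
  expect_equal(silhouette_score(x2, c(1, 2)), 0)

  # tight natural pairing scores near 1
  x4 <- rbind(c(0, 0), c(0, 0.1), c(10, 0), c(10, 0.1))
  s4 <- silhouette_score(x4, c(1, 1, 2, 2))
  expect_gt(s4, 0.95)
  expect_equal(s4, silhouette_bruteforce(x4, c(1, 1, 2, 2)), tolerance = 1e-12)

  # random labels on one blob score near zero
  set.seed(61)
  low <- replicate(40, {
    x <- matrix(rnorm(60), 30, 2)
    silhouette_score(x, sample(1:2, 30, replace = TRUE))
  })
  expect_gte(mean(low <= 0.1), 0.95)

  # oracle + reference-library agreement, label-permutation invariance
  set.seed(62)
  x <- matrix(rnorm(24), 12, 2)
  labels <- rep(1:3, each = 4)
  ours <- silhouette_score(x, labels)
  expect_equal(ours, silhouette_bruteforce(x, labels), tolerance = 1e-12)
  skip_if_not_installed("cluster")
  ref <- mean(cluster::silhouette(labels, dist(x))[, "sil_width"])
  expect_equal(ours, ref, tolerance = 1e-9)
  perm <- c(2, 3, 1)[labels]
  expect_equal(silhouette_score(x, perm), ours)
  expect_error(silhouette_score(x, rep(1, 12)), class = "posturekit_undefined_score")
})

test_that("adjusted Rand agrees with the reference implementation", {
  skip_if_not_installed("mclust")
  set.seed(71)
  for (rep in 1:10) {
    a <- sample(1:3, 40, replace = TRUE)
    b <- sample(1:4, 40, replace = TRUE)
    expect_equal(adjusted_rand(a, b), mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
  expect_equal(adjusted_rand(1:5, rep(1, 5) + c(0, 0, 0, 0, 0)), adjusted_rand(1:5, rep(1, 5)))
})

test_that("the elbow curve is non-increasing with a knee at the true k", {
  set.seed(81)
  x <- rbind(
    matrix(rnorm(80, 0, 0.5), ncol = 2),
    matrix(rnorm(80, 8, 0.5), ncol = 2)
  )
  res <- elbow_curve(x, k_range = 1:6)
  expect_true(all(diff(res$curve$wcss) <= 1e-8))
  expect_equal(res$knee, 2)
  expect_true(res$confident)

  # single blob: shallow curve, low-confidence knee
  y <- matrix(rnorm(200), 100, 2)
  res1 <- elbow_curve(y, k_range = 1:6)
  expect_false(res1$confident)

  # k = n drives WCSS to zero
  z <- matrix(rnorm(12), 6, 2)
  resz <- elbow_curve(z, k_range = c(1, 6))
  expect_equal(resz$curve$wcss[resz$curve$k == 6], 0, tolerance = 1e-9)
})

test_that("cluster-stratified comparison orients CG1 by shoulder-hip difference", {
  set.seed(91)
  n <- 40
  prof <- data.frame(
    subject_id = sprintf("S%02d", 1:n), session = 1,
    sex = rep(c("M", "F"), n / 2), age = 25, height = 170, weight = 65
  )
  for (p in posture_parameters()) prof[[p]] <- rnorm(n, 10)
  grp <- rep(1:2, each = n / 2)
  prof$shoulder_hip_difference <- ifelse(grp == 1, rnorm(n, 85, 5), rnorm(n, 57, 5))
  tab <- cluster_stratified_comparison(prof, grp)
  row <- tab[tab$parameter == "shoulder_hip_difference", ]
  # group 2 (smaller values) must be CG1, so d is positive
  expect_gt(row$d, 0)
  expect_lt(row$mean_cg1, row$mean_cg2)

  # labels identical to sex reduce to the sex comparison
  labels_sex <- as.integer(factor(prof$sex))
  tab2 <- cluster_stratified_comparison(prof, labels_sex)
  sex_tab <- sex_comparison_table(prof)
  m_is_cg1 <- tab2$mean_cg1[1] %in% sex_tab$mean_men[1]
  expect_equal(sort(abs(tab2$d)), sort(abs(sex_tab$d)), tolerance = 1e-12)

  expect_error(cluster_stratified_comparison(prof, rep(1, n)), class = "posturekit_shape_error")
  expect_error(
    cluster_stratified_comparison(prof, c(rep(1, n - 1), 2)),
    class = "posturekit_insufficient_sample"
  )
})
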