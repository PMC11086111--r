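#' Principal component analysis of a posture-profile matrix
#'
#' Eigendecomposition of the covariance structure (`scaling = "none"`,
#' the default, appropriate when pixel-length vectors should dominate) or of
#' the correlation structure (`scaling = "zscore"`). Loading signs follow a
#' deterministic convention: within each component the largest-magnitude
#' loading is positive.
#'
#' @param x Numeric matrix or data frame, subjects x parameters, no missing
#'   values.
#' @param scaling `"none"` (covariance) or `"zscore"` (correlation).
#' @return Object of class `pca_result`: `loadings` (parameters x
#'   components, orthonormal), `variance_ratio`, `scores` (subjects x
#'   components), `center`, `scale`, `scaling`.
#' @export
run_pca <- function(x, scaling = c("none", "zscore")) {
  scaling <- match.arg(scaling)
  x <- as.matrix(x)
  if (anyNA(x)) stop_posturekit("PCA input contains missing values", "completeness_error")
  if (nrow(x) <= 2) stop_posturekit("PCA needs more subjects than components", "insufficient_sample")
  pc <- stats::prcomp(x, center = TRUE, scale. = (scaling == "zscore"))
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  loadings <- sweep(pc$rotation, 2, flip, `*`)
  scores <- sweep(pc$x, 2, flip, `*`)
  structure(
    list(
      loadings = loadings,
      variance_ratio = pc$sdev^2 / sum(pc$sdev^2),
      scores = scores,
      center = pc$center,
      scale = if (scaling == "zscore") pc$scale else NULL,
      scaling = scaling
    ),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf(
    "<pca_result> %d x %d, %s scaling; variance ratios: %s\n",
    nrow(x$scores), ncol(x$scores), x$scaling,
    paste(sprintf("%.3f", utils::head(x$variance_ratio, 4)), collapse = ", ")
  ))
  invisible(x)
}

#' Number of components needed to retain a variance fraction
#'
#' Smallest m whose cumulative explained-variance ratio reaches `retention`.
#'
#' @param x A `pca_result` or a numeric vector of variance ratios.
#' @param retention Fraction of variance to retain, in `(0, 1]`; default
#'   0.90.
#' @return Integer component count.
#' @export
#' @examples
#' select_components(c(0.815, 0.093, 0.060, 0.032), 0.90) # 2
select_components <- function(x, retention = 0.90) {
  ratios <- if (inherits(x, "pca_result")) x$variance_ratio else as.numeric(x)
  if (retention <= 0 || retention > 1) {
    stop_posturekit("retention must lie in (0, 1]", "invalid_input")
  }
  cum <- cumsum(ratios)
  idx <- which(cum >= retention - 1e-12)
  if (length(idx) == 0) length(ratios) else idx[1]
}

#' Cluster subjects in principal-component score space
#'
#' One front end for the five clustering algorithms of the analysis:
#' k-means (seeded multi-restart), mean-shift (bandwidth estimated from the
#' data unless given), and agglomerative Ward / complete / average linkage
#' cut at `k`. Hierarchical methods and k-means require `k`; mean-shift
#' discovers the cluster count from the bandwidth.
#'
#' @param scores Numeric matrix, subjects x dimensions (typically retained
#'   PCA scores).
#' @param method One of `"kmeans"`, `"meanshift"`, `"ward"`, `"complete"`,
#'   `"average"`.
#' @param k Number of clusters (ignored by mean-shift).
#' @param bandwidth Mean-shift bandwidth; `NULL` for the quantile estimate.
#' @param nstart Restarts for k-means.
#' @param seed RNG seed used for k-means restarts (default 20230315).
#' @return Object of class `cluster_result`: `method`, `labels`,
#'   `n_clusters`, `silhouette` (NA when fewer than 2 clusters), `params`.
#' @export
cluster_scores <- function(scores, method = c("kmeans", "meanshift", "ward", "complete", "average"),
                           k = 2L, bandwidth = NULL, nstart = 10L, seed = 20230315L) {
  method <- match.arg(method)
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (n < 3) stop_posturekit("clustering needs at least 3 points", "insufficient_sample")
  params <- list()
  if (method == "meanshift") {
    ms <- mean_shift(scores, bandwidth = bandwidth)
    labels <- ms$labels
    params$bandwidth <- ms$bandwidth
  } else {
    if (k > n) stop_posturekit("fewer points than requested clusters", "infeasible_k")
    if (method == "kmeans") {
      if (nrow(unique(scores)) < k) {
        stop_posturekit("fewer distinct points than requested clusters", "infeasible_k")
      }
      labels <- with_seed(seed, {
        stats::kmeans(scores, centers = k, nstart = nstart, iter.max = 100)$cluster
      })
      params$k <- k
      params$nstart <- nstart
      params$seed <- seed
    } else {
      hc_method <- c(ward = "ward.D2", complete = "complete", average = "average")[[method]]
      hc <- stats::hclust(stats::dist(scores), method = hc_method)
      labels <- stats::cutree(hc, k = k)
      params$k <- k
    }
  }
  labels <- as.integer(labels)
  n_clusters <- length(unique(labels))
  sil <- if (n_clusters >= 2) silhouette_score(scores, labels) else NA_real_
  structure(
    list(
      method = method, labels = labels, n_clusters = n_clusters,
      silhouette = sil, params = params
    ),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf(
    "<cluster_result> %s: %d clusters, silhouette %.3f\n",
    x$method, x$n_clusters, x$silhouette
  ))
  invisible(x)
}

#' Mean-shift clustering with a flat kernel
#'
#' Mode-seeking clustering: every point is iteratively shifted to the mean
#' of the points within `bandwidth` until convergence; converged modes
#' closer than `bandwidth` are merged and points take the label of their
#' mode. When `bandwidth` is `NULL` it is estimated from the data as the
#' mean, over points, of the distance to their `ceiling(quantile * n)`-th
#' nearest neighbour (quantile rule, default 0.3).
#'
#' @param x Numeric matrix, points x dimensions.
#' @param bandwidth Kernel radius; `NULL` to estimate.
#' @param quantile Quantile for the bandwidth estimate.
#' @param max_iter,tol Convergence controls for the shift iteration.
#' @return List: `labels` (integer, 1-based, ordered by decreasing cluster
#'   size), `modes` (matrix of cluster modes), `bandwidth`.
#' @export
mean_shift <- function(x, bandwidth = NULL, quantile = 0.3, max_iter = 300L, tol = 1e-6) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (is.null(bandwidth)) bandwidth <- estimate_bandwidth(x, quantile)
  if (bandwidth <= 0) {
    # degenerate data (all points identical): one cluster
    return(list(labels = rep(1L, n), modes = x[1, , drop = FALSE], bandwidth = bandwidth))
  }
  shifted <- x
  active <- rep(TRUE, n)
  for (iter in seq_len(max_iter)) {
    if (!any(active)) break
    d2 <- cross_dist2(shifted[active, , drop = FALSE], x)
    within <- d2 <= bandwidth^2
    # every point is within bandwidth of itself, so rows are non-empty
    new_pts <- (within %*% x) / rowSums(within)
    moved <- sqrt(rowSums((new_pts - shifted[active, , drop = FALSE])^2))
    shifted[active, ] <- new_pts
    idx <- which(active)
    active[idx[moved < tol]] <- FALSE
  }
  # mode post-processing: rank candidate modes by their support (points
  # within one bandwidth), greedily keep the strongest mode of each
  # bandwidth-sized neighbourhood, then assign every point to its nearest
  # surviving mode
  support <- rowSums(cross_dist2(shifted, x) <= bandwidth^2)
  ord <- order(-support, seq_len(n))
  modes <- matrix(numeric(0), 0, ncol(x))
  for (i in ord) {
    if (nrow(modes) > 0) {
      dm <- sqrt(rowSums(sweep(modes, 2, shifted[i, ])^2))
      if (any(dm < bandwidth)) next
    }
    modes <- rbind(modes, shifted[i, ])
  }
  d_modes <- cross_dist2(x, modes)
  labels <- max.col(-d_modes, ties.method = "first")
  # drop empty modes, then relabel by decreasing cluster size (ties by
  # mode rank) for determinism
  used <- sort(unique(labels))
  modes <- modes[used, , drop = FALSE]
  labels <- match(labels, used)
  sizes <- tabulate(labels, nbins = nrow(modes))
  new_order <- order(-sizes, seq_along(sizes))
  rank_of <- integer(length(new_order))
  rank_of[new_order] <- seq_along(new_order)
  labels <- rank_of[labels]
  modes <- modes[new_order, , drop = FALSE]
  list(labels = labels, modes = modes, bandwidth = bandwidth)
}

#' Bandwidth estimate for mean-shift
#'
#' Mean over points of the distance to the `ceiling(quantile * (n - 1))`-th
#' nearest neighbour.
#'
#' @param x Numeric matrix, points x dimensions.
#' @param quantile Neighbourhood quantile in (0, 1].
#' @return Bandwidth (0 when all points coincide).
#' @export
estimate_bandwidth <- function(x, quantile = 0.3) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2) {
    return(0)
  }
  d <- as.matrix(stats::dist(x))
  kth <- max(1L, ceiling(quantile * (n - 1)))
  # sorted row includes the self-distance 0 first, so the kth neighbour is
  # at position kth + 1
  mean(apply(d, 1, function(row) sort(row)[kth + 1]))
}

cross_dist2 <- function(a, b) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, `+`) - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

#' Mean silhouette score of a clustering
#'
#' Per point, `(b - a) / max(a, b)` with Euclidean distances, where `a` is
#' the mean distance to the point's own cluster (excluding itself) and `b`
#' the smallest mean distance to another cluster; points in singleton
#' clusters score 0 by convention. The score is the mean over points.
#'
#' @param x Numeric matrix, points x dimensions.
#' @param labels Cluster labels (any type; at least 2 distinct).
#' @return Mean silhouette in `[-1, 1]`.
#' @export
silhouette_score <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.vector(labels)
  ulab <- unique(labels)
  if (length(ulab) < 2) {
    stop_posturekit("silhouette undefined for a single cluster", "undefined_score")
  }
  if (any(table(labels) == 0)) stop_posturekit("empty cluster", "undefined_score")
  d <- as.matrix(stats::dist(x))
  n <- nrow(x)
  s <- numeric(n)
  sizes <- table(labels)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    n_own <- sizes[[as.character(labels[i])]]
    if (n_own == 1) {
      s[i] <- 0
      next
    }
    a <- sum(d[i, own]) / (n_own - 1)
    b <- min(vapply(
      ulab[ulab != labels[i]],
      function(l) mean(d[i, labels == l]), 0
    ))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Within-cluster sum of squares over a k range (elbow curve)
#'
#' Multi-restart k-means WCSS per k, with the knee located at the maximum
#' second difference of the curve. A knee is flagged low-confidence when
#' the curvature at the knee is small relative to the total WCSS drop.
#'
#' @param scores Numeric matrix, points x dimensions.
#' @param k_range Integer vector of k values (default `1:8`, truncated to
#'   `n - 1`).
#' @param nstart,seed k-means controls.
#' @return List: `curve` (data frame `k`, `wcss`), `knee` (estimated k),
#'   `confident` (logical).
#' @export
elbow_curve <- function(scores, k_range = 1:8, nstart = 10L, seed = 20230315L) {
  scores <- as.matrix(scores)
  k_range <- k_range[k_range >= 1 & k_range <= nrow(scores)]
  wcss <- with_seed(seed, vapply(k_range, function(k) {
    if (k == 1) {
      sum(sweep(scores, 2, colMeans(scores))^2)
    } else if (k >= nrow(scores)) {
      0 # every point its own center
    } else {
      stats::kmeans(scores, centers = k, nstart = nstart, iter.max = 100)$tot.withinss
    }
  }, 0))
  knee <- NA_integer_
  confident <- FALSE
  if (length(k_range) >= 3) {
    d2 <- diff(diff(wcss)) # second difference; positive at a convex knee
    i <- which.max(d2) + 1L
    knee <- k_range[i]
    # confident when the drop into the knee dwarfs everything still to gain
    num <- wcss[i - 1] - wcss[i]
    den <- wcss[i] - min(wcss) + 1e-12
    confident <- num > 2 * den
  }
  list(curve = data.frame(k = k_range, wcss = wcss), knee = knee, confident = confident)
}

#' Cluster-stratified comparison of all postural parameters
#'
#' Re-runs the two-group inferential layer between the two discovered
#' posture clusters. The cluster with the smaller mean shoulder-hip
#' difference is labeled CG1 (matching the published orientation), and d is
#' signed as CG2 minus CG1.
#'
#' @param profiles Profile table from [profile_cohort()] (one session).
#' @param labels Cluster labels aligned with `profiles` rows; exactly 2
#'   distinct values.
#' @param welch,holm Options forwarded to [compare_groups()].
#' @return Data frame in the same layout as [sex_comparison_table()], with
#'   groups `cg1`/`cg2`.
#' @export
cluster_stratified_comparison <- function(profiles, labels, welch = FALSE, holm = FALSE) {
  ulab <- unique(labels)
  if (length(ulab) != 2) {
    stop_posturekit("cluster-stratified comparison requires exactly 2 clusters", "shape_error")
  }
  if (min(table(labels)) < 3) {
    stop_posturekit("each cluster needs at least 3 subjects", "insufficient_sample")
  }
  m1 <- mean(profiles$shoulder_hip_difference[labels == ulab[1]], na.rm = TRUE)
  m2 <- mean(profiles$shoulder_hip_difference[labels == ulab[2]], na.rm = TRUE)
  cg1 <- if (m1 <= m2) ulab[1] else ulab[2]
  cg2 <- setdiff(ulab, cg1)
  comparison_table(
    profiles[labels == cg1, , drop = FALSE],
    profiles[labels == cg2, , drop = FALSE],
    labels = c("cg1", "cg2"), welch = welch, holm = holm
  )
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same points:
#' 1 for identical partitions (up to label permutation), ~0 for independent
#' ones.
#'
#' @param a,b Label vectors of equal length.
#' @return Adjusted Rand index.
#' @export
adjusted_rand <- function(a, b) {
  if (length(a) != length(b)) stop_posturekit("partitions differ in length", "invalid_input")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) {
    return(ifelse(sum_ij == expected, 1, 0))
  }
  (sum_ij - expected) / (max_index - expected)
}

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
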