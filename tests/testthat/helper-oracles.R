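# Brute-force reference implementations, deliberately naive (explicit
# loops, no shared code with the package internals), used as oracles on
# small instances.

# silhouette: direct per-point double loop
silhouette_bruteforce <- function(x, labels) {
  x <- as.matrix(x)
  n <- nrow(x)
  dd <- function(i, j) sqrt(sum((x[i, ] - x[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    same <- setdiff(which(labels == labels[i]), i)
    if (length(same) == 0) {
      s[i] <- 0
      next
    }
    a <- mean(vapply(same, function(j) dd(i, j), 0))
    b <- Inf
    for (l in setdiff(unique(labels), labels[i])) {
      others <- which(labels == l)
      b <- min(b, mean(vapply(others, function(j) dd(i, j), 0)))
    }
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# ICC(3,k): textbook two-way ANOVA with explicit sums
icc_3k_bruteforce <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  grand <- mean(m)
  ss_rows <- 0
  for (i in seq_len(n)) ss_rows <- ss_rows + k * (mean(m[i, ]) - grand)^2
  ss_cols <- 0
  for (j in seq_len(k)) ss_cols <- ss_cols + n * (mean(m[, j]) - grand)^2
  ss_tot <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) ss_tot <- ss_tot + (m[i, j] - grand)^2
  msr <- ss_rows / (n - 1)
  mse <- (ss_tot - ss_rows - ss_cols) / ((n - 1) * (k - 1))
  (msr - mse) / msr
}

# naive agglomerative clustering; linkage in {ward, complete, average}.
# Returns the partition at k clusters.
agglomerate_bruteforce <- function(x, k, linkage) {
  x <- as.matrix(x)
  clusters <- as.list(seq_len(nrow(x)))
  cluster_dist <- function(a, b) {
    if (linkage == "complete") {
      max(apply(x[a, , drop = FALSE], 1, function(p) {
        apply(x[b, , drop = FALSE], 1, function(q) sqrt(sum((p - q)^2)))
      }))
    } else if (linkage == "average") {
      mean(apply(x[a, , drop = FALSE], 1, function(p) {
        apply(x[b, , drop = FALSE], 1, function(q) sqrt(sum((p - q)^2)))
      }))
    } else { # ward: SSE increase of the merge
      ca <- colMeans(x[a, , drop = FALSE])
      cb <- colMeans(x[b, , drop = FALSE])
      (length(a) * length(b)) / (length(a) + length(b)) * sum((ca - cb)^2)
    }
  }
  while (length(clusters) > k) {
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        dij <- cluster_dist(clusters[[i]], clusters[[j]])
        if (dij < best_d) {
          best_d <- dij
          best <- c(j, i)
        }
      }
    }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1L]] <- merged
  }
  labels <- integer(nrow(x))
  for (i in seq_along(clusters)) labels[clusters[[i]]] <- i
  labels
}
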