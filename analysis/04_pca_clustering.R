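#!/usr/bin/env Rscript

# Stage 4: dimensionality reduction and cluster discovery.
#
# Covariance PCA of the session-1 profiles, component retention at 90%
# explained variance, the five clustering algorithms (k-means, mean-shift,
# Ward / complete / average linkage) in the retained score space, elbow
# and silhouette model selection, and the cluster-stratified re-comparison
# of every parameter oriented so CG1 is the narrow-shoulder cluster.
# Writes PCA, clustering, and comparison tables under results/.

suppressMessages(library(posturekit))

profiles <- utils::read.csv("results/profiles.csv", stringsAsFactors = FALSE)
names(profiles) <- sub("\\.(deg|pd)$", "", names(profiles))
s1 <- profiles[profiles$session == 1, ]

x <- as.matrix(s1[posture_parameters()])
rownames(x) <- s1$subject_id
pca <- run_pca(x, scaling = "none")
m <- select_components(pca, 0.90)
cat(sprintf(
  "variance ratios: %s -> %d components retained at 90%%\n",
  paste(sprintf("%.3f", pca$variance_ratio[1:4]), collapse = ", "), m
))
utils::write.csv(
  data.frame(component = seq_along(pca$variance_ratio), variance_ratio = pca$variance_ratio),
  "results/pca_variance.csv",
  row.names = FALSE
)
scores <- pca$scores[, seq_len(m), drop = FALSE]
utils::write.csv(
  data.frame(subject_id = rownames(scores), scores),
  "results/pca_scores.csv",
  row.names = FALSE
)

elbow <- elbow_curve(scores)
cat(sprintf("elbow: knee at k = %d (confident: %s)\n", elbow$knee, elbow$confident))

methods <- c("kmeans", "meanshift", "ward", "complete", "average")
clusterings <- lapply(methods, function(meth) cluster_scores(scores, method = meth, k = 2))
names(clusterings) <- methods
for (meth in methods) {
  cl <- clusterings[[meth]]
  cat(sprintf("  %-9s k=%d silhouette=%.3f\n", meth, cl$n_clusters, cl$silhouette))
}
labels_df <- do.call(rbind, lapply(methods, function(meth) {
  data.frame(subject_id = s1$subject_id, method = meth, cluster = clusterings[[meth]]$labels)
}))
utils::write.csv(labels_df, "results/cluster_labels.csv", row.names = FALSE)

sils <- vapply(clusterings, function(cl) cl$silhouette, 0)
best <- names(which.max(sils))
cat(sprintf("best method by silhouette: %s (%.3f)\n", best, max(sils)))

labels <- clusterings[[best]]$labels
if (length(unique(labels)) == 2) {
  tab <- cluster_stratified_comparison(s1, labels)
  utils::write.csv(tab, "results/cluster_comparison.csv", row.names = FALSE)
  vec <- tab[tab$group == "vector_lengths", ]
  cat("cluster comparison, vector lengths:\n")
  print(vec[c("parameter", "mean_cg1", "sd_cg1", "mean_cg2", "sd_cg2", "p_value", "stars", "d")],
        row.names = FALSE, digits = 3)
  # sex composition of the clusters: the split is not a sex split
  comp <- table(s1$sex, labels)
  cat("sex composition by cluster:\n")
  print(comp)
} else {
  cat(sprintf("best method found %d clusters; no stratified table\n", length(unique(labels))))
}
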