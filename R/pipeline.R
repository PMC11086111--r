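#' Run the full posture-analysis replica
#'
#' Orchestrates every stage of the analysis over a cohort: profile
#' extraction, sex comparison with effect sizes, height correlations,
#' test-retest reliability (when a second session is present), covariance
#' (or correlation) PCA with variance-retention component selection, the
#' five clustering algorithms with silhouette/elbow model selection, and
#' the cluster-stratified re-comparison. All tables are written as CSV
#' under `out_dir`, along with a JSON run manifest (seed, configuration,
#' per-stage status and timing).
#'
#' @param x A [cohort()] with captures, or the list returned by
#'   [generate_cohort()].
#' @param out_dir Output directory (created if missing); `NULL` to skip
#'   writing files.
#' @param min_visibility Landmark visibility threshold for the geometry.
#' @param welch,holm Statistical options forwarded to the comparisons.
#' @param scaling PCA scaling mode (`"none"` = covariance, the default).
#' @param retention Variance fraction the retained components must reach.
#' @param methods Clustering algorithms to run.
#' @param k Cluster count for the fixed-k methods.
#' @param seed Seed for the seeded clustering stages.
#' @return List of class `posture_run`: `profiles`, `sex_table`,
#'   `correlations`, `reliability`, `pca`, `n_components`, `clusterings`,
#'   `best_method`, `elbow`, `cluster_table`, `manifest`.
#' @export
run_full_analysis <- function(x, out_dir = NULL, min_visibility = 0.5,
                              welch = FALSE, holm = FALSE,
                              scaling = c("none", "zscore"), retention = 0.90,
                              methods = c("kmeans", "meanshift", "ward", "complete", "average"),
                              k = 2L, seed = 20230315L) {
  scaling <- match.arg(scaling)
  if (retention <= 0 || retention > 1) {
    stop_posturekit("retention must lie in (0, 1]", "invalid_input")
  }
  cohort_obj <- if (inherits(x, "posture_cohort")) x else x$cohort
  stages <- list()
  result <- list()
  t_all <- proc.time()[["elapsed"]]
  run_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) e)
    stages[[name]] <<- list(
      status = if (inherits(out, "error")) "failed" else "ok",
      seconds = round(proc.time()[["elapsed"]] - t0, 3),
      error = if (inherits(out, "error")) conditionMessage(out) else NULL
    )
    if (inherits(out, "error")) stop(out)
    out
  }

  profiles <- run_stage("profiles", profile_cohort(cohort_obj, min_visibility = min_visibility))
  s1 <- profiles[profiles$session == 1, , drop = FALSE]

  result$sex_table <- run_stage(
    "sex_comparison",
    if (all(is.na(s1$sex))) NULL else sex_comparison_table(profiles, welch = welch, holm = holm)
  )
  result$correlations <- run_stage(
    "height_correlations",
    if (all(is.na(s1$height))) NULL else height_correlations(profiles)
  )
  result$reliability <- run_stage(
    "reliability",
    if (sum(profiles$session == 2) >= 3) reliability_table(profiles) else NULL
  )

  params <- intersect(posture_parameters(), names(s1))
  complete_params <- params[colSums(is.na(s1[params])) == 0]
  mat <- as.matrix(s1[complete_params])
  rownames(mat) <- s1$subject_id
  pca <- run_stage("pca", run_pca(mat, scaling = scaling))
  m <- select_components(pca, retention)
  scores <- pca$scores[, seq_len(m), drop = FALSE]

  clusterings <- run_stage("clustering", {
    out <- lapply(methods, function(meth) {
      cluster_scores(scores, method = meth, k = k, seed = seed)
    })
    names(out) <- methods
    out
  })
  sils <- vapply(clusterings, function(cl) {
    if (is.na(cl$silhouette)) -Inf else cl$silhouette
  }, 0)
  best <- names(which.max(sils))
  result$elbow <- run_stage("elbow", elbow_curve(scores, seed = seed))
  result$cluster_table <- run_stage("cluster_comparison", {
    labels <- clusterings[[best]]$labels
    if (length(unique(labels)) == 2 && min(table(labels)) >= 3) {
      cluster_stratified_comparison(s1, labels, welch = welch, holm = holm)
    } else {
      NULL
    }
  })

  result$profiles <- profiles
  result$pca <- pca
  result$n_components <- m
  result$clusterings <- clusterings
  result$best_method <- best

  manifest <- list(
    package_version = as.character(utils::packageVersion("posturekit")),
    seed = seed,
    config = list(
      min_visibility = min_visibility, welch = welch, holm = holm,
      scaling = scaling, retention = retention, methods = methods, k = k
    ),
    n_subjects = length(cohort_obj$subjects),
    n_components = m,
    variance_ratio = round(pca$variance_ratio, 6),
    silhouettes = lapply(clusterings, function(cl) cl$silhouette),
    n_clusters = lapply(clusterings, function(cl) cl$n_clusters),
    best_method = best,
    elbow_knee = result$elbow$knee,
    stages = stages,
    seconds_total = round(proc.time()[["elapsed"]] - t_all, 3)
  )
  result$manifest <- manifest

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_profiles(profiles, file.path(out_dir, "profiles.csv"))
    if (!is.null(result$sex_table)) {
      utils::write.csv(result$sex_table, file.path(out_dir, "sex_comparison.csv"), row.names = FALSE)
    }
    if (!is.null(result$correlations)) {
      utils::write.csv(result$correlations, file.path(out_dir, "height_correlations.csv"), row.names = FALSE)
    }
    if (!is.null(result$reliability)) {
      utils::write.csv(result$reliability, file.path(out_dir, "reliability.csv"), row.names = FALSE)
    }
    utils::write.csv(
      data.frame(component = seq_along(pca$variance_ratio), variance_ratio = pca$variance_ratio),
      file.path(out_dir, "pca_variance.csv"),
      row.names = FALSE
    )
    scores_df <- data.frame(subject_id = rownames(pca$scores), pca$scores[, seq_len(m), drop = FALSE])
    utils::write.csv(scores_df, file.path(out_dir, "pca_scores.csv"), row.names = FALSE)
    labels_df <- do.call(rbind, lapply(names(clusterings), function(meth) {
      data.frame(
        subject_id = s1$subject_id, method = meth,
        cluster = clusterings[[meth]]$labels, stringsAsFactors = FALSE
      )
    }))
    utils::write.csv(labels_df, file.path(out_dir, "cluster_labels.csv"), row.names = FALSE)
    if (!is.null(result$cluster_table)) {
      utils::write.csv(result$cluster_table, file.path(out_dir, "cluster_comparison.csv"), row.names = FALSE)
    }
    jsonlite::write_json(
      manifest, file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
    )
  }
  structure(result, class = "posture_run")
}

#' @export
print.posture_run <- function(x, ...) {
  cat(sprintf(
    "<posture_run> %d profile rows; %d components retained; best clustering: %s (silhouette %.3f, %d clusters)\n",
    nrow(x$profiles), x$n_components, x$best_method,
    x$clusterings[[x$best_method]]$silhouette,
    x$clusterings[[x$best_method]]$n_clusters
  ))
  invisible(x)
}
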