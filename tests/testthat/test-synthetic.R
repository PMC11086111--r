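test_that("degenerate spec with zero SDs reproduces the group means exactly", {
  ref <- reference_sex_table()
  at <- ref[!ref$parameter %in% posture_parameters("vectors"),
            c("parameter", "men_mean", "men_sd", "women_mean", "women_sd")]
  at$men_sd <- 0
  at$women_sd <- 0
  cl <- reference_cluster_table()
  vt <- cl[cl$parameter %in% posture_parameters("vectors"),
           c("parameter", "cg1_mean", "cg1_sd", "cg2_mean", "cg2_sd")]
  vt$cg1_sd <- 0
  vt$cg2_sd <- 0
  spec <- synthetic_spec(
    n_subjects = 12, angle_table = at, vector_table = vt,
    target_icc = stats::setNames(rep(1, 22), posture_parameters()),
    jitter_sd = 0, n_retest = 0
  )
  set.seed(1)
  truth <- sample_parameters(spec)
  for (i in seq_len(12)) {
    sex <- truth$subjects$sex[i]
    mcol <- if (sex == "M") "men_mean" else "women_mean"
    expect_equal(unname(truth$profile[i, at$parameter]), at[[mcol]], ignore_attr = TRUE)
    ccol <- if (truth$subjects$cluster[i] == 1) "cg1_mean" else "cg2_mean"
    expect_equal(unname(truth$profile[i, vt$parameter]), vt[[ccol]], ignore_attr = TRUE)
  }
  # target ICC 1: both sessions equal the truth
  expect_equal(truth$sessions[["1"]], truth$profile)
  expect_equal(truth$sessions[["2"]], truth$profile)
})

test_that("sampled parameters land on the configured population moments", {
  spec <- synthetic_spec(n_subjects = 5000, n_retest = 0)
  set.seed(2024)
  truth <- sample_parameters(spec)
  men <- truth$subjects$sex == "M"
  # men's hip adduction mean: 9.9 +/- 2.2 over ~2100 men
  expect_equal(mean(truth$profile[men, "hip_adduction"]), 9.9, tolerance = 0.1 / 9.9)
  # height-torso correlation hits the copula target
  r <- cor(truth$subjects$height, truth$profile[, "torso_vector"])
  expect_equal(r, spec$height_corr, tolerance = 0.05 / 0.5)
  # per-sex height marginals are preserved despite the coupling
  expect_equal(mean(truth$subjects$height[men]), 175, tolerance = 0.5 / 175)
  expect_equal(sd(truth$subjects$height[men]), 6.4, tolerance = 0.05)
  # cluster membership is independent of sex
  tab <- table(truth$subjects$sex, truth$subjects$cluster)
  expect_gt(chisq.test(tab)$p.value, 0.01)
})

test_that("infeasible correlation targets are rejected", {
  expect_error(
    {
      spec <- synthetic_spec(n_subjects = 2, height_corr = 0.99, n_retest = 0)
      set.seed(1)
      sample_parameters(spec)
    },
    class = "posturekit_spec_error"
  )
})

test_that("inverse Spearman-Brown and the session-noise calibration are exact", {
  expect_equal(inverse_spearman_brown(0.95, 2), 0.9048, tolerance = 1e-4)
  # round trip: step the single-measure value back up
  icc1 <- inverse_spearman_brown(0.85, 2)
  expect_equal(2 * icc1 / (1 + icc1), 0.85)
  # calibrated noise yields the target consistency ICC in expectation:
  # sigma_e^2 = 2 sigma_b^2 (1 - t)/t  =>  sigma_b^2/(sigma_b^2 + sigma_e^2/2) = t
  for (t in c(0.7, 0.85, 0.95)) {
    se <- icc_session_noise_sd(1.3, t)
    expect_equal(1.3^2 / (1.3^2 + se^2 / 2), t, tolerance = 1e-12)
  }
  expect_error(icc_session_noise_sd(1, 0), class = "posturekit_spec_error")
})

test_that("make_retest recovers target ICCs in parameter space", {
  spec <- synthetic_spec(n_subjects = 90, n_retest = 90)
  set.seed(314)
  # shoulder adduction (mean ~15: folding never triggers) at three targets;
  # a fresh cohort per replicate so the sampled between-subject variance
  # averages out
  for (t in c(0.70, 0.85, 0.95)) {
    est <- replicate(30, {
      truth <- sample_parameters(spec)
      sess <- make_retest(truth, spec, target_icc = stats::setNames(
        rep(t, 22), posture_parameters()
      ))
      icc_3k(cbind(
        sess[["1"]][, "shoulder_adduction"],
        sess[["2"]][, "shoulder_adduction"]
      ))
    })
    expect_equal(mean(est), t, tolerance = 0.03 / t)
  }
})

test_that("per-parameter reliability tracks the calibration targets at n = 90", {
  spec <- synthetic_spec(n_subjects = 90, n_retest = 90)
  set.seed(808)
  truth <- sample_parameters(spec)
  prof <- do.call(rbind, lapply(c(1L, 2L), function(s) {
    data.frame(
      subject_id = rownames(truth$sessions[[s]]), session = s,
      sex = truth$subjects$sex, age = truth$subjects$age,
      height = truth$subjects$height, weight = truth$subjects$weight,
      as.data.frame(truth$sessions[[s]]), stringsAsFactors = FALSE
    )
  }))
  rel <- reliability_table(prof)
  dev <- rel$icc_3k - spec$target_icc[rel$parameter]
  # near-zero line parameters are attenuated by the fold at zero; the bulk
  # of the parameters sit on their targets
  expect_gte(sum(abs(dev) <= 0.05), 15)
  expect_true(all(rel$icc_3k > 0.55 & rel$icc_3k <= 1))
  expect_equal(rel$mdc95 / rel$sem, rep(1.96 * sqrt(2), nrow(rel)))
})

test_that("the skeleton solver inverts the geometry exactly at zero jitter", {
  spec <- synthetic_spec()
  set.seed(99)
  mu <- (function() {
    ref <- reference_sex_table()
    w <- spec$sex_ratio
    prof <- stats::setNames(numeric(22), posture_parameters())
    for (i in seq_len(nrow(ref))) {
      p <- ref$parameter[i]
      prof[p] <- w * ref$men_mean[i] + (1 - w) * ref$women_mean[i]
    }
    cl <- reference_cluster_table()
    for (p in posture_parameters("vectors")) {
      j <- match(p, cl$parameter)
      prof[p] <- (cl$cg1_mean[j] + cl$cg2_mean[j]) / 2
    }
    prof
  })()
  pts <- solve_skeleton(mu)
  rec <- subject_record("chk", captures = lapply(
    c("frontal", "dorsal", "lateral"),
    function(v) project_skeleton(pts, v, spec$skeleton, subject_id = "chk")
  ))
  achieved <- quiet_profile(rec, 1)
  expect_lt(max(abs(achieved - mu)), 1e-7)
})

test_that("synthesized captures carry landmark jitter of the requested scale", {
  spec <- synthetic_spec()
  mu <- parameter_population_sd(spec) # any valid-ish profile will not do; use means
  prof <- stats::setNames(numeric(22), posture_parameters())
  ref <- reference_sex_table()
  for (i in seq_len(nrow(ref))) {
    prof[ref$parameter[i]] <- (ref$men_mean[i] + ref$women_mean[i]) / 2
  }
  cl <- reference_cluster_table()
  for (p in posture_parameters("vectors")) {
    j <- match(p, cl$parameter)
    prof[p] <- (cl$cg1_mean[j] + cl$cg2_mean[j]) / 2
  }
  set.seed(7)
  cap0 <- synthesize_capture(prof, "frontal", jitter_sd = 0)
  set.seed(7)
  cap2 <- synthesize_capture(prof, "frontal", jitter_sd = 2)
  dev <- cap2$landmarks$x - cap0$landmarks$x
  expect_gt(sd(dev), 0.8)
  expect_lt(sd(dev), 4)
})

test_that("cohort generation is bit-reproducible from the seed", {
  spec <- synthetic_spec(n_subjects = 4, jitter_sd = 1.0, n_retest = 2)
  g1 <- generate_cohort(spec, seed = 7)
  g2 <- generate_cohort(spec, seed = 7)
  expect_identical(g1$truth, g2$truth)
  p1 <- tempfile(fileext = ".csv")
  p2 <- tempfile(fileext = ".csv")
  write_captures(g1$cohort, p1)
  write_captures(g2$cohort, p2)
  expect_identical(readLines(p1), readLines(p2))
  g3 <- generate_cohort(spec, seed = 8)
  expect_false(identical(g1$truth$profile, g3$truth$profile))
})

test_that("zero-jitter cohorts profile back to their session ground truth", {
  g <- small_cohort()
  prof <- suppressWarnings(profile_cohort(g$cohort))
  m <- as.matrix(prof[prof$session == 1, posture_parameters()])
  rownames(m) <- prof$subject_id[prof$session == 1]
  truth <- g$truth$sessions[["1"]][rownames(m), ]
  expect_lt(max(abs(m - truth)), 1e-6)
})

test_that("landmark jitter degrades parameter recovery monotonically", {
  spec <- synthetic_spec(n_subjects = 1, n_retest = 0)
  ref <- reference_sex_table()
  prof <- stats::setNames(numeric(22), posture_parameters())
  for (i in seq_len(nrow(ref))) prof[ref$parameter[i]] <- ref$men_mean[i]
  cl <- reference_cluster_table()
  for (p in posture_parameters("vectors")) {
    prof[p] <- cl$cg2_mean[match(p, cl$parameter)]
  }
  set.seed(123)
  pts <- solve_skeleton(prof)
  err_at <- function(sd_px, reps) {
    mean(replicate(reps, {
      rec <- subject_record("J", captures = lapply(
        c("frontal", "dorsal", "lateral"),
        function(v) project_skeleton(pts, v, spec$skeleton, "J", jitter_sd = sd_px)
      ))
      abs(quiet_profile(rec, 1)[["shoulder_adduction"]] - prof[["shoulder_adduction"]])
    }))
  }
  e2 <- err_at(2, 60)
  e1 <- err_at(1, 60)
  expect_lt(e2, 1.5)
  expect_lt(e1, e2)
})
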