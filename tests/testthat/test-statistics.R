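test_that("the Shapiro-Wilk gate separates normal from skewed samples", {
  set.seed(101)
  norm_pass <- mean(replicate(100, normality_gate(rnorm(200))$is_normal))
  expect_gte(norm_pass, 0.90)
  exp_fail <- mean(replicate(100, !normality_gate(rexp(200))$is_normal))
  expect_gte(exp_fail, 0.95)
  expect_error(normality_gate(c(1, 2)), class = "posturekit_insufficient_sample")
  expect_error(normality_gate(rep(3, 10)), class = "posturekit_insufficient_variance")
})

test_that("Cohen's d uses the average-variance denominator and published cells recompute", {
  # printed cluster-table cells reproduce the printed effect sizes
  expect_equal(cohens_d(4.8, 2.6, 6.3, 3.4), 0.50, tolerance = 0.005 / 0.5)
  expect_equal(cohens_d(57.5, 7.0, 86.6, 10.7), 3.21, tolerance = 0.02 / 3.21)
  expect_equal(cohens_d(5, 2, 5, 3), 0)
  expect_error(cohens_d(1, 0, 2, 0), class = "posturekit_undefined_effect")

  # antisymmetry and affine invariance
  set.seed(5)
  for (i in 1:20) {
    m <- rnorm(2, 10, 3)
    s <- runif(2, 0.5, 2)
    expect_equal(cohens_d(m[1], s[1], m[2], s[2]), -cohens_d(m[2], s[2], m[1], s[1]))
    a <- runif(1, 0.1, 5)
    b <- rnorm(1)
    expect_equal(
      cohens_d(a * m[1] + b, a * s[1], a * m[2] + b, a * s[2]),
      cohens_d(m[1], s[1], m[2], s[2]),
      tolerance = 1e-12
    )
  }
})

test_that("group comparison gates the test choice and attaches the effect size", {
  x <- c(1.2, 1.9, 2.4, 3.1, 2.2, 1.7, 2.8, 2.1)
  same <- compare_groups(x, x)
  expect_gt(same$p_value, 0.9)
  expect_equal(same$cohens_d, 0)
  expect_equal(same$test, "student_t")

  set.seed(42)
  skew <- compare_groups(rexp(100), rexp(100) + 1)
  expect_equal(skew$test, "mann_whitney_u")

  set.seed(43)
  hits <- replicate(100, {
    cmp <- compare_groups(rnorm(100), rnorm(100, 1))
    cmp$p_value < 0.001 && cmp$cohens_d > 0.7 && cmp$cohens_d < 1.3
  })
  expect_gte(mean(hits), 0.95)
})

test_that("height correlations follow the p < 0.05 and r > 0.45 relevance rule", {
  mk_profiles <- function(height, y) {
    df <- data.frame(
      subject_id = sprintf("S%d", seq_along(height)), session = 1,
      sex = "F", age = 25, height = height, weight = 60
    )
    for (p in posture_parameters()) df[[p]] <- y
    df
  }
  hc <- height_correlations(mk_profiles(1:20, 2 * (1:20)))
  expect_true(all(hc$pearson_r == 1))
  expect_true(all(hc$relevant))

  set.seed(9)
  weak <- replicate(50, {
    df <- mk_profiles(rnorm(200, 170, 6), rnorm(200))
    r <- height_correlations(df)
    all(abs(r$pearson_r) < 0.2) && !any(r$relevant)
  })
  expect_gte(mean(weak), 0.95)

  # strong negative correlation is significant but not "relevant" (r > 0.45 is one-sided)
  hneg <- height_correlations(mk_profiles(1:30, -(1:30) + rnorm(30, 0, 0.1)))
  expect_false(any(hneg$relevant))
})

test_that("ICC(3,k) matches its definition on canonical cases", {
  set.seed(3)
  m <- cbind(rnorm(10, 50, 5), 0)
  m[, 2] <- m[, 1]
  expect_equal(icc_3k(m), 1)
  # constant session offset is invisible to the consistency form
  toy <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8), 4, 2, byrow = TRUE)
  expect_equal(icc_3k(toy), 1)
  expect_equal(icc_3k(toy + cbind(rep(0, 4), rep(100, 4))), icc_3k(toy))
  expect_error(icc_3k(matrix(1:4, 2, 2)), class = "posturekit_insufficient_sample")
  expect_error(icc_3k(matrix(c(1, NA, 2, 3, 4, 5), 3, 2)), class = "posturekit_incomplete_design")
})

test_that("ICC recovers simulated variance components and decreases in noise", {
  set.seed(77)
  # target ICC(3,2) = 0.95 via the calibrated session-noise SD
  sigma_e <- icc_session_noise_sd(1, 0.95)
  est <- replicate(100, {
    truth <- rnorm(90)
    icc_3k(cbind(truth + rnorm(90, 0, sigma_e), truth + rnorm(90, 0, sigma_e)))
  })
  expect_gte(mean(est > 0.92 & est < 0.97), 0.90)

  # strictly decreasing in error variance at fixed subject variance
  set.seed(78)
  truth <- rnorm(300)
  iccs <- vapply(c(0.1, 0.3, 0.6, 1, 1.5), function(se) {
    icc_3k(cbind(truth + rnorm(300, 0, se), truth + rnorm(300, 0, se)))
  }, 0)
  expect_true(all(diff(iccs) < 0))
})

test_that("SEM and MDC follow their closed forms and published cells recompute", {
  expect_equal(sem_from_icc(1, 1), 0)
  expect_equal(sem_from_icc(2.5, 0), 2.5)
  expect_equal(sem_from_icc(0.9, 0.94), 0.2205, tolerance = 1e-4 / 0.22)
  expect_error(sem_from_icc(1, 1.2), class = "posturekit_invalid_input")

  expect_equal(mdc95(0.22), 0.61, tolerance = 0.005 / 0.61)
  expect_equal(mdc95(0.89), 2.47, tolerance = 0.005 / 2.47)
  expect_equal(mdc95(0), 0)
  expect_error(mdc95(-1), class = "posturekit_invalid_input")
  # the MDC/SEM ratio is a constant of the definitions
  expect_equal(mdc95(1.37) / 1.37, 1.96 * sqrt(2))
})

test_that("the reliability table spans matched sessions and excludes vectors", {
  set.seed(12)
  n <- 20
  base <- data.frame(
    subject_id = sprintf("S%02d", 1:n), sex = "M", age = 25,
    height = 175, weight = 70
  )
  for (p in posture_parameters()) base[[p]] <- rnorm(n, 10)
  s1 <- cbind(base, session = 1)
  s2 <- cbind(base, session = 2)
  prof <- rbind(s1, s2)
  tab <- reliability_table(prof)
  expect_setequal(tab$parameter, setdiff(posture_parameters(), posture_parameters("vectors")))
  expect_true(all(tab$icc_3k == 1))
  expect_true(all(tab$sem == 0))
  expect_equal(tab$mdc95, tab$sem * 1.96 * sqrt(2))

  # orphan subjects are dropped with a warning
  expect_warning(reliability_table(prof[-1, ]), "without both sessions")
  expect_error(
    reliability_table(prof[prof$subject_id %in% c("S01", "S02"), ]),
    class = "posturekit_insufficient_sample"
  )
})

test_that("sex comparison table reproduces a direct two-group computation", {
  g <- small_cohort()
  set.seed(2)
  prof <- suppressWarnings(profile_cohort(g$cohort))
  # small n: just check structural agreement with compare_groups on one parameter
  tab <- sex_comparison_table(prof)
  p1 <- tab$parameter[1]
  cmp <- compare_groups(
    prof[[p1]][prof$sex == "M"], prof[[p1]][prof$sex == "F"],
    labels = c("men", "women")
  )
  expect_equal(tab$p_value[1], cmp$p_value)
  # the normative table's sign convention is men minus women
  expect_equal(tab$d[1], -cmp$cohens_d)
  expect_equal(tab$mean_men[1], cmp$mean[1])
})
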