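#' Shapiro-Wilk normality gate
#'
#' The inferential layer chooses between Student's t and Mann-Whitney U per
#' parameter and group via this gate: a sample is treated as normal when the
#' Shapiro-Wilk p-value is at least `alpha`.
#'
#' @param values Numeric sample, `n >= 3` (Shapiro-Wilk also requires
#'   `n <= 5000`).
#' @param alpha Gate level, default 0.05.
#' @return List with `W`, `p_value`, `is_normal`.
#' @export
normality_gate <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  if (length(values) < 3) {
    stop_posturekit("normality test needs at least 3 observations", "insufficient_sample")
  }
  if (stats::sd(values) < .Machine$double.eps^0.5) {
    stop_posturekit("normality test undefined for a (near-)constant sample", "insufficient_variance")
  }
  sw <- stats::shapiro.test(values)
  list(W = unname(sw$statistic), p_value = sw$p.value, is_normal = sw$p.value >= alpha)
}

#' Cohen's d with the average-variance denominator
#'
#' `d = (mean_b - mean_a) / sqrt((sd_a^2 + sd_b^2) / 2)`. The denominator is
#' the unweighted average of the two group variances (not the n-weighted
#' pooled SD): this is the form that reproduces the study's printed effect
#' sizes from its printed group means and SDs. Group order is
#' (first-listed, second-listed), so the sign matches the reporting tables.
#'
#' @param mean_a,sd_a First group's mean and SD.
#' @param mean_b,sd_b Second group's mean and SD.
#' @return Signed effect size d.
#' @export
#' @examples
#' cohens_d(4.8, 2.6, 6.3, 3.4) # ~0.50
cohens_d <- function(mean_a, sd_a, mean_b, sd_b) {
  if (any(c(sd_a, sd_b) <= 0) || any(!is.finite(c(sd_a, sd_b)))) {
    stop_posturekit("Cohen's d undefined for non-positive group SDs", "undefined_effect")
  }
  (mean_b - mean_a) / sqrt((sd_a^2 + sd_b^2) / 2)
}

#' Two-group comparison with a normality gate and effect size
#'
#' Student's t (two-sided, pooled variance) when both groups pass the
#' Shapiro-Wilk gate, otherwise Mann-Whitney U; Cohen's d (average-variance
#' denominator, signed b - a) is always attached. Welch's t is available
#' behind `welch = TRUE`.
#'
#' @param a,b Numeric samples (first- and second-listed group), `n >= 3`
#'   each.
#' @param labels Group labels, default `c("a", "b")`.
#' @param welch Use Welch's unequal-variance t instead of the classical
#'   Student form when the gate selects the t-test.
#' @param alpha Normality-gate level.
#' @return List of class `group_comparison`: `labels`, `n`, `mean`, `sd`
#'   (per group), `test` (`"student_t"` or `"mann_whitney_u"`), `statistic`,
#'   `p_value`, `cohens_d`, `normal` (per-group gate results).
#' @export
compare_groups <- function(a, b, labels = c("a", "b"), welch = FALSE, alpha = 0.05) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 3 || length(b) < 3) {
    stop_posturekit("both groups need at least 3 observations", "insufficient_sample")
  }
  if (stats::sd(a) < .Machine$double.eps^0.5 && stats::sd(b) < .Machine$double.eps^0.5) {
    if (isTRUE(all.equal(mean(a), mean(b)))) {
      # identical constant groups: no evidence of difference
      return(structure(
        list(
          labels = labels, n = c(length(a), length(b)),
          mean = c(mean(a), mean(b)), sd = c(0, 0),
          test = "degenerate", statistic = NA_real_, p_value = 1,
          cohens_d = 0, normal = c(NA, NA)
        ),
        class = "group_comparison"
      ))
    }
    stop_posturekit("both groups are constant; comparison undefined", "insufficient_variance")
  }
  gate <- function(x) {
    tryCatch(normality_gate(x, alpha)$is_normal, posturekit_insufficient_variance = function(e) FALSE)
  }
  normal <- c(gate(a), gate(b))
  if (all(normal)) {
    ht <- stats::t.test(a, b, var.equal = !welch)
    test <- "student_t"
  } else {
    ht <- stats::wilcox.test(a, b, exact = FALSE)
    test <- "mann_whitney_u"
  }
  d <- if (stats::sd(a) > 0 && stats::sd(b) > 0) {
    cohens_d(mean(a), stats::sd(a), mean(b), stats::sd(b))
  } else {
    NA_real_
  }
  structure(
    list(
      labels = labels, n = c(length(a), length(b)),
      mean = c(mean(a), mean(b)), sd = c(stats::sd(a), stats::sd(b)),
      test = test, statistic = unname(ht$statistic), p_value = ht$p.value,
      cohens_d = d, normal = normal
    ),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison> %s (n=%d) vs %s (n=%d): %s p=%.4g, d=%.2f\n",
    x$labels[1], x$n[1], x$labels[2], x$n[2], x$test, x$p_value, x$cohens_d
  ))
  invisible(x)
}

#' Sex comparison of every postural parameter
#'
#' Reproduces the normative-table layout: per parameter, per-sex n, mean,
#' SD, the gated test, raw p-value with significance stars, and Cohen's d
#' signed as men minus women (men are the first-listed group). No
#' multiple-testing correction is applied by default, matching the study's
#' raw-p reporting; `holm = TRUE` adds a Holm-adjusted column.
#'
#' @param profiles Profile table from [profile_cohort()] (session 1 rows are
#'   used unless `session` says otherwise).
#' @param session Which session to compare (default 1).
#' @param welch,holm Options forwarded to the tests.
#' @return Data frame, one row per parameter.
#' @export
sex_comparison_table <- function(profiles, session = 1L, welch = FALSE, holm = FALSE) {
  df <- profiles[profiles$session == session, , drop = FALSE]
  comparison_table(
    df[df$sex == "M", , drop = FALSE], df[df$sex == "F", , drop = FALSE],
    labels = c("men", "women"), welch = welch, holm = holm,
    d_reverse = TRUE # the normative table signs d as men minus women
  )
}

comparison_table <- function(df_a, df_b, labels, welch = FALSE, holm = FALSE,
                             d_reverse = FALSE) {
  params <- intersect(posture_parameters(), names(df_a))
  rows <- lapply(params, function(p) {
    a <- df_a[[p]]
    b <- df_b[[p]]
    if (sum(!is.na(a)) < 3 || sum(!is.na(b)) < 3) {
      return(NULL)
    }
    cmp <- compare_groups(a, b, labels = labels, welch = welch)
    data.frame(
      parameter = p, group = parameter_group(p),
      n_a = cmp$n[1], mean_a = cmp$mean[1], sd_a = cmp$sd[1],
      n_b = cmp$n[2], mean_b = cmp$mean[2], sd_b = cmp$sd[2],
      test = cmp$test, p_value = cmp$p_value,
      stars = p_stars(cmp$p_value),
      d = if (d_reverse) -cmp$cohens_d else cmp$cohens_d,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (holm) out$p_holm <- stats::p.adjust(out$p_value, method = "holm")
  names(out) <- sub("_a$", paste0("_", labels[1]), names(out))
  names(out) <- sub("_b$", paste0("_", labels[2]), names(out))
  out
}

p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Height-posture correlations
#'
#' Pearson correlation of each postural parameter with stature, with the
#' study's relevance rule: a correlation is flagged relevant only when
#' `p < 0.05` and `r > 0.45`.
#'
#' @param profiles Profile table from [profile_cohort()] with a `height`
#'   column.
#' @param session Which session to use (default 1).
#' @param r_threshold Relevance threshold on r (default 0.45).
#' @return Data frame: `parameter`, `n`, `pearson_r`, `p_value`, `relevant`.
#' @export
height_correlations <- function(profiles, session = 1L, r_threshold = 0.45) {
  df <- profiles[profiles$session == session, , drop = FALSE]
  params <- intersect(posture_parameters(), names(df))
  rows <- lapply(params, function(p) {
    ok <- !is.na(df[[p]]) & !is.na(df$height)
    x <- df$height[ok]
    y <- df[[p]][ok]
    if (length(x) < 3) {
      return(NULL)
    }
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      stop_posturekit(
        sprintf("zero variance in correlation for %s", p), "undefined_correlation"
      )
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    data.frame(
      parameter = p, n = length(x), pearson_r = unname(ct$estimate),
      p_value = ct$p.value,
      relevant = ct$p.value < 0.05 && unname(ct$estimate) > r_threshold,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' ICC(3,k): two-way mixed effects, consistency, average of k measurements
#'
#' From the two-way (subjects x sessions) ANOVA decomposition:
#' `ICC(3,k) = (MS_subjects - MS_error) / MS_subjects`, where `MS_error` is
#' the residual (subject x session interaction) mean square. The consistency
#' form ignores fixed session shifts, so adding a constant to one session
#' leaves it unchanged.
#'
#' @param measurements Numeric n x k matrix: rows subjects, columns
#'   sessions; no missing cells, `n >= 3`, `k >= 2`.
#' @return ICC(3,k) estimate (`<= 1`; can be negative when subjects are less
#'   consistent than noise).
#' @export
icc_3k <- function(measurements) {
  m <- as.matrix(measurements)
  if (anyNA(m)) stop_posturekit("ICC requires a complete n x k matrix", "incomplete_design")
  n <- nrow(m)
  k <- ncol(m)
  if (n < 3 || k < 2) {
    stop_posturekit("ICC(3,k) needs at least 3 subjects and 2 sessions", "insufficient_sample")
  }
  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_total <- sum((m - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  ms_rows <- ss_rows / (n - 1)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  if (ms_rows <= 0) {
    stop_posturekit("no between-subject variance; ICC undefined", "insufficient_variance")
  }
  (ms_rows - ms_err) / ms_rows
}

#' Standard error of measurement from a pooled SD and an ICC
#'
#' `SEM = sd_pooled * sqrt(1 - ICC)`. The pooled SD is conventionally the
#' SD of all n x k measurements about their session means (consistency-
#' compatible pooling; see [pooled_measurement_sd()]).
#'
#' @param sd_pooled Pooled measurement SD, parameter units.
#' @param icc Reliability in `[0, 1]`.
#' @return SEM in parameter units.
#' @export
sem_from_icc <- function(sd_pooled, icc) {
  if (!is.finite(icc) || icc > 1 || icc < 0) {
    stop_posturekit("SEM requires ICC in [0, 1]", "invalid_input")
  }
  if (sd_pooled < 0) stop_posturekit("pooled SD must be non-negative", "invalid_input")
  sd_pooled * sqrt(1 - icc)
}

#' Session-centred pooled SD of a test-retest matrix
#'
#' SD of all measurements after centering each session (column), i.e. the
#' square root of the average within-session variance; the consistency-
#' compatible spread that enters the SEM.
#'
#' @param measurements Numeric n x k matrix.
#' @return Pooled SD.
#' @export
pooled_measurement_sd <- function(measurements) {
  m <- as.matrix(measurements)
  centered <- sweep(m, 2, colMeans(m))
  sqrt(sum(centered^2) / (ncol(m) * (nrow(m) - 1)))
}

#' Minimal detectable change at 95% confidence
#'
#' `MDC95 = SEM * 1.96 * sqrt(2)`: the smallest between-session change that
#' exceeds measurement error with 95% confidence.
#'
#' @param sem Standard error of measurement (non-negative).
#' @return MDC95 in parameter units.
#' @export
#' @examples
#' mdc95(0.22) # ~0.61
mdc95 <- function(sem) {
  if (any(sem < 0)) stop_posturekit("SEM must be non-negative", "invalid_input")
  sem * 1.96 * sqrt(2)
}

#' Test-retest reliability table
#'
#' One row per angle/inclination parameter (vector lengths are excluded,
#' matching the study's blank reliability cells): ICC(3,k), SEM, and MDC95
#' from the matched two-session profiles.
#'
#' @param profiles Profile table from [profile_cohort()] containing both
#'   sessions.
#' @param sessions Length-2 vector of session ids (default `c(1, 2)`).
#' @param parameters Parameters to assess; default all angles and
#'   inclinations.
#' @return Data frame: `parameter`, `n`, `k`, `icc_3k`, `sem`, `mdc95`.
#' @export
reliability_table <- function(profiles, sessions = c(1L, 2L),
                              parameters = setdiff(
                                posture_parameters(),
                                posture_parameters("vectors")
                              )) {
  s1 <- profiles[profiles$session == sessions[1], , drop = FALSE]
  s2 <- profiles[profiles$session == sessions[2], , drop = FALSE]
  common <- intersect(s1$subject_id, s2$subject_id)
  orphans <- c(setdiff(s1$subject_id, s2$subject_id), setdiff(s2$subject_id, s1$subject_id))
  if (length(orphans)) {
    warning(sprintf(
      "dropping %d subject(s) without both sessions: %s",
      length(orphans), paste(utils::head(orphans, 5), collapse = ", ")
    ))
  }
  if (length(common) < 3) {
    stop_posturekit("reliability needs at least 3 subjects with both sessions", "insufficient_sample")
  }
  s1 <- s1[match(common, s1$subject_id), , drop = FALSE]
  s2 <- s2[match(common, s2$subject_id), , drop = FALSE]
  rows <- lapply(intersect(parameters, names(profiles)), function(p) {
    m <- cbind(s1[[p]], s2[[p]])
    if (anyNA(m)) {
      keep <- stats::complete.cases(m)
      m <- m[keep, , drop = FALSE]
    }
    if (nrow(m) < 3) {
      return(NULL)
    }
    icc <- icc_3k(m)
    sem <- sem_from_icc(pooled_measurement_sd(m), max(0, min(1, icc)))
    data.frame(
      parameter = p, n = nrow(m), k = 2L,
      icc_3k = icc, sem = sem, mdc95 = mdc95(sem),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
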