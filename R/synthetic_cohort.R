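#' Configuration of the synthetic posture cohort generator
#'
#' The generator emulates the statistical structure the analysis assumes:
#' sex-specific distributions of the angle and inclination parameters
#' (normative-table defaults), a sex-independent two-cluster mixture for the
#' four body-vector lengths (cluster-table defaults), per-sex
#' anthropometrics with a height-vector coupling, and test-retest
#' measurement error calibrated per parameter to target ICC(3,k) values.
#' From each subject's parameter set a 3D stick-figure skeleton is posed
#' whose frontal/dorsal/lateral projections invert the geometry layer
#' exactly at zero landmark jitter.
#'
#' @param n_subjects Cohort size (default 200, the study's n).
#' @param sex_ratio Proportion of men (default 84/200).
#' @param cluster_weight Mixing weight of the short-vector cluster CG1
#'   (default 0.5; cluster membership is independent of sex by
#'   construction).
#' @param angle_table Per-sex (mean, SD) of the 18 angle/inclination
#'   parameters; default [reference_sex_table()].
#' @param vector_table Per-cluster (mean, SD) of the 4 vector parameters;
#'   default the vector rows of [reference_cluster_table()].
#' @param anthropometrics Per-sex age/height/weight moments; default
#'   [reference_anthropometrics()].
#' @param height_corr Target Pearson correlation between height and the
#'   torso vector (default 0.5).
#' @param target_icc Named per-parameter target ICC(3,k) for session noise;
#'   default the normative-table ICC column, 0.95 for vectors.
#' @param jitter_sd Isotropic Gaussian landmark jitter, px (default 0.25).
#'   Session-to-session measurement error is already injected in parameter
#'   space by the ICC calibration; the jitter represents the residual
#'   landmark-detection noise on top of it, and its default is chosen small
#'   enough that the per-parameter reliability stays on the calibration
#'   targets.
#' @param n_retest Subjects re-measured in session 2 (default 90).
#' @param skeleton Skeleton proportions not constrained by the parameters
#'   (pixel units); these affect landmark placement only, never the scored
#'   parameters.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_subjects = 200L,
                           sex_ratio = 84 / 200,
                           cluster_weight = 0.5,
                           angle_table = NULL,
                           vector_table = NULL,
                           anthropometrics = reference_anthropometrics(),
                           height_corr = 0.5,
                           target_icc = NULL,
                           jitter_sd = 0.25,
                           n_retest = 90L,
                           skeleton = list()) {
  ref <- reference_sex_table()
  if (is.null(angle_table)) {
    angle_table <- ref[!ref$parameter %in% posture_parameters("vectors"),
                       c("parameter", "men_mean", "men_sd", "women_mean", "women_sd")]
  }
  if (is.null(vector_table)) {
    cl <- reference_cluster_table()
    vector_table <- cl[cl$parameter %in% posture_parameters("vectors"),
                       c("parameter", "cg1_mean", "cg1_sd", "cg2_mean", "cg2_sd")]
  }
  if (is.null(target_icc)) {
    target_icc <- stats::setNames(ref$icc, ref$parameter)
    target_icc[posture_parameters("vectors")] <- 0.95
  }
  stopifnot(
    n_subjects >= 1, sex_ratio > 0, sex_ratio < 1,
    cluster_weight > 0, cluster_weight < 1,
    all(angle_table$men_sd >= 0), all(angle_table$women_sd >= 0),
    jitter_sd >= 0
  )
  if (any(target_icc <= 0 | target_icc > 1, na.rm = TRUE)) {
    stop_posturekit("target ICCs must lie in (0, 1]", "spec_error")
  }
  skel <- utils::modifyList(list(
    hip_width = 110, ear_width = 95, neck_length = 105,
    foot_length = 70, hand_length = 45, out_toe_deg = 10,
    arm_split = 0.54, leg_split = 0.53,
    center = c(540, 1100), image_size = c(1080, 1920)
  ), skeleton)
  out <- structure(
    list(
      n_subjects = as.integer(n_subjects), sex_ratio = sex_ratio,
      cluster_weight = cluster_weight, angle_table = angle_table,
      vector_table = vector_table, anthropometrics = anthropometrics,
      height_corr = height_corr, target_icc = target_icc,
      jitter_sd = jitter_sd, n_retest = as.integer(min(n_retest, n_subjects)),
      skeleton = skel
    ),
    class = "synthetic_spec"
  )
  # cache derived quantities used per subject draw
  out$pop_mean <- parameter_population_mean(out)
  out$pop_sd <- parameter_population_sd(out)
  # The configured tables are *measured* moments: they include the
  # session-level measurement error that the ICC targets quantify. True
  # (error-free) parameters are drawn with the within-group SDs shrunk so
  # that truth + calibrated session error reproduces the printed moments:
  # total true variance = ICC1 * printed total variance, with the fixed
  # group-mean gaps absorbed by the within-group part.
  w <- sex_ratio
  icc1 <- inverse_spearman_brown(out$target_icc[names(out$pop_sd)], 2)
  out$sd_between_true <- sqrt(icc1) * out$pop_sd
  shrink_factor <- function(gapvar, avgvar, icc1_p) {
    if (avgvar <= .Machine$double.eps) {
      return(1)
    }
    sqrt(max(1e-12, (icc1_p * (gapvar + avgvar) - gapvar) / avgvar))
  }
  at <- out$angle_table
  out$angle_table_true <- at
  for (i in seq_len(nrow(at))) {
    p <- at$parameter[i]
    gapvar <- w * (1 - w) * (at$men_mean[i] - at$women_mean[i])^2
    avgvar <- w * at$men_sd[i]^2 + (1 - w) * at$women_sd[i]^2
    f <- shrink_factor(gapvar, avgvar, inverse_spearman_brown(out$target_icc[[p]], 2))
    out$angle_table_true$men_sd[i] <- at$men_sd[i] * f
    out$angle_table_true$women_sd[i] <- at$women_sd[i] * f
  }
  wc <- cluster_weight
  vt <- out$vector_table
  out$vector_table_true <- vt
  for (i in seq_len(nrow(vt))) {
    p <- vt$parameter[i]
    gapvar <- wc * (1 - wc) * (vt$cg1_mean[i] - vt$cg2_mean[i])^2
    avgvar <- wc * vt$cg1_sd[i]^2 + (1 - wc) * vt$cg2_sd[i]^2
    f <- shrink_factor(gapvar, avgvar, inverse_spearman_brown(out$target_icc[[p]], 2))
    out$vector_table_true$cg1_sd[i] <- vt$cg1_sd[i] * f
    out$vector_table_true$cg2_sd[i] <- vt$cg2_sd[i] * f
  }
  sd_h_tot <- sqrt(
    w * (1 - w) * diff(anthropometrics$height_mean)^2 +
      sum(c(w, 1 - w)[match(anthropometrics$sex, c("M", "F"))] *
            anthropometrics$height_sd^2)
  )
  e_sigma <- w * anthropometrics$height_sd[anthropometrics$sex == "M"] +
    (1 - w) * anthropometrics$height_sd[anthropometrics$sex == "F"]
  out$height_lambda <- height_corr * sd_h_tot / e_sigma
  if (abs(out$height_lambda) >= 1) {
    stop_posturekit(
      "height-vector correlation target infeasible for these moments",
      "spec_error"
    )
  }
  out
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(
    "<synthetic_spec> n=%d (%.0f%% men), cluster weight %.2f, jitter %.1f px, retest n=%d\n",
    x$n_subjects, 100 * x$sex_ratio, x$cluster_weight, x$jitter_sd, x$n_retest
  ))
  invisible(x)
}

#' Population SD of each parameter implied by a generator configuration
#'
#' Mixture SD over the sexes (angle parameters) or over the two clusters
#' (vector parameters): `sqrt(sum w (sd^2 + mean^2) - mixture_mean^2)`.
#' This is the between-subject spread that calibrates session noise.
#'
#' @param spec A [synthetic_spec()].
#' @return Named numeric vector over all parameters.
#' @export
parameter_population_sd <- function(spec) {
  if (!is.null(spec$pop_sd)) {
    return(spec$pop_sd)
  }
  w <- spec$sex_ratio
  at <- spec$angle_table
  mu <- w * at$men_mean + (1 - w) * at$women_mean
  v <- w * (at$men_sd^2 + at$men_mean^2) + (1 - w) * (at$women_sd^2 + at$women_mean^2) - mu^2
  out <- stats::setNames(sqrt(pmax(v, 0)), at$parameter)
  wc <- spec$cluster_weight
  vt <- spec$vector_table
  muv <- wc * vt$cg1_mean + (1 - wc) * vt$cg2_mean
  vv <- wc * (vt$cg1_sd^2 + vt$cg1_mean^2) + (1 - wc) * (vt$cg2_sd^2 + vt$cg2_mean^2) - muv^2
  out[vt$parameter] <- sqrt(pmax(vv, 0))
  out[posture_parameters()]
}

parameter_population_mean <- function(spec) {
  if (!is.null(spec$pop_mean)) {
    return(spec$pop_mean)
  }
  w <- spec$sex_ratio
  at <- spec$angle_table
  out <- stats::setNames(w * at$men_mean + (1 - w) * at$women_mean, at$parameter)
  wc <- spec$cluster_weight
  vt <- spec$vector_table
  out[vt$parameter] <- wc * vt$cg1_mean + (1 - wc) * vt$cg2_mean
  out[posture_parameters()]
}

#' Inverse Spearman-Brown step-down
#'
#' Single-measure reliability implied by an average-of-k reliability:
#' `ICC1 = ICCk / (k - (k - 1) ICCk)`.
#'
#' @param icc_k Average-measures ICC in (0, 1].
#' @param k Number of measurements.
#' @return Single-measure ICC.
#' @export
#' @examples
#' inverse_spearman_brown(0.95, 2) # 0.9048
inverse_spearman_brown <- function(icc_k, k = 2) {
  icc_k / (k - (k - 1) * icc_k)
}

#' Session-noise SD that calibrates a target ICC(3,k)
#'
#' Both sessions receive independent measurement error of this SD, so that
#' the expected consistency ICC over k sessions equals the target:
#' `sigma_e = sigma_between * sqrt((1 - ICC1) / ICC1)` with `ICC1` the
#' inverse Spearman-Brown single-measure reliability.
#'
#' @param sd_between Between-subject SD of the parameter.
#' @param icc_k Target ICC(3,k) in (0, 1].
#' @param k Sessions (default 2).
#' @return Within-subject error SD per session.
#' @export
icc_session_noise_sd <- function(sd_between, icc_k, k = 2) {
  if (any(icc_k <= 0 | icc_k > 1)) {
    stop_posturekit("target ICC must lie in (0, 1]", "spec_error")
  }
  icc1 <- inverse_spearman_brown(icc_k, k)
  sd_between * sqrt((1 - icc1) / icc1)
}

# one truncated-normal draw (>= lower) by rejection
rtruncnorm1 <- function(mean, sd, lower = 0) {
  if (sd == 0) {
    if (mean < lower) stop_posturekit("degenerate draw below bound", "spec_error")
    return(mean)
  }
  for (i in 1:1000) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lower) return(x)
  }
  stop_posturekit("truncated draw failed (mean far below bound?)", "spec_error")
}

# random sign assignments that persist per subject: which way each line
# tilts, which way the thigh/shank deviate in each plane, lean direction
draw_signs <- function() {
  nm <- c(
    "ear_line", "shoulder_line", "elbow_line", "wrist_line", "hip_line",
    "knee_line", "ankle_line", "body_imbalance", "knee_varus_valgus",
    "hip_extension", "knee_extension"
  )
  stats::setNames(sample(c(-1, 1), length(nm), replace = TRUE), nm)
}

draw_subject <- function(spec, sex) {
  at <- spec$angle_table_true %||% spec$angle_table
  vt <- spec$vector_table_true %||% spec$vector_table
  cluster <- if (stats::runif(1) < spec$cluster_weight) 1L else 2L
  prof <- stats::setNames(numeric(length(posture_parameters())), posture_parameters())
  mcol <- if (sex == "M") "men_mean" else "women_mean"
  scol <- if (sex == "M") "men_sd" else "women_sd"
  for (i in seq_len(nrow(at))) {
    prof[at$parameter[i]] <- rtruncnorm1(at[[mcol]][i], at[[scol]][i], 0)
  }
  ccol_m <- if (cluster == 1L) "cg1_mean" else "cg2_mean"
  ccol_s <- if (cluster == 1L) "cg1_sd" else "cg2_sd"
  for (i in seq_len(nrow(vt))) {
    prof[vt$parameter[i]] <- stats::rnorm(1, vt[[ccol_m]][i], vt[[ccol_s]][i])
  }
  # height shares a latent factor with the torso vector (standardized
  # against the analytic mixture moments), preserving per-sex marginals
  anth <- spec$anthropometrics
  a <- anth[anth$sex == sex, ]
  lambda <- spec$height_lambda
  mixmu <- parameter_population_mean(spec)[["torso_vector"]]
  mixsd <- (spec$sd_between_true %||% parameter_population_sd(spec))[["torso_vector"]]
  z_mix <- (prof[["torso_vector"]] - mixmu) / mixsd
  height <- a$height_mean + a$height_sd * (lambda * z_mix + sqrt(1 - lambda^2) * stats::rnorm(1))
  age <- rtruncnorm1(a$age_mean, a$age_sd, 18)
  weight <- rtruncnorm1(a$weight_mean, a$weight_sd, 30)
  signs <- draw_signs()
  # raw standard-normal session errors; scaled deterministically later
  sess_err <- matrix(stats::rnorm(2 * length(prof)), nrow = 2,
                     dimnames = list(NULL, names(prof)))
  list(
    sex = sex, cluster = cluster, profile = prof, height = height,
    age = age, weight = weight, signs = signs, sess_err = sess_err
  )
}

# redraw a subset of a subject's true parameters (respecting their sex- or
# cluster-conditional distribution) together with those parameters' session
# errors; everything else is kept
redraw_parameters <- function(dr, spec, params) {
  at <- spec$angle_table_true %||% spec$angle_table
  vt <- spec$vector_table_true %||% spec$vector_table
  mcol <- if (dr$sex == "M") "men_mean" else "women_mean"
  scol <- if (dr$sex == "M") "men_sd" else "women_sd"
  ccol_m <- if (dr$cluster == 1L) "cg1_mean" else "cg2_mean"
  ccol_s <- if (dr$cluster == 1L) "cg1_sd" else "cg2_sd"
  for (pname in params) {
    i <- match(pname, at$parameter)
    if (!is.na(i)) {
      dr$profile[pname] <- rtruncnorm1(at[[mcol]][i], at[[scol]][i], 0)
    } else {
      j <- match(pname, vt$parameter)
      if (is.na(j)) stop_posturekit(sprintf("unknown parameter '%s'", pname), "spec_error")
      dr$profile[pname] <- stats::rnorm(1, vt[[ccol_m]][j], vt[[ccol_s]][j])
    }
    dr$sess_err[, pname] <- stats::rnorm(2)
  }
  dr
}

# redraw the leg inclination from its sex-conditional distribution,
# restricted (by inverse-CDF sampling) to the reachable window the skeleton
# solver reported; NULL when the window holds almost no probability mass
redraw_lambda <- function(dr, spec, window) {
  if (is.null(window)) {
    return(redraw_parameters(dr, spec, "leg_inclination"))
  }
  at <- spec$angle_table_true %||% spec$angle_table
  i <- match("leg_inclination", at$parameter)
  mu <- if (dr$sex == "M") at$men_mean[i] else at$women_mean[i]
  sd_ <- if (dr$sex == "M") at$men_sd[i] else at$women_sd[i]
  lo <- max(0.005, window[1])
  hi <- max(window[2], lo + 0.01)
  p_lo <- stats::pnorm(lo, mu, sd_)
  p_hi <- stats::pnorm(hi, mu, sd_)
  if (p_hi - p_lo < 1e-8) {
    return(NULL)
  }
  dr$profile["leg_inclination"] <- stats::qnorm(stats::runif(1, p_lo, p_hi), mu, sd_)
  dr$sess_err[, "leg_inclination"] <- stats::rnorm(2)
  dr
}

session_profiles_from <- function(profile, sess_err, spec) {
  sd_b <- spec$sd_between_true %||% parameter_population_sd(spec)
  icc <- spec$target_icc[names(profile)]
  sigma_e <- icc_session_noise_sd(sd_b[names(profile)], icc)
  non_neg <- !names(profile) %in% posture_parameters("vectors")
  out <- lapply(1:2, function(s) {
    v <- profile + sess_err[s, names(profile)] * sigma_e
    # an unsigned inclination measured after its direction flips folds at 0
    v[non_neg] <- abs(v[non_neg])
    v
  })
  names(out) <- c("1", "2")
  out
}

#' Sample ground-truth parameters for a synthetic cohort
#'
#' Draws, per subject: sex (fixed proportion), cluster membership
#' (independent of sex), the 18 angle/inclination parameters from per-sex
#' truncated normals, the 4 vector parameters from the per-cluster mixture,
#' anthropometrics with the height-vector latent coupling, per-subject tilt
#' directions, and both sessions' measurement-error realizations. Uses the
#' current RNG state; call `set.seed()` first for reproducibility.
#'
#' @param spec A [synthetic_spec()].
#' @return Object of class `posture_ground_truth`: `subjects` (data frame:
#'   id, sex, cluster, age, height, weight, retest), `profile` (n x 22 true
#'   parameters), `sessions` (list of two n x 22 matrices: truth plus
#'   session error, folded at zero for angles), `signs` (n x 11 tilt
#'   directions).
#' @export
sample_parameters <- function(spec) {
  n <- spec$n_subjects
  n_men <- round(n * spec$sex_ratio)
  sexes <- sample(rep(c("M", "F"), c(n_men, n - n_men)))
  draws <- lapply(sexes, function(s) draw_subject(spec, s))
  assemble_truth(draws, spec)
}

assemble_truth <- function(draws, spec) {
  n <- length(draws)
  ids <- sprintf("S%03d", seq_len(n))
  prof <- do.call(rbind, lapply(draws, function(d) d$profile))
  rownames(prof) <- ids
  sess <- lapply(c("1", "2"), function(s) {
    m <- do.call(rbind, lapply(draws, function(d) {
      session_profiles_from(d$profile, d$sess_err, spec)[[s]]
    }))
    rownames(m) <- ids
    m
  })
  names(sess) <- c("1", "2")
  signs <- do.call(rbind, lapply(draws, function(d) d$signs))
  rownames(signs) <- ids
  subjects <- data.frame(
    subject_id = ids,
    sex = vapply(draws, function(d) d$sex, ""),
    cluster = vapply(draws, function(d) d$cluster, 0L),
    age = vapply(draws, function(d) d$age, 0),
    height = vapply(draws, function(d) d$height, 0),
    weight = vapply(draws, function(d) d$weight, 0),
    retest = seq_len(n) <= spec$n_retest,
    stringsAsFactors = FALSE
  )
  structure(
    list(subjects = subjects, profile = prof, sessions = sess, signs = signs),
    class = "posture_ground_truth"
  )
}

#' @export
print.posture_ground_truth <- function(x, ...) {
  cat(sprintf(
    "<posture_ground_truth> %d subjects (%d retest), %d parameters\n",
    nrow(x$subjects), sum(x$subjects$retest), ncol(x$profile)
  ))
  invisible(x)
}

#' Session profiles with ICC-calibrated measurement error
#'
#' Adds independent per-session measurement error to the true parameters so
#' that the expected test-retest ICC(3,k) over `k = 2` sessions equals the
#' per-parameter target: the error SD follows [icc_session_noise_sd()] with
#' the between-subject SD implied by the generator moments. Angle
#' parameters are folded at zero (an unsigned tilt whose direction flips is
#' measured by its magnitude). A target of 1 reproduces the truth exactly
#' in both sessions.
#'
#' @param truth A `posture_ground_truth` from [sample_parameters()].
#' @param spec The generating [synthetic_spec()].
#' @param target_icc Optional named override of per-parameter targets.
#' @return List of two n x p session matrices (names `"1"`, `"2"`). Uses
#'   the current RNG state.
#' @export
make_retest <- function(truth, spec, target_icc = NULL) {
  if (!is.null(target_icc)) {
    spec$target_icc[names(target_icc)] <- target_icc
  }
  n <- nrow(truth$profile)
  params <- colnames(truth$profile)
  sd_b <- spec$sd_between_true %||% parameter_population_sd(spec)
  sigma_e <- icc_session_noise_sd(sd_b[params], spec$target_icc[params])
  non_neg <- !params %in% posture_parameters("vectors")
  out <- lapply(1:2, function(s) {
    err <- matrix(stats::rnorm(n * length(params)), n, length(params))
    m <- truth$profile + sweep(err, 2, sigma_e, `*`)
    m[, non_neg] <- abs(m[, non_neg])
    m
  })
  names(out) <- c("1", "2")
  out
}
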