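#' Names of the postural parameters
#'
#' In reporting order: 7 body-joint angles (degrees), 7 horizontal
#' inclinations (degrees), 4 vertical inclinations (degrees), and 4 body
#' vector lengths (pixel distance).
#'
#' @param group Optional subset: `"joints"`, `"horizontal"`, `"vertical"`,
#'   or `"vectors"`.
#' @return Character vector of parameter names.
#' @export
posture_parameters <- function(group = c("all", "joints", "horizontal", "vertical", "vectors")) {
  group <- match.arg(group)
  joints <- c(
    "shoulder_adduction", "elbow_extension", "hip_adduction", "hip_extension",
    "knee_varus_valgus", "knee_extension", "ankle_flexion"
  )
  horizontal <- c(
    "ear_line", "shoulder_line", "elbow_line", "wrist_line",
    "hip_line", "knee_line", "ankle_line"
  )
  vertical <- c(
    "neck_inclination", "trunk_forward_inclination", "body_imbalance",
    "leg_inclination"
  )
  vectors <- c(
    "shoulder_hip_difference", "torso_vector", "total_arm_vector",
    "total_leg_vector"
  )
  switch(group,
    all = c(joints, horizontal, vertical, vectors),
    joints = joints, horizontal = horizontal, vertical = vertical,
    vectors = vectors
  )
}

# unit conversion map for the profile-table header
posture_parameter_units <- function() {
  p <- posture_parameters()
  units <- rep("deg", length(p))
  units[p %in% posture_parameters("vectors")] <- "pd"
  stats::setNames(units, p)
}

#' Raw per-side joint angles of one coronal capture
#'
#' Computes the seven body-joint parameters for the left and right side from
#' a frontal or dorsal capture, on full `(x, y, z)` coordinates (the two
#' single-plane parameters, hip extension and knee varus/valgus and knee
#' extension, use the stated projections). Definitions:
#'
#' * `shoulder_adduction`: angle at the shoulder between shoulder-to-elbow
#'   and shoulder-to-hip (arm-trunk separation).
#' * `elbow_extension`: 180 degrees minus the angle at the elbow between
#'   elbow-to-shoulder and elbow-to-wrist (deviation from a straight arm).
#' * `hip_adduction`: 180 degrees minus the angle at the hip between
#'   hip-to-knee and hip-to-shoulder (thigh deviation from the trunk line).
#' * `hip_extension`: sagittal-plane (z-y) deviation between trunk line and
#'   thigh line at the hip.
#' * `knee_varus_valgus`: 180 degrees minus the coronal-plane (x-y) angle at
#'   the knee between knee-to-hip and knee-to-ankle.
#' * `knee_extension`: 180 degrees minus the sagittal-plane (z-y) angle at
#'   the knee between knee-to-hip and knee-to-ankle.
#' * `ankle_flexion`: 3D angle at the ankle between ankle-to-knee and
#'   ankle-to-foot-index.
#'
#' @param capture A frontal or dorsal [pose_capture()].
#' @param min_visibility Visibility threshold for the required landmarks.
#' @return A `view_angles` object: matrix with rows = joint parameters,
#'   columns `left`/`right`, degrees.
#' @export
joint_angles <- function(capture, min_visibility = 0.5) {
  if (!capture$view %in% c("frontal", "dorsal")) {
    stop_posturekit("joint angles are defined on coronal (frontal/dorsal) captures", "wrong_view")
  }
  capture <- canonicalize_capture(capture)
  out <- matrix(
    NA_real_, 7, 2,
    dimnames = list(posture_parameters("joints"), c("left", "right"))
  )
  for (side in c("left", "right")) {
    pt <- side_points(capture, side, min_visibility)
    sh <- pt$shoulder
    el <- pt$elbow
    wr <- pt$wrist
    hp <- pt$hip
    kn <- pt$knee
    an <- pt$ankle
    ft <- pt$foot_index
    out["shoulder_adduction", side] <- angle_between(el - sh, hp - sh)
    out["elbow_extension", side] <- 180 - angle_between(sh - el, wr - el)
    out["hip_adduction", side] <- 180 - angle_between(kn - hp, sh - hp)
    out["hip_extension", side] <- 180 - angle_between_plane(sh - hp, kn - hp, c(3, 2))
    out["knee_varus_valgus", side] <- 180 - angle_between_plane(hp - kn, an - kn, c(1, 2))
    out["knee_extension", side] <- 180 - angle_between_plane(hp - kn, an - kn, c(3, 2))
    out["ankle_flexion", side] <- angle_between(kn - an, ft - an)
  }
  structure(out, class = c("view_angles", class(out)), view = capture$view)
}

side_points <- function(capture, side, min_visibility) {
  labels <- paste0(side, "_", c("shoulder", "elbow", "wrist", "hip", "knee", "ankle", "foot_index"))
  low <- labels[vapply(labels, function(l) landmark_visibility(capture, l), 0) < min_visibility]
  if (length(low)) {
    stop_posturekit(
      sprintf(
        "cannot compute joint angles for subject %s (%s view): low visibility on %s",
        capture$subject_id, capture$view, paste(low, collapse = ", ")
      ),
      "low_visibility"
    )
  }
  pts <- lapply(labels, function(l) landmark_xyz(capture, l))
  names(pts) <- c("shoulder", "elbow", "wrist", "hip", "knee", "ankle", "foot_index")
  pts
}

#' Fuse joint angles across the frontal and dorsal views
#'
#' Per parameter, the circular mean over all available view-side raw angles
#' (frontal left/right and dorsal left/right). If one coronal view is
#' missing, the other is used alone with a warning.
#'
#' @param frontal,dorsal `view_angles` objects from [joint_angles()]; either
#'   (but not both) may be `NULL`.
#' @return Named numeric vector of the 7 fused joint angles, degrees.
#' @export
fuse_views <- function(frontal = NULL, dorsal = NULL) {
  views <- Filter(Negate(is.null), list(frontal = frontal, dorsal = dorsal))
  if (length(views) == 0) {
    stop_posturekit("no coronal view available to fuse", "insufficient_data")
  }
  if (length(views) == 1) {
    warning(sprintf("only the %s view is available; no cross-view fusion", names(views)[1]))
  }
  params <- posture_parameters("joints")
  vapply(params, function(p) {
    vals <- unlist(lapply(views, function(v) v[p, c("left", "right")]))
    m <- as.numeric(circular_mean(vals))
    # joint angles live in [0, 180); fold means that wrap past 360 back down
    if (m > 180) m - 360 else m
  }, 0)
}

#' Body vector lengths of one coronal capture
#'
#' All distances are image-plane (x, y) Euclidean, in pixel distance (pd):
#' `torso_vector` between the shoulder and hip midpoints;
#' `total_arm_vector` = shoulder-elbow + elbow-wrist, averaged over sides;
#' `total_leg_vector` = hip-knee + knee-ankle, averaged over sides;
#' `shoulder_hip_difference` = shoulder width minus hip width.
#'
#' @param capture A frontal or dorsal [pose_capture()].
#' @param min_visibility Visibility threshold.
#' @return Named numeric vector of the 4 vector parameters.
#' @export
vector_lengths <- function(capture, min_visibility = 0.5) {
  if (!capture$view %in% c("frontal", "dorsal")) {
    stop_posturekit("vector lengths are defined on coronal captures", "wrong_view")
  }
  L <- side_points(capture, "left", min_visibility)
  R <- side_points(capture, "right", min_visibility)
  arm <- function(p) dist_xy(p$shoulder, p$elbow) + dist_xy(p$elbow, p$wrist)
  leg <- function(p) dist_xy(p$hip, p$knee) + dist_xy(p$knee, p$ankle)
  c(
    shoulder_hip_difference = dist_xy(L$shoulder, R$shoulder) - dist_xy(L$hip, R$hip),
    torso_vector = dist_xy((L$shoulder + R$shoulder) / 2, (L$hip + R$hip) / 2),
    total_arm_vector = (arm(L) + arm(R)) / 2,
    total_leg_vector = (leg(L) + leg(R)) / 2
  )
}

#' Neck and trunk inclination from the lateral capture
#'
#' Vertical inclination of the ear-shoulder segment (neck) and the
#' shoulder-hip segment (trunk forward lean) on the camera-facing side. The
#' camera-facing side is chosen as the one with the higher mean visibility
#' of ear, shoulder, and hip (ties go to the left side).
#'
#' @param capture A lateral [pose_capture()].
#' @param min_visibility Visibility threshold for the camera-facing side.
#' @return Named numeric vector: `neck_inclination`,
#'   `trunk_forward_inclination` (degrees).
#' @export
lateral_parameters <- function(capture, min_visibility = 0.5) {
  if (capture$view != "lateral") {
    stop_posturekit("neck/trunk inclinations require the lateral view", "wrong_view")
  }
  vis_mean <- function(side) {
    mean(vapply(
      paste0(side, "_", c("ear", "shoulder", "hip")),
      function(l) landmark_visibility(capture, l), 0
    ))
  }
  side <- if (vis_mean("right") > vis_mean("left")) "right" else "left"
  labels <- paste0(side, "_", c("ear", "shoulder", "hip"))
  low <- labels[vapply(labels, function(l) landmark_visibility(capture, l), 0) < min_visibility]
  if (length(low)) {
    stop_posturekit(
      sprintf("lateral view: low visibility on %s", paste(low, collapse = ", ")),
      "low_visibility"
    )
  }
  ear <- landmark_xyz(capture, paste0(side, "_ear"))
  sh <- landmark_xyz(capture, paste0(side, "_shoulder"))
  hp <- landmark_xyz(capture, paste0(side, "_hip"))
  c(
    neck_inclination = vertical_inclination(ear, sh),
    trunk_forward_inclination = vertical_inclination(sh, hp)
  )
}

# horizontal inclinations and coronal vertical inclinations of one capture
coronal_inclinations <- function(capture) {
  capture <- canonicalize_capture(capture)
  g <- function(l) landmark_xyz(capture, l)
  pairs <- list(
    ear_line = c("left_ear", "right_ear"),
    shoulder_line = c("left_shoulder", "right_shoulder"),
    elbow_line = c("left_elbow", "right_elbow"),
    wrist_line = c("left_wrist", "right_wrist"),
    hip_line = c("left_hip", "right_hip"),
    knee_line = c("left_knee", "right_knee"),
    ankle_line = c("left_ankle", "right_ankle")
  )
  hor <- vapply(pairs, function(p) horizontal_inclination(g(p[1]), g(p[2])), 0)
  sh_mid <- (g("left_shoulder") + g("right_shoulder")) / 2
  an_mid <- (g("left_ankle") + g("right_ankle")) / 2
  vert <- c(
    body_imbalance = vertical_inclination(sh_mid, an_mid),
    leg_inclination = mean(c(
      vertical_inclination(g("left_hip"), g("left_ankle")),
      vertical_inclination(g("right_hip"), g("right_ankle"))
    ))
  )
  c(hor, vert)
}

#' Compute the full posture profile of one subject session
#'
#' Joint angles are computed per coronal view and side, then fused by
#' circular mean; horizontal inclinations, the two coronal vertical
#' inclinations, and vector lengths are computed per coronal view and
#' averaged arithmetically across views; neck and trunk inclination come
#' from the lateral capture. Parameters whose source captures are missing
#' are returned as `NA` (with a warning naming them).
#'
#' @param record A [subject_record()].
#' @param session Session number (default 1).
#' @param min_visibility Visibility threshold for required landmarks.
#' @return Named numeric vector of the postural parameters in
#'   [posture_parameters()] order.
#' @export
compute_profile <- function(record, session = 1L, min_visibility = 0.5) {
  caps <- session_captures(record, session)
  views <- vapply(caps, function(cp) cp$view, "")
  frontal <- if ("frontal" %in% views) caps[[which(views == "frontal")[1]]]
  dorsal <- if ("dorsal" %in% views) caps[[which(views == "dorsal")[1]]]
  lateral <- if ("lateral" %in% views) caps[[which(views == "lateral")[1]]]
  coronal <- Filter(Negate(is.null), list(frontal, dorsal))
  if (length(coronal) == 0) {
    stop_posturekit(
      sprintf(
        "subject %s session %d has no coronal capture; cannot compute a profile",
        record$subject_id, session
      ),
      "insufficient_data"
    )
  }
  profile <- stats::setNames(rep(NA_real_, length(posture_parameters())), posture_parameters())

  va_frontal <- if (!is.null(frontal)) joint_angles(frontal, min_visibility)
  va_dorsal <- if (!is.null(dorsal)) joint_angles(dorsal, min_visibility)
  profile[posture_parameters("joints")] <- suppressWarnings(fuse_views(va_frontal, va_dorsal))

  incl <- rowMeans(vapply(coronal, coronal_inclinations, numeric(9)))
  profile[names(incl)] <- incl

  vecs <- rowMeans(vapply(coronal, function(cp) vector_lengths(cp, min_visibility), numeric(4)))
  profile[names(vecs)] <- vecs

  if (!is.null(lateral)) {
    profile[c("neck_inclination", "trunk_forward_inclination")] <-
      lateral_parameters(lateral, min_visibility)
  } else {
    warning(sprintf(
      "subject %s session %d: no lateral capture; neck and trunk inclination are NA",
      record$subject_id, session
    ))
  }
  profile
}

#' Profile table of a cohort
#'
#' One row per subject and session with the postural parameters as columns, plus
#' subject metadata. Column names carry units (`_deg` / `_pd` suffixes are
#' not used; see `attr(, "units")`).
#'
#' @param x A [cohort()].
#' @param sessions Sessions to profile; default all present per subject.
#' @param min_visibility Visibility threshold.
#' @return Data frame with columns `subject_id`, `session`, `sex`, `age`,
#'   `height`, `weight`, then the parameters; attribute `"units"` maps
#'   parameters to units.
#' @export
profile_cohort <- function(x, sessions = NULL, min_visibility = 0.5) {
  rows <- list()
  for (s in x$subjects) {
    sess <- if (is.null(sessions)) cohort_sessions(s) else sessions
    for (k in sess) {
      if (length(session_captures(s, k)) == 0) next
      prof <- compute_profile(s, k, min_visibility)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = s$subject_id, session = k, sex = s$sex, age = s$age,
        height = s$height, weight = s$weight,
        as.list(prof), stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "units") <- posture_parameter_units()
  out
}

#' Write a profile table as CSV
#'
#' One row per subject and session; parameter columns carry their unit in
#' the header (e.g. `shoulder_adduction.deg`, `torso_vector.pd`), mirroring
#' the reporting layout of the parameter table.
#'
#' @param profiles Output of [profile_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  out <- profiles
  units <- posture_parameter_units()
  idx <- match(names(units), names(out))
  names(out)[idx[!is.na(idx)]] <-
    paste0(names(units)[!is.na(idx)], ".", units[!is.na(idx)])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
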