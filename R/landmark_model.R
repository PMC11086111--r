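#' Construct a single-view pose capture
#'
#' A capture is one photograph's worth of pose-estimation output: 33 labeled
#' landmarks with image coordinates. The coordinate convention is the usual
#' image convention: `x` in pixels increasing rightward, `y` in pixels
#' increasing *downward* (origin top-left), `z` a pixel-scaled depth
#' increasing away from the camera with origin at the hip midpoint, and
#' `visibility` in `[0, 1]`.
#'
#' @param subject_id Subject identifier (coerced to character).
#' @param session Session number, integer `>= 1`.
#' @param view One of `"frontal"`, `"dorsal"`, `"lateral"`.
#' @param landmarks Data frame with columns `landmark`, `x`, `y`, `z`,
#'   `visibility`: exactly one row per label in [pose_landmarks()].
#' @param image_size Optional `c(width, height)` in pixels.
#' @return An object of class `pose_capture`.
#' @export
pose_capture <- function(subject_id, session, view, landmarks, image_size = NULL) {
  view <- match.arg(view, .pose_views)
  session <- as.integer(session)
  if (is.na(session) || session < 1L) {
    stop_posturekit("`session` must be an integer >= 1", "invalid_capture")
  }
  landmarks <- as.data.frame(landmarks)
  required <- c("landmark", "x", "y", "z", "visibility")
  missing_cols <- setdiff(required, names(landmarks))
  if (length(missing_cols) > 0) {
    stop_posturekit(
      sprintf("landmark table lacks column(s): %s", paste(missing_cols, collapse = ", ")),
      "format_error"
    )
  }
  landmarks <- landmarks[required]
  check_landmark_labels(landmarks$landmark, subject_id, view)
  for (col in c("x", "y", "z", "visibility")) {
    v <- landmarks[[col]]
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v))) {
      stop_posturekit(
        sprintf(
          "non-finite or non-numeric '%s' for subject %s, view %s",
          col, subject_id, view
        ),
        "parse_error"
      )
    }
  }
  if (any(landmarks$visibility < 0 | landmarks$visibility > 1)) {
    stop_posturekit("visibility must lie in [0, 1]", "invalid_capture")
  }
  # canonical row order
  landmarks <- landmarks[match(pose_landmarks(), landmarks$landmark), , drop = FALSE]
  rownames(landmarks) <- landmarks$landmark
  structure(
    list(
      subject_id = as.character(subject_id),
      session = session,
      view = view,
      landmarks = landmarks,
      image_size = if (!is.null(image_size)) as.numeric(image_size) else NULL
    ),
    class = "pose_capture"
  )
}

check_landmark_labels <- function(labels, subject_id, view) {
  labels <- as.character(labels)
  topo <- pose_landmarks()
  missing <- setdiff(topo, labels)
  extra <- setdiff(labels, topo)
  dup <- unique(labels[duplicated(labels)])
  if (length(missing) || length(extra) || length(dup) || length(labels) != 33L) {
    parts <- c(
      if (length(missing)) sprintf("missing: %s", paste(missing, collapse = ", ")),
      if (length(extra)) sprintf("unknown: %s", paste(extra, collapse = ", ")),
      if (length(dup)) sprintf("duplicated: %s", paste(dup, collapse = ", "))
    )
    stop_posturekit(
      sprintf(
        "capture for subject %s (%s view) does not carry the 33 topology labels (%s)",
        subject_id, view, paste(parts, collapse = "; ")
      ),
      "format_error"
    )
  }
  invisible(TRUE)
}

#' @export
print.pose_capture <- function(x, ...) {
  cat(sprintf(
    "<pose_capture> subject %s, session %d, %s view, 33 landmarks\n",
    x$subject_id, x$session, x$view
  ))
  invisible(x)
}

#' Construct a subject record
#'
#' Bundles one subject's anthropometrics with their captures. At most one
#' capture per (session, view) pair is allowed.
#'
#' @param subject_id Identifier.
#' @param sex `"M"` or `"F"` (or `NA` when unknown).
#' @param age Years.
#' @param height Stature in cm.
#' @param weight Body mass in kg.
#' @param captures List of [pose_capture()] objects for this subject.
#' @return An object of class `subject_record`.
#' @export
subject_record <- function(subject_id, sex = NA_character_, age = NA_real_,
                           height = NA_real_, weight = NA_real_,
                           captures = list()) {
  if (!is.na(sex)) sex <- match.arg(sex, c("M", "F"))
  for (cap in captures) {
    stopifnot(inherits(cap, "pose_capture"))
    if (cap$subject_id != as.character(subject_id)) {
      stop_posturekit(
        sprintf("capture subject_id '%s' does not match record '%s'", cap$subject_id, subject_id),
        "invalid_record"
      )
    }
  }
  key <- vapply(captures, function(cp) paste(cp$session, cp$view), "")
  if (anyDuplicated(key)) {
    stop_posturekit(
      sprintf(
        "subject %s has more than one capture for session/view %s",
        subject_id, key[duplicated(key)][1]
      ),
      "invalid_record"
    )
  }
  structure(
    list(
      subject_id = as.character(subject_id), sex = sex, age = as.numeric(age),
      height = as.numeric(height), weight = as.numeric(weight),
      captures = captures
    ),
    class = "subject_record"
  )
}

#' Construct a cohort
#'
#' @param subjects List of [subject_record()] objects with unique ids.
#' @param provenance Free-text provenance (e.g. `"synthetic seed=7"`).
#' @return An object of class `posture_cohort`.
#' @export
cohort <- function(subjects, provenance = "unspecified") {
  ids <- vapply(subjects, function(s) s$subject_id, "")
  if (anyDuplicated(ids)) {
    stop_posturekit(
      sprintf("duplicated subject ids: %s", paste(unique(ids[duplicated(ids)]), collapse = ", ")),
      "invalid_cohort"
    )
  }
  structure(
    list(subjects = subjects, provenance = provenance),
    class = "posture_cohort"
  )
}

#' @export
print.posture_cohort <- function(x, ...) {
  n_cap <- sum(vapply(x$subjects, function(s) length(s$captures), 0L))
  cat(sprintf(
    "<posture_cohort> %d subjects, %d captures (%s)\n",
    length(x$subjects), n_cap, x$provenance
  ))
  invisible(x)
}

#' Extract one landmark's (x, y, z) from a capture
#'
#' @param capture A [pose_capture()].
#' @param label Landmark label.
#' @return Numeric length-3 vector `(x, y, z)`.
#' @export
landmark_xyz <- function(capture, label) {
  row <- capture$landmarks[label, ]
  if (is.na(row$x)) stop_posturekit(sprintf("unknown landmark '%s'", label), "format_error")
  c(x = row$x, y = row$y, z = row$z)
}

landmark_visibility <- function(capture, label) {
  capture$landmarks[label, "visibility"]
}

#' Automatically classify the view of a capture
#'
#' Orientation is inferred from the hip midpoint and the shoulder-hip
#' geometry: a capture is lateral when the projected shoulder width collapses
#' relative to the torso length (width/length below `lateral_ratio`); the
#' frontal/dorsal split follows the shoulder x-ordering, since frontal images
#' mirror anatomical left and right (the subject's left shoulder appears at
#' larger image x when they face the camera).
#'
#' @param capture A [pose_capture()].
#' @param lateral_ratio Width/length threshold below which a capture is
#'   classified lateral. Default 0.35.
#' @param min_visibility Minimum visibility required of shoulders and hips.
#' @return `"frontal"`, `"dorsal"`, or `"lateral"`.
#' @export
detect_view <- function(capture, lateral_ratio = 0.35, min_visibility = 0.5) {
  need <- c("left_shoulder", "right_shoulder", "left_hip", "right_hip")
  vis <- vapply(need, function(l) landmark_visibility(capture, l), 0)
  if (any(vis < min_visibility)) {
    stop_posturekit(
      sprintf(
        "cannot determine orientation: low visibility on %s",
        paste(need[vis < min_visibility], collapse = ", ")
      ),
      "undetectable_orientation"
    )
  }
  ls <- landmark_xyz(capture, "left_shoulder")
  rs <- landmark_xyz(capture, "right_shoulder")
  lh <- landmark_xyz(capture, "left_hip")
  rh <- landmark_xyz(capture, "right_hip")
  width <- sqrt(sum((ls[1:2] - rs[1:2])^2))
  torso <- sqrt(sum(((ls[1:2] + rs[1:2]) / 2 - (lh[1:2] + rh[1:2]) / 2)^2))
  if (torso <= 0) {
    stop_posturekit("degenerate torso (shoulder and hip midpoints coincide)", "undetectable_orientation")
  }
  if (width / torso < lateral_ratio) {
    return("lateral")
  }
  if (ls[["x"]] > rs[["x"]]) "frontal" else "dorsal"
}

#' Validate a capture against the topology and visibility requirements
#'
#' Returns structured findings rather than raising: an empty data frame means
#' the capture satisfies all invariants and every landmark the geometry layer
#' needs is at least `min_visibility` visible.
#'
#' @param capture A [pose_capture()].
#' @param min_visibility Visibility threshold for geometry landmarks.
#' @return Data frame with columns `severity` (`"error"`/`"warning"`),
#'   `label`, `message`; zero rows when pristine.
#' @export
validate_capture <- function(capture, min_visibility = 0.5) {
  findings <- list()
  add <- function(severity, label, message) {
    findings[[length(findings) + 1L]] <<- data.frame(
      severity = severity, label = label, message = message,
      stringsAsFactors = FALSE
    )
  }
  lm <- capture$landmarks
  for (col in c("x", "y", "z")) {
    bad <- !is.finite(lm[[col]])
    for (label in lm$landmark[bad]) {
      add("error", label, sprintf("non-finite %s coordinate", col))
    }
  }
  bad_vis <- lm$visibility < 0 | lm$visibility > 1 | !is.finite(lm$visibility)
  for (label in lm$landmark[bad_vis]) add("error", label, "visibility outside [0, 1]")
  low <- intersect(.geometry_landmarks(), lm$landmark[lm$visibility < min_visibility])
  for (label in low) {
    add(
      "error", label,
      sprintf(
        "visibility %.2f below threshold %.2f for a landmark required by the geometry layer",
        lm[label, "visibility"], min_visibility
      )
    )
  }
  if (!is.null(capture$image_size)) {
    w <- capture$image_size[1]
    h <- capture$image_size[2]
    out <- lm$x < 0 | lm$x > w | lm$y < 0 | lm$y > h
    for (label in lm$landmark[out & is.finite(lm$x) & is.finite(lm$y)]) {
      add("warning", label, "coordinate outside the image bounds")
    }
  }
  if (length(findings) == 0) {
    return(data.frame(
      severity = character(), label = character(), message = character(),
      stringsAsFactors = FALSE
    ))
  }
  do.call(rbind, findings)
}

#' Mirror a capture about a vertical axis
#'
#' Reflects x about the hip-midpoint column and flips depth; turns a frontal
#' capture into a geometrically equivalent dorsal one and vice versa. Used
#' both by tests of view detection and to un-mirror frontal captures so that
#' downstream geometry sees one consistent frame.
#'
#' @param capture A [pose_capture()].
#' @param relabel Flip the `view` label between frontal and dorsal
#'   (default `TRUE`).
#' @return A new `pose_capture`.
#' @export
mirror_capture <- function(capture, relabel = TRUE) {
  lh <- landmark_xyz(capture, "left_hip")
  rh <- landmark_xyz(capture, "right_hip")
  cx <- (lh[["x"]] + rh[["x"]]) / 2
  lm <- capture$landmarks
  lm$x <- 2 * cx - lm$x
  lm$z <- -lm$z
  view <- capture$view
  if (relabel && view %in% c("frontal", "dorsal")) {
    view <- if (view == "frontal") "dorsal" else "frontal"
  }
  pose_capture(capture$subject_id, capture$session, view, lm, capture$image_size)
}

# Un-mirror frontal captures so the geometry layer always works in a
# dorsal-consistent frame. Side identity comes from landmark labels either
# way; this only fixes the handedness of the coordinate frame.
canonicalize_capture <- function(capture) {
  if (capture$view == "frontal") mirror_capture(capture, relabel = FALSE) else capture
}

# ---- shared helpers ---------------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_posturekit <- function(message, subclass, call = sys.call(-1)) {
  stop(errorCondition(
    message,
    class = c(paste0("posturekit_", subclass), "posturekit_error", "error", "condition"),
    call = call
  ))
}

session_captures <- function(record, session) {
  Filter(function(cp) cp$session == session, record$captures)
}

cohort_sessions <- function(record) {
  sort(unique(vapply(record$captures, function(cp) cp$session, 0L)))
}
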