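# Hand-placed toy capture: an upright, left-right symmetric figure in image
# coordinates (y down). Useful for view detection, validation, and symmetry
# tests without invoking the skeleton solver.
toy_landmarks <- function(cx = 500, cy = 1000, scale = 1) {
  pt <- function(dx, dy, dz = 0) c(cx + scale * dx, cy + scale * dy, scale * dz)
  # image y grows downward: head at smaller y than hips
  coords <- list(
    nose = pt(0, -460, -60),
    left_eye_inner = pt(8, -475, -50), left_eye = pt(14, -475, -48),
    left_eye_outer = pt(20, -475, -46),
    right_eye_inner = pt(-8, -475, -50), right_eye = pt(-14, -475, -48),
    right_eye_outer = pt(-20, -475, -46),
    left_ear = pt(40, -455, -10), right_ear = pt(-40, -455, -10),
    mouth_left = pt(12, -440, -48), mouth_right = pt(-12, -440, -48),
    left_shoulder = pt(90, -380, 0), right_shoulder = pt(-90, -380, 0),
    left_elbow = pt(110, -230, 5), right_elbow = pt(-110, -230, 5),
    left_wrist = pt(120, -90, 10), right_wrist = pt(-120, -90, 10),
    left_pinky = pt(125, -50, 10), right_pinky = pt(-125, -50, 10),
    left_index = pt(128, -48, 5), right_index = pt(-128, -48, 5),
    left_thumb = pt(120, -55, 0), right_thumb = pt(-120, -55, 0),
    left_hip = pt(55, 0, 0), right_hip = pt(-55, 0, 0),
    left_knee = pt(55, 190, 0), right_knee = pt(-55, 190, 0),
    left_ankle = pt(55, 370, 0), right_ankle = pt(-55, 370, 0),
    left_heel = pt(55, 395, 10), right_heel = pt(-55, 395, 10),
    left_foot_index = pt(60, 400, -60), right_foot_index = pt(-60, 400, -60)
  )
  data.frame(
    landmark = names(coords),
    x = vapply(coords, `[`, 0, 1),
    y = vapply(coords, `[`, 0, 2),
    z = vapply(coords, `[`, 0, 3),
    visibility = 0.99,
    stringsAsFactors = FALSE
  )
}

toy_capture <- function(view = "frontal", subject_id = "T1", session = 1, ...) {
  pose_capture(subject_id, session, view, toy_landmarks(...), image_size = c(1080, 1920))
}

# small zero-jitter synthetic cohort shared by several geometry tests
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_cohort(
        synthetic_spec(n_subjects = 6, jitter_sd = 0, n_retest = 0),
        seed = 404
      )
    }
    cache
  }
})

quiet_profile <- function(...) suppressWarnings(compute_profile(...))
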