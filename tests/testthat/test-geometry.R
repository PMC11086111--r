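test_that("angle_between matches closed-form cases and rejects degenerate segments", {
  expect_equal(angle_between(c(1, 0, 0), c(0, 1, 0)), 90)
  expect_equal(angle_between(c(1, 1, 0), c(2, 2, 0)), 0, tolerance = 1e-5)
  expect_equal(angle_between(c(1, 0, 0), c(-1, 1e-9, 0)), 180, tolerance = 1e-6)
  expect_error(angle_between(c(0, 0, 0), c(1, 0, 0)), class = "posturekit_degenerate_segment")
})

test_that("circular_mean handles wraparound and degenerate inputs", {
  expect_equal(as.numeric(circular_mean(c(350, 10))), 0)
  expect_equal(as.numeric(circular_mean(c(10, 10, 10))), 10)
  expect_equal(as.numeric(circular_mean(c(0, 90))), 45)
  expect_error(circular_mean(c(0, 180)), class = "posturekit_undefined_mean")
  expect_error(circular_mean(numeric(0)), class = "posturekit_undefined_mean")
})

test_that("circular mean tracks the arithmetic mean on narrow arcs", {
  # exact agreement holds for configurations symmetric about their mean
  # (the view/side fusion case); general narrow arcs agree to within a
  # bound that shrinks with the arc width
  set.seed(11)
  for (rep in 1:25) {
    base <- runif(1, 0, 360)
    half <- runif(2, 0, 45)
    sym <- (base + c(-half, half)) %% 360
    cm <- as.numeric(circular_mean(sym))
    expect_lt(abs(((cm - base + 180) %% 360) - 180), 1e-9)

    for (width in c(90, 10)) {
      angles <- (base + runif(5, 0, width)) %% 360
      cm2 <- as.numeric(circular_mean(angles))
      unwrapped <- angles[1] + ((angles - angles[1] + 180) %% 360 - 180)
      delta <- ((cm2 - mean(unwrapped) + 180) %% 360) - 180
      expect_lt(abs(delta), if (width == 90) 4 else 0.05)
    }
  }
})

test_that("horizontal and vertical inclinations follow the image-axis conventions", {
  expect_equal(horizontal_inclination(c(0, 100), c(50, 100)), 0)
  expect_equal(horizontal_inclination(c(0, 0), c(10, 10)), 45)
  expect_equal(
    horizontal_inclination(c(10, 10), c(0, 0)),
    horizontal_inclination(c(0, 0), c(10, 10))
  )
  expect_equal(vertical_inclination(c(0, 0), c(0, 10)), 0)
  expect_equal(vertical_inclination(c(0, 0), c(10, 10)), 45)
  expect_equal(
    vertical_inclination(c(5, -3), c(15, 7)),
    vertical_inclination(c(105, 97), c(115, 107))
  )
  expect_error(horizontal_inclination(c(1, 1), c(1, 1)), class = "posturekit_degenerate_segment")
})

test_that("joint angles recover constructed poses exactly", {
  # straight arm: shoulder, elbow, wrist collinear -> elbow extension 0
  lm <- toy_landmarks()
  for (side in c("left", "right")) {
    sh <- lm[lm$landmark == paste0(side, "_shoulder"), c("x", "y", "z")]
    wr <- lm[lm$landmark == paste0(side, "_wrist"), c("x", "y", "z")]
    lm[lm$landmark == paste0(side, "_elbow"), c("x", "y", "z")] <-
      (sh + wr) / 2
  }
  va <- joint_angles(pose_capture("S", 1, "frontal", lm))
  expect_equal(unname(va["elbow_extension", ]), c(0, 0), tolerance = 1e-9)

  # thigh plumb under the hip: hip adduction equals the trunk line's tilt
  lm2 <- toy_landmarks()
  cap2 <- pose_capture("S", 1, "frontal", lm2)
  va2 <- joint_angles(cap2)
  hip <- c(555, 1000, 0)
  sh <- c(590, 620, 0)
  knee <- c(555, 1190, 0)
  expected <- 180 - angle_between(knee - hip, sh - hip)
  expect_equal(va2["hip_adduction", "left"], expected, tolerance = 1e-9)

  expect_error(joint_angles(toy_capture("lateral")), class = "posturekit_wrong_view")
})

test_that("view fusion is a circular mean with single-view fallback", {
  f <- joint_angles(toy_capture("frontal"))
  d <- joint_angles(mirror_capture(toy_capture("frontal")))
  fused <- fuse_views(f, d)
  expect_equal(unname(fused["elbow_extension"]),
    as.numeric(circular_mean(c(f["elbow_extension", ], d["elbow_extension", ]))),
    tolerance = 1e-9
  )
  # constant angles fuse to themselves; wraparound respects the circle
  m <- matrix(15, 7, 2, dimnames = list(posture_parameters("joints"), c("left", "right")))
  expect_equal(unname(fuse_views(m, m)), rep(15, 7))
  m1 <- m
  m1[] <- 359
  m2 <- m
  m2[] <- 1
  expect_equal(unname(fuse_views(m1, m2)), rep(0, 7), tolerance = 1e-9)
  expect_warning(fuse_views(frontal = f), "only the frontal")
  expect_error(fuse_views(), class = "posturekit_insufficient_data")
})

test_that("vector lengths match hand geometry and scale homogeneously", {
  lm <- toy_landmarks()
  set_xy <- function(lm, label, x, y) {
    lm[lm$landmark == label, c("x", "y")] <- c(x, y)
    lm
  }
  lm <- set_xy(lm, "left_shoulder", 100, 500)
  lm <- set_xy(lm, "right_shoulder", 0, 500)
  lm <- set_xy(lm, "left_hip", 80, 700)
  lm <- set_xy(lm, "right_hip", 20, 700)
  v <- vector_lengths(pose_capture("S", 1, "frontal", lm))
  expect_equal(unname(v["shoulder_hip_difference"]), 40)
  expect_equal(unname(v["torso_vector"]), 200)

  scaled <- lm
  scaled[c("x", "y", "z")] <- scaled[c("x", "y", "z")] * 2
  v2 <- vector_lengths(pose_capture("S", 1, "frontal", scaled))
  expect_equal(unname(v2), unname(v) * 2, tolerance = 1e-12)
})

test_that("lateral parameters match the arctangent closed form", {
  lm <- toy_landmarks()
  # lateral view: make the left side the camera-facing side
  lm$visibility[startsWith(lm$landmark, "right_")] <- 0.55
  # ear directly above the shoulder -> neck inclination 0
  lm[lm$landmark == "left_ear", c("x", "y")] <- c(590, 545)
  lm[lm$landmark == "left_shoulder", c("x", "y")] <- c(590, 620)
  # shoulder 2 px forward of hip over a 200-px torso
  lm[lm$landmark == "left_hip", c("x", "y")] <- c(588, 820)
  lat <- lateral_parameters(pose_capture("S", 1, "lateral", lm))
  expect_equal(unname(lat["neck_inclination"]), 0)
  expect_equal(unname(lat["trunk_forward_inclination"]), atan(2 / 200) * 180 / pi,
    tolerance = 1e-9
  )
  expect_error(lateral_parameters(toy_capture("frontal")), class = "posturekit_wrong_view")
})

test_that("a perfectly symmetric figure has zero inclinations and imbalance", {
  rec <- subject_record("T1", captures = list(
    toy_capture("frontal"),
    mirror_capture(toy_capture("frontal")),
    toy_capture("lateral") # same geometry, treated as lateral for neck/trunk
  ))
  prof <- quiet_profile(rec, 1)
  for (p in posture_parameters("horizontal")) {
    expect_equal(unname(prof[p]), 0, tolerance = 1e-9)
  }
  expect_equal(unname(prof["body_imbalance"]), 0, tolerance = 1e-9)
})

test_that("profiles flag missing lateral data and still compute the rest", {
  rec <- subject_record("T1", captures = list(toy_capture("frontal")))
  expect_warning(prof <- compute_profile(rec, 1), "lateral")
  expect_true(all(is.na(prof[c("neck_inclination", "trunk_forward_inclination")])))
  expect_false(anyNA(prof[posture_parameters("vectors")]))
  rec2 <- subject_record("T2", captures = list(toy_capture("lateral", subject_id = "T2")))
  expect_error(compute_profile(rec2, 1), class = "posturekit_insufficient_data")
})

test_that("profiles are translation-invariant and angles scale-invariant", {
  g <- small_cohort()
  rec <- g$cohort$subjects[[1]]
  prof <- quiet_profile(rec, 1)
  shift_cap <- function(cap, dx, dy, s = 1) {
    lm <- cap$landmarks
    lm$x <- lm$x * s + dx
    lm$y <- lm$y * s + dy
    lm$z <- lm$z * s
    pose_capture(cap$subject_id, cap$session, cap$view, lm)
  }
  rec_shift <- subject_record(rec$subject_id,
    captures = lapply(rec$captures, shift_cap, dx = 77, dy = -31)
  )
  expect_equal(quiet_profile(rec_shift, 1), prof, tolerance = 1e-9)

  rec_scale <- subject_record(rec$subject_id,
    captures = lapply(rec$captures, shift_cap, dx = 0, dy = 0, s = 2.5)
  )
  prof_scaled <- quiet_profile(rec_scale, 1)
  angles <- setdiff(posture_parameters(), posture_parameters("vectors"))
  expect_equal(prof_scaled[angles], prof[angles], tolerance = 1e-8)
  expect_equal(prof_scaled[posture_parameters("vectors")],
    prof[posture_parameters("vectors")] * 2.5,
    tolerance = 1e-8
  )
})

test_that("reflecting a capture about the body midline leaves the profile unchanged", {
  g <- small_cohort()
  rec <- g$cohort$subjects[[2]]
  rec_mirror <- subject_record(rec$subject_id,
    captures = lapply(rec$captures, function(cap) {
      if (cap$view == "lateral") cap else mirror_capture(cap)
    })
  )
  expect_equal(quiet_profile(rec_mirror, 1), quiet_profile(rec, 1), tolerance = 1e-8)
})
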