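# Forward stick-figure synthesis.
#
# World frame: X toward the subject's anatomical left, Y up, Z forward
# (toward the frontal camera); hip midpoint at the origin. The solver poses
# a 33-landmark skeleton so that the geometry layer's parameter definitions
# evaluate *exactly* to a requested parameter profile:
#   - hip/shoulder/ear lines and the trunk are placed in closed form;
#   - thigh and shank directions are solved from the hip/knee angle
#     constraints (closed-form rotations in the coronal and sagittal
#     planes plus a 1-D trigonometric solve for the 3D hip adduction);
#   - segment lengths are solved by a 4-dimensional Newton iteration so
#     that the knee/ankle (or elbow/wrist) lines, the summed vector
#     lengths, and the mean leg inclination come out exactly;
#   - an outer fixed point reconciles the trunk placement (which needs the
#     ankle midpoint for the body-imbalance line) with the legs.
# Discrete choices (which way a line tilts, which side of the trunk the
# thigh deviates) come from per-subject sign draws; when a sign combination
# is infeasible the solver searches the other branches before giving up.

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

rot2 <- function(v, deg) {
  a <- deg2rad(deg)
  c(cos(a) * v[1] - sin(a) * v[2], sin(a) * v[1] + cos(a) * v[2])
}

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop_posturekit("zero-length direction", "pose_infeasible")
  v / n
}

# Solve psi in A sin(psi) + B cos(psi) = C; returns both wrapped roots.
solve_harmonic <- function(A, B, C) {
  R <- sqrt(A^2 + B^2)
  if (R < abs(C)) {
    return(numeric(0))
  }
  delta <- atan2(B, A)
  base <- asin(max(-1, min(1, C / R)))
  wrap <- function(x) atan2(sin(x), cos(x))
  unique(c(wrap(base - delta), wrap(pi - base - delta)))
}

# Direction of a limb segment given:
#  - g: its unit direction in the sagittal (z, y) plane (as c(z, y));
#  - u: the reference segment (3D) and the target 3D angle to it (deg).
# Returns list of candidate unit 3D directions (x, y, z), downward first.
limb_direction_candidates <- function(g, u, angle3_deg) {
  uh <- unit(u)
  A <- uh[1]
  B <- g[2] * uh[2] + g[1] * uh[3]
  C <- cos(deg2rad(angle3_deg))
  psis <- solve_harmonic(A, B, C)
  cands <- lapply(psis, function(psi) {
    c(sin(psi), cos(psi) * g[2], cos(psi) * g[1])
  })
  cands <- Filter(function(d) d[2] < -1e-9, cands)
  if (length(cands) > 1) {
    cands <- cands[order(vapply(cands, function(d) d[2], 0))] # most downward first
  }
  cands
}

# sagittal-plane unit direction (z, y) rotated off a reference direction
sagittal_dir <- function(ref_zy, offset_deg) {
  unit(rot2(unit(ref_zy), offset_deg))
}

# signed coronal inclination (deg) of the descending line from p to q
signed_incl_xy <- function(p, q) {
  rad2deg(atan2(q[1] - p[1], p[2] - q[2]))
}

# Shoulder midpoint: at distance `torso` from the hip midpoint (hx, 0) and
# on the body-imbalance line through the ankle midpoint `am`.
solve_trunk <- function(am, torso, beta_deg, sign_beta, hx = 0) {
  t <- sign_beta * tan(deg2rad(beta_deg))
  k <- am[1] - t * am[2] - hx
  a <- t^2 + 1
  b <- 2 * t * k
  cc <- k^2 - torso^2
  disc <- b^2 - 4 * a * cc
  if (disc < 0) stop_posturekit("trunk placement infeasible", "pose_infeasible")
  y_s <- (-b + sqrt(disc)) / (2 * a)
  if (y_s <= 0) stop_posturekit("trunk placement infeasible", "pose_infeasible")
  c(hx + k + t * y_s, y_s)
}

# Leg pose for one sign branch. The thigh and shank directions are fixed
# in closed form by the hip/knee angle constraints; of the four remaining
# length constraints, the summed vector length and the knee/ankle line
# slopes are *linear* in the four segment lengths, leaving a one-parameter
# affine family on which the mean leg inclination is solved by a bracketed
# 1-D root find. This yields exact solutions and exact per-branch
# feasibility verdicts (no iterative multi-dimensional solve).
solve_legs <- function(p, H, S, sg, V_leg, split, branch) {
  d <- list()
  e <- list()
  for (side in c("L", "R")) {
    u <- S[[side]] - H[[side]]
    g_thigh <- sagittal_dir(c(u[3], u[2]), 180 + branch$s_he * p[["hip_extension"]])
    cands <- limb_direction_candidates(
      g_thigh, u, 180 - p[["hip_adduction"]]
    )
    if (length(cands) < branch$ha_root) {
      stop_posturekit("hip adduction infeasible", "pose_infeasible")
    }
    dd <- cands[[branch$ha_root]]
    # shank: rotate the thigh's plane projections by the knee deviations;
    # the varus/valgus sign is per side (equal-sign pairs are the mirror-
    # symmetric stance, mixed pairs shift the reachable leg inclination)
    mirror <- if (side == "L") 1 else -1
    s_vv_side <- if (side == "L") branch$s_vv[1] else branch$s_vv[2]
    p_xy <- rot2(unit(dd[1:2]), mirror * s_vv_side * p[["knee_varus_valgus"]])
    q_zy <- rot2(unit(c(dd[3], dd[2])), branch$s_ke * p[["knee_extension"]])
    if (abs(p_xy[2]) < 1e-9 || abs(q_zy[2]) < 1e-9) {
      stop_posturekit("degenerate shank direction", "pose_infeasible")
    }
    ee <- unit(c(p_xy[1] / p_xy[2], 1, q_zy[1] / q_zy[2]))
    if (ee[2] > 0) ee <- -ee
    d[[side]] <- dd
    e[[side]] <- ee
  }
  r_d <- lapply(d, function(v) sqrt(sum(v[1:2]^2)))
  r_e <- lapply(e, function(v) sqrt(sum(v[1:2]^2)))
  t_knee <- branch$s_kl * tan(deg2rad(p[["knee_line"]]))
  t_ankle <- branch$s_al * tan(deg2rad(p[["ankle_line"]]))
  lambda_t <- p[["leg_inclination"]]
  dH <- H$L - H$R
  # linear constraints A x = b in x = (LtL, LsL, LtR, LsR)
  A <- rbind(
    c(r_d$L, r_e$L, r_d$R, r_e$R) / 2,
    c(d$L[2] - t_knee * d$L[1], 0, -(d$R[2] - t_knee * d$R[1]), 0),
    c(
      d$L[2] - t_ankle * d$L[1], e$L[2] - t_ankle * e$L[1],
      -(d$R[2] - t_ankle * d$R[1]), -(e$R[2] - t_ankle * e$R[1])
    )
  )
  b <- c(
    V_leg,
    -(dH[2] - t_knee * dH[1]),
    -(dH[2] - t_ankle * dH[1])
  )
  AAt <- A %*% t(A)
  if (rcond(AAt) < 1e-12) stop_posturekit("degenerate leg system", "pose_infeasible")
  x0 <- drop(t(A) %*% solve(AAt, b)) # minimum-norm particular solution
  u_null <- svd(A, nu = 0, nv = 4)$v[, 4]
  # positivity interval for the segment lengths along x0 + tau * u
  len_min <- 10
  tau_lo <- -Inf
  tau_hi <- Inf
  for (i in 1:4) {
    if (abs(u_null[i]) < 1e-12) {
      if (x0[i] < len_min) stop_posturekit("leg lengths infeasible", "pose_infeasible")
    } else if (u_null[i] > 0) {
      tau_lo <- max(tau_lo, (len_min - x0[i]) / u_null[i])
    } else {
      tau_hi <- min(tau_hi, (len_min - x0[i]) / u_null[i])
    }
  }
  if (!is.finite(tau_lo) || !is.finite(tau_hi) || tau_lo >= tau_hi) {
    stop_posturekit("leg lengths infeasible", "pose_infeasible")
  }
  pos <- function(tau) {
    x <- x0 + tau * u_null
    K_L <- H$L + x[1] * d$L
    A_L <- K_L + x[2] * e$L
    K_R <- H$R + x[3] * d$R
    A_R <- K_R + x[4] * e$R
    list(x = x, K_L = K_L, A_L = A_L, K_R = K_R, A_R = A_R)
  }
  f <- function(tau) {
    q <- pos(tau)
    (abs(signed_incl_xy(H$L, q$A_L)) + abs(signed_incl_xy(H$R, q$A_R))) / 2 - lambda_t
  }
  grid <- seq(tau_lo, tau_hi, length.out = 49)
  fv <- vapply(grid, f, 0)
  root <- NA_real_
  for (i in seq_len(length(grid) - 1)) {
    if (is.finite(fv[i]) && is.finite(fv[i + 1]) &&
        (fv[i] == 0 || sign(fv[i]) != sign(fv[i + 1]))) {
      root <- if (fv[i] == 0) {
        grid[i]
      } else {
        stats::uniroot(f, c(grid[i], grid[i + 1]), tol = 1e-12)$root
      }
      break
    }
  }
  f_gap <- 0
  if (!is.finite(root)) {
    # no exact root on the family: clamp to the nearest-achievable
    # inclination. The caller iterates the whole-body geometry (the trunk
    # lean responds to where the ankles land), so an exact root may appear
    # at the converged geometry; the final solution is only accepted with
    # a vanishing gap.
    j <- which.min(abs(fv))
    lo_j <- grid[max(1, j - 1)]
    hi_j <- grid[min(length(grid), j + 1)]
    opt <- stats::optimize(function(t) f(t)^2, c(lo_j, hi_j), tol = 1e-12)
    root <- opt$minimum
    f_gap <- f(root)
  }
  q <- pos(root)
  list(
    d = d, e = e, lengths = q$x, K = list(L = q$K_L, R = q$K_R),
    A = list(L = q$A_L, R = q$A_R),
    f_gap = f_gap, window = lambda_t + range(fv)
  )
}

`%or_one%` <- function(a, b) if (is.na(a) || a == 0) b else a

# Arm pose: directions are closed-form (shoulder adduction and elbow
# extension), and all four length constraints (summed vector, elbow line,
# wrist line, thigh/forearm split on the left) are linear.
solve_arms <- function(p, S, H, sg, V_arm, split, s_el, s_wl) {
  a <- list()
  b <- list()
  for (side in c("L", "R")) {
    u <- H[[side]] - S[[side]] # shoulder -> hip, points down
    g_arm <- unit(c(u[3], u[2]))
    cands <- limb_direction_candidates(g_arm, u, p[["shoulder_adduction"]])
    if (length(cands) == 0) stop_posturekit("shoulder adduction infeasible", "pose_infeasible")
    # lateral root: elbow outside the trunk line
    lat <- if (side == "L") {
      which.max(vapply(cands, function(v) v[1], 0))
    } else {
      which.min(vapply(cands, function(v) v[1], 0))
    }
    aa <- cands[[lat]]
    w0 <- c(0, 0, 1)
    w_perp <- unit(w0 - sum(w0 * aa) * aa)
    bb <- cos(deg2rad(p[["elbow_extension"]])) * aa +
      sin(deg2rad(p[["elbow_extension"]])) * w_perp
    a[[side]] <- aa
    b[[side]] <- bb
  }
  r_a <- lapply(a, function(v) sqrt(sum(v[1:2]^2)))
  r_b <- lapply(b, function(v) sqrt(sum(v[1:2]^2)))
  t_el <- s_el * tan(deg2rad(p[["elbow_line"]]))
  t_wl <- s_wl * tan(deg2rad(p[["wrist_line"]]))
  ratio <- (1 - split) / split
  dS <- S$L - S$R
  M <- rbind(
    c(r_a$L, r_b$L, r_a$R, r_b$R) / 2,
    c(a$L[2] - t_el * a$L[1], 0, -(a$R[2] - t_el * a$R[1]), 0),
    c(
      a$L[2] - t_wl * a$L[1], b$L[2] - t_wl * b$L[1],
      -(a$R[2] - t_wl * a$R[1]), -(b$R[2] - t_wl * b$R[1])
    ),
    c(-ratio, 1, 0, 0)
  )
  rhs <- c(
    V_arm,
    -(dS[2] - t_el * dS[1]),
    -(dS[2] - t_wl * dS[1]),
    0
  )
  if (rcond(M) < 1e-12) stop_posturekit("degenerate arm system", "pose_infeasible")
  x <- drop(solve(M, rhs))
  if (any(x < 10)) stop_posturekit("arm lengths infeasible", "pose_infeasible")
  E_L <- S$L + x[1] * a$L
  W_L <- E_L + x[2] * b$L
  E_R <- S$R + x[3] * a$R
  W_R <- E_R + x[4] * b$R
  list(a = a, b = b, lengths = x, E = list(L = E_L, R = E_R), W = list(L = W_L, R = W_R))
}

build_skeleton_branch <- function(p, sg, cfg, branch, hx = 0) {
  W_h <- cfg$hip_width
  W_s <- W_h + p[["shoulder_hip_difference"]]
  if (W_s < 30) stop_posturekit("shoulder width collapses", "pose_infeasible")
  torso <- p[["torso_vector"]]
  alpha_h <- sg[["hip_line"]] * p[["hip_line"]]
  half_h <- (W_h / 2) * c(cos(deg2rad(alpha_h)), sin(deg2rad(alpha_h)), 0)
  # hx translates the whole figure laterally (gauge freedom; the default 0
  # centers the hip midpoint)
  H <- list(L = c(hx, 0, 0) + half_h, R = c(hx, 0, 0) - half_h)

  # the trunk needs the ankle midpoint (body-imbalance line) while the legs
  # need the shoulders (hip adduction): reconciled by a secant iteration on
  # the ankle-midpoint x (the plain fixed point is non-contractive)
  alpha_s <- sg[["shoulder_line"]] * p[["shoulder_line"]]
  half_s <- (W_s / 2) * c(cos(deg2rad(alpha_s)), sin(deg2rad(alpha_s)), 0)
  eval_at <- function(am, br) {
    S_m <- c(solve_trunk(am, torso, p[["body_imbalance"]], sg[["body_imbalance"]], hx), 0)
    S <- list(L = S_m + half_s, R = S_m - half_s)
    z_S <- tan(deg2rad(p[["trunk_forward_inclination"]])) * (S$L[2] - H$L[2])
    S$L[3] <- z_S
    S$R[3] <- z_S
    legs <- solve_legs(p, H, S, sg, p[["total_leg_vector"]], cfg$leg_split, br)
    list(S = S, legs = legs, am = (legs$A$L[1:2] + legs$A$R[1:2]) / 2)
  }
  ay <- -0.9 * p[["total_leg_vector"]]
  ax_a <- hx
  ev <- eval_at(c(ax_a, ay), branch)
  h_a <- ev$am[1] - ax_a
  ay <- ev$am[2]
  ax_b <- ax_a + h_a
  converged <- abs(h_a) < 1e-9
  for (iter in 1:80) {
    if (converged) break
    ev <- eval_at(c(ax_b, ay), branch)
    h_b <- ev$am[1] - ax_b
    ay <- ev$am[2]
    if (abs(h_b) < 1e-9) {
      converged <- TRUE
      break
    }
    denom <- h_b - h_a
    ax_new <- if (abs(denom) < 1e-15) ax_b + h_b else ax_b - h_b * (ax_b - ax_a) / denom
    ax_a <- ax_b
    h_a <- h_b
    ax_b <- ax_new
  }
  if (!converged) stop_posturekit("trunk/leg reconciliation did not converge", "pose_infeasible")
  # final re-evaluation so every part is consistent with the converged point
  ev <- eval_at(ev$am, branch)
  S <- ev$S
  legs <- ev$legs
  if (abs(legs$f_gap) > 1e-9) {
    # the leg inclination stayed out of reach at the converged geometry;
    # expose the reachable window for conditional redraws
    stop(errorCondition(
      "leg inclination out of reach on the feasible length family",
      class = c(
        "posturekit_pose_infeasible", "posturekit_error", "error", "condition"
      ),
      lo = legs$window[1], hi = legs$window[2]
    ))
  }

  arms <- solve_arms(
    p, S, H, sg, p[["total_arm_vector"]], cfg$arm_split,
    sg[["elbow_line"]], sg[["wrist_line"]]
  )

  # head: ear line over the shoulder midpoint; neck inclination sets ear depth
  S_mid <- (S$L + S$R) / 2
  E_m <- S_mid + c(0, cfg$neck_length, 0)
  alpha_e <- sg[["ear_line"]] * p[["ear_line"]]
  half_e <- (cfg$ear_width / 2) * c(cos(deg2rad(alpha_e)), sin(deg2rad(alpha_e)), 0)
  Ear <- list(L = E_m + half_e, R = E_m - half_e)
  z_E <- S$L[3] + tan(deg2rad(p[["neck_inclination"]])) * (Ear$L[2] - S$L[2])
  Ear$L[3] <- z_E
  Ear$R[3] <- z_E

  # feet: out-toed, posed so the 3D ankle-flexion angle is exact
  toe <- deg2rad(cfg$out_toe_deg)
  feet <- list()
  heels <- list()
  for (side in c("L", "R")) {
    ee <- legs$e[[side]]
    w0 <- c(if (side == "L") sin(toe) else -sin(toe), 0, cos(toe))
    w_perp <- unit(w0 - sum(w0 * ee) * ee)
    f <- cos(deg2rad(p[["ankle_flexion"]])) * (-ee) + sin(deg2rad(p[["ankle_flexion"]])) * w_perp
    feet[[side]] <- legs$A[[side]] + cfg$foot_length * f
    heels[[side]] <- legs$A[[side]] - 0.35 * cfg$foot_length * w_perp
  }

  # hands and face: plausible, unscored placements
  hands <- list()
  for (side in c("L", "R")) {
    bb <- arms$b[[side]]
    Wp <- arms$W[[side]]
    hands[[side]] <- list(
      pinky = Wp + cfg$hand_length * bb + c(0, 0, -4),
      index = Wp + cfg$hand_length * bb + c(0, 0, 6),
      thumb = Wp + 0.55 * cfg$hand_length * bb + c(0, 0, 12)
    )
  }
  face_pt <- function(dx, dy, dz) c(E_m[1] + dx, E_m[2] + dy, z_E + dz)
  face <- list(
    nose = face_pt(0, 0.1 * cfg$neck_length, 55),
    left_eye_inner = face_pt(12, 0.22 * cfg$neck_length, 45),
    left_eye = face_pt(20, 0.22 * cfg$neck_length, 42),
    left_eye_outer = face_pt(28, 0.22 * cfg$neck_length, 38),
    right_eye_inner = face_pt(-12, 0.22 * cfg$neck_length, 45),
    right_eye = face_pt(-20, 0.22 * cfg$neck_length, 42),
    right_eye_outer = face_pt(-28, 0.22 * cfg$neck_length, 38),
    mouth_left = face_pt(14, -0.05 * cfg$neck_length, 48),
    mouth_right = face_pt(-14, -0.05 * cfg$neck_length, 48)
  )

  pts <- list(
    nose = face$nose,
    left_eye_inner = face$left_eye_inner, left_eye = face$left_eye,
    left_eye_outer = face$left_eye_outer,
    right_eye_inner = face$right_eye_inner, right_eye = face$right_eye,
    right_eye_outer = face$right_eye_outer,
    left_ear = Ear$L, right_ear = Ear$R,
    mouth_left = face$mouth_left, mouth_right = face$mouth_right,
    left_shoulder = S$L, right_shoulder = S$R,
    left_elbow = arms$E$L, right_elbow = arms$E$R,
    left_wrist = arms$W$L, right_wrist = arms$W$R,
    left_pinky = hands$L$pinky, right_pinky = hands$R$pinky,
    left_index = hands$L$index, right_index = hands$R$index,
    left_thumb = hands$L$thumb, right_thumb = hands$R$thumb,
    left_hip = H$L, right_hip = H$R,
    left_knee = legs$K$L, right_knee = legs$K$R,
    left_ankle = legs$A$L, right_ankle = legs$A$R,
    left_heel = heels$L, right_heel = heels$R,
    left_foot_index = feet$L, right_foot_index = feet$R
  )
  pts
}

skeleton_branches <- function(sg) {
  vv_pairs <- list(c(1, -1), c(-1, 1), c(1, 1), c(-1, -1))
  line_pairs <- list(c(1, 1), c(-1, 1), c(1, -1), c(-1, -1)) # (knee, ankle) flips
  grid <- expand.grid(
    vv = seq_along(vv_pairs), ha_root = c(1L, 2L), f_he = c(1, -1), f_ke = c(1, -1),
    KEEP.OUT.ATTRS = FALSE
  )
  branches <- list()
  for (lp in line_pairs) {
    for (i in seq_len(nrow(grid))) {
      branches[[length(branches) + 1L]] <- list(
        ha_root = grid$ha_root[i],
        s_vv = vv_pairs[[grid$vv[i]]] * sg[["knee_varus_valgus"]],
        s_he = grid$f_he[i] * sg[["hip_extension"]],
        s_ke = grid$f_ke[i] * sg[["knee_extension"]],
        s_kl = lp[1] * sg[["knee_line"]],
        s_al = lp[2] * sg[["ankle_line"]]
      )
    }
  }
  branches
}

#' Pose a 3D stick-figure skeleton realizing a parameter profile
#'
#' Solves landmark positions (world frame: x toward anatomical left, y up,
#' z forward, hip midpoint at origin) such that the geometry layer's
#' parameter definitions evaluate exactly to `profile`. Discrete tilt
#' directions come from `signs`; infeasible sign combinations fall back to
#' the other branches, and an error of class
#' `posturekit_pose_infeasible` is raised when no branch realizes the
#' profile.
#'
#' @param profile Named vector of the postural parameters
#'   ([posture_parameters()] names).
#' @param signs Named vector of tilt directions (+1/-1); default all +1.
#' @param skeleton Skeleton proportion overrides (see [synthetic_spec()]).
#' @param profile Named vector of the postural parameters
#'   ([posture_parameters()] names).
#' @param signs Named vector of tilt directions (+1/-1); default all +1.
#' @param skeleton Skeleton proportion overrides (see [synthetic_spec()]).
#' @return Named list of 33 world-space 3-vectors. On failure the raised
#'   condition carries `lambda_lo`/`lambda_hi`, the union of the reachable
#'   leg-inclination windows over the sign branches.
#' @export
solve_skeleton <- function(profile, signs = NULL, skeleton = list()) {
  cfg <- synthetic_spec(skeleton = skeleton)$skeleton
  if (is.null(signs)) {
    signs <- stats::setNames(rep(1, 11), c(
      "ear_line", "shoulder_line", "elbow_line", "wrist_line", "hip_line",
      "knee_line", "ankle_line", "body_imbalance", "knee_varus_valgus",
      "hip_extension", "knee_extension"
    ))
  }
  err <- NULL
  w_lo <- Inf
  w_hi <- -Inf
  for (branch in skeleton_branches(signs)) {
    pts <- withCallingHandlers(
      tryCatch(
        build_skeleton_branch(profile, signs, cfg, branch),
        posturekit_pose_infeasible = function(e) NULL
      ),
      posturekit_pose_infeasible = function(e) {
        if (!is.null(e$lo)) {
          w_lo <<- min(w_lo, e$lo)
          w_hi <<- max(w_hi, e$hi)
        }
      }
    )
    if (is.null(pts)) next
    achieved <- tryCatch(
      skeleton_profile(pts, cfg),
      posturekit_error = function(e) NULL
    )
    if (is.null(achieved)) next
    gap <- max(abs(achieved[names(profile)] - profile))
    if (is.finite(gap) && gap < 1e-7) {
      return(pts)
    }
    err <- gap
  }
  stop(errorCondition(
    sprintf(
      "no skeleton branch realizes this profile (best residual %s)",
      format(err)
    ),
    class = c(
      "posturekit_pose_infeasible", "posturekit_error", "error", "condition"
    ),
    lambda_lo = if (is.finite(w_lo)) w_lo else NULL,
    lambda_hi = if (is.finite(w_hi)) w_hi else NULL
  ))
}

# measure a world skeleton through the real capture pipeline (zero jitter)
skeleton_profile <- function(pts, cfg) {
  caps <- lapply(c("frontal", "dorsal", "lateral"), function(view) {
    project_skeleton(pts, view, cfg, subject_id = "chk", session = 1L)
  })
  rec <- subject_record("chk", captures = caps)
  suppressWarnings(compute_profile(rec, 1L))
}

#' Project a world skeleton to a single-view pose capture
#'
#' Applies the view's camera model in y-down image coordinates: the frontal
#' view mirrors anatomical left/right (the subject faces the camera), the
#' dorsal view is direct, and the lateral view is taken from the subject's
#' left with the far side down-weighted in visibility. Depth keeps the
#' upstream convention (hip-midpoint origin, increasing away from the
#' camera). Optional isotropic Gaussian jitter is added to every
#' coordinate.
#'
#' @param pts Skeleton from [solve_skeleton()].
#' @param view `"frontal"`, `"dorsal"`, or `"lateral"`.
#' @param cfg Skeleton configuration (for image center/size).
#' @param subject_id,session Capture identity fields.
#' @param jitter_sd Landmark jitter SD in px (default 0); uses the current
#'   RNG state.
#' @return A [pose_capture()].
#' @export
project_skeleton <- function(pts, view, cfg = synthetic_spec()$skeleton,
                             subject_id = "S1", session = 1L, jitter_sd = 0) {
  cx <- cfg$center[1]
  cy <- cfg$center[2]
  labels <- pose_landmarks()
  m <- t(vapply(labels, function(l) pts[[l]], numeric(3)))
  img <- switch(view,
    frontal = cbind(cx + m[, 1], cy - m[, 2], -m[, 3]),
    dorsal = cbind(cx - m[, 1], cy - m[, 2], m[, 3]),
    lateral = cbind(cx - m[, 3], cy - m[, 2], -m[, 1])
  )
  if (jitter_sd > 0) {
    img <- img + matrix(stats::rnorm(length(img), 0, jitter_sd), nrow(img), 3)
  }
  vis <- rep(0.98, length(labels))
  if (view == "lateral") {
    vis[startsWith(labels, "right_")] <- 0.55
    vis[labels %in% c("nose", "mouth_left", "mouth_right")] <- 0.85
  }
  pose_capture(
    subject_id, session, view,
    data.frame(
      landmark = labels, x = img[, 1], y = img[, 2], z = img[, 3],
      visibility = vis, stringsAsFactors = FALSE
    ),
    image_size = cfg$image_size
  )
}

#' Synthesize one capture from a parameter profile
#'
#' Convenience wrapper: poses the skeleton for `profile` and projects it to
#' the requested view with optional landmark jitter.
#'
#' @param profile Named parameter vector.
#' @param view Target view.
#' @param signs Tilt-direction signs (see [solve_skeleton()]).
#' @param jitter_sd Landmark jitter SD in px.
#' @param skeleton Skeleton proportion overrides.
#' @param subject_id,session Capture identity fields.
#' @return A [pose_capture()].
#' @export
synthesize_capture <- function(profile, view, signs = NULL, jitter_sd = 0,
                               skeleton = list(), subject_id = "S1", session = 1L) {
  cfg <- synthetic_spec(skeleton = skeleton)$skeleton
  pts <- solve_skeleton(profile, signs, skeleton)
  project_skeleton(pts, view, cfg, subject_id, session, jitter_sd)
}

#' Generate a full synthetic cohort with captures and ground truth
#'
#' Per subject: parameters and anthropometrics are drawn, both sessions'
#' measurement-error profiles are formed, a skeleton is solved per session,
#' and frontal/dorsal/lateral captures are projected with landmark jitter.
#' Session-2 captures are produced for the retest subgroup. The result is
#' bit-reproducible from (`spec`, `seed`). A subject whose drawn profile
#' admits no feasible pose is redrawn (this slightly truncates the extreme
#' joint tails of the parameter distributions).
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed (default 20230315).
#' @param captures Solve skeletons and emit landmark captures (default
#'   `TRUE`); `FALSE` skips landmark synthesis and returns the cohort
#'   shell with ground-truth profiles only (fast path for parameter-space
#'   studies).
#' @return List with `cohort` (a [cohort()]) and `truth`
#'   (`posture_ground_truth`).
#' @export
generate_cohort <- function(spec = synthetic_spec(), seed = 20230315L, captures = TRUE) {
  set.seed(seed)
  n <- spec$n_subjects
  n_men <- round(n * spec$sex_ratio)
  sexes <- sample(rep(c("M", "F"), c(n_men, n - n_men)))
  draws <- vector("list", n)
  all_caps <- vector("list", n)
  for (i in seq_len(n)) {
    dr <- draw_subject(spec, sexes[i])
    caps <- NULL
    if (captures) {
      # a drawn profile can be geometrically inconsistent (parameters are
      # drawn independently but are coupled in a real body). Redraw
      # escalation keeps the distributional distortion local: first the
      # leg inclination alone, then the small-tilt block, and only then
      # the whole subject.
      window <- NULL
      for (attempt in 1:40) {
        sess <- session_profiles_from(dr$profile, dr$sess_err, spec)
        sessions_needed <- if (i <= spec$n_retest) c("1", "2") else "1"
        caps <- tryCatch(
          {
            out <- list()
            for (s in sessions_needed) {
              pts <- solve_skeleton(sess[[s]], dr$signs, spec$skeleton)
              for (view in c("frontal", "dorsal", "lateral")) {
                out[[length(out) + 1L]] <- project_skeleton(
                  pts, view, spec$skeleton,
                  subject_id = sprintf("S%03d", i), session = as.integer(s),
                  jitter_sd = spec$jitter_sd
                )
              }
            }
            out
          },
          posturekit_pose_infeasible = function(e) {
            window <<- if (!is.null(e$lambda_lo)) c(e$lambda_lo, e$lambda_hi)
            NULL
          }
        )
        if (!is.null(caps)) break
        if (attempt == 40) {
          stop_posturekit(
            sprintf("subject %d: no feasible pose after staged redraws", i),
            "pose_infeasible"
          )
        }
        dr2 <- NULL
        if (attempt <= 10) {
          dr2 <- redraw_lambda(dr, spec, window)
        } else if (attempt <= 16) {
          dr2 <- redraw_parameters(
            dr, spec,
            c("leg_inclination", "knee_varus_valgus", "body_imbalance")
          )
        }
        dr <- if (is.null(dr2)) draw_subject(spec, sexes[i]) else dr2
      }
    }
    draws[[i]] <- dr
    all_caps[[i]] <- caps
  }
  truth <- assemble_truth(draws, spec)
  subjects <- lapply(seq_len(n), function(i) {
    subject_record(
      subject_id = truth$subjects$subject_id[i],
      sex = truth$subjects$sex[i], age = truth$subjects$age[i],
      height = truth$subjects$height[i], weight = truth$subjects$weight[i],
      captures = if (captures) all_caps[[i]] else list()
    )
  })
  list(
    cohort = cohort(subjects, provenance = sprintf("synthetic seed=%d", seed)),
    truth = truth
  )
}
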