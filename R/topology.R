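#' The 33-landmark whole-body pose topology
#'
#' Landmark labels of the standard 33-keypoint pose-estimation topology
#' (nose, eyes with inner/outer corners, ears, mouth corners, and the
#' bilateral shoulder/elbow/wrist/hand/hip/knee/ankle/foot chain), in
#' canonical order — the layout emitted by MediaPipe Pose / BlazePose-style
#' models. Every [pose_capture()] carries exactly one landmark per label.
#' Left/right refer to the subject's anatomical side throughout.
#'
#' @return Character vector of 33 landmark labels.
#' @export
#' @examples
#' length(pose_landmarks())
pose_landmarks <- function() {
  c(
    "nose",
    "left_eye_inner", "left_eye", "left_eye_outer",
    "right_eye_inner", "right_eye", "right_eye_outer",
    "left_ear", "right_ear",
    "mouth_left", "mouth_right",
    "left_shoulder", "right_shoulder",
    "left_elbow", "right_elbow",
    "left_wrist", "right_wrist",
    "left_pinky", "right_pinky",
    "left_index", "right_index",
    "left_thumb", "right_thumb",
    "left_hip", "right_hip",
    "left_knee", "right_knee",
    "left_ankle", "right_ankle",
    "left_heel", "right_heel",
    "left_foot_index", "right_foot_index"
  )
}

# landmarks that the geometry layer consumes; validation checks their visibility
.geometry_landmarks <- function() {
  c(
    "left_ear", "right_ear",
    "left_shoulder", "right_shoulder",
    "left_elbow", "right_elbow",
    "left_wrist", "right_wrist",
    "left_hip", "right_hip",
    "left_knee", "right_knee",
    "left_ankle", "right_ankle",
    "left_foot_index", "right_foot_index"
  )
}

.pose_views <- c("frontal", "dorsal", "lateral")
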