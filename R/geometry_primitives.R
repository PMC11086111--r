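#' Angle between two 3-vectors
#'
#' Arc-cosine of the clamped normalized dot product, in degrees.
#'
#' @param u,v Numeric vectors of length 2 or 3.
#' @return Angle in degrees, in `[0, 180]`.
#' @export
#' @examples
#' angle_between(c(1, 0, 0), c(0, 1, 0)) # 90
angle_between <- function(u, v) {
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu < 1e-12 || nv < 1e-12) {
    stop_posturekit("zero-length segment in angle computation", "degenerate_segment")
  }
  ct <- sum(u * v) / (nu * nv)
  ct <- min(1, max(-1, ct))
  acos(ct) * 180 / pi
}

# angle between the projections of u and v onto the coordinate plane given by
# two dimension indices (e.g. c(1, 2) for the image plane, c(3, 2) for the
# sagittal depth-vertical plane)
angle_between_plane <- function(u, v, dims) {
  angle_between(u[dims], v[dims])
}

#' Circular mean of angles in degrees
#'
#' Mean direction via the resultant of unit vectors, robust to 0/360
#' wraparound. The resultant length is attached as attribute `"resultant"`
#' for diagnostics; a resultant below `1e-9` (e.g. `c(0, 180)`) has no
#' defined mean direction and raises an error.
#'
#' @param angles Numeric vector of angles in degrees (non-empty).
#' @return Mean direction in degrees, in `[0, 360)`.
#' @export
#' @examples
#' circular_mean(c(350, 10)) # 0
circular_mean <- function(angles) {
  if (length(angles) == 0) {
    stop_posturekit("circular mean of an empty set", "undefined_mean")
  }
  rad <- angles * pi / 180
  s <- mean(sin(rad))
  c_ <- mean(cos(rad))
  r <- sqrt(s^2 + c_^2)
  if (r < 1e-9) {
    stop_posturekit("circular mean undefined: resultant length ~ 0", "undefined_mean")
  }
  mu <- atan2(s, c_) * 180 / pi
  mu <- mu %% 360
  if (360 - mu < 1e-9) mu <- 0 # fold the wraparound rounding artifact
  attr(mu, "resultant") <- r
  mu
}

#' Horizontal inclination of a bilateral landmark line
#'
#' Absolute acute angle, in degrees, between the left-to-right segment
#' (projected onto the image plane) and the image horizontal axis. This is
#' the study's asymmetry index for paired landmarks ("shoulder line" etc.).
#'
#' @param left,right Landmark coordinates: numeric `(x, y)` or `(x, y, z)`.
#' @return Degrees in `[0, 90]`.
#' @export
horizontal_inclination <- function(left, right) {
  dx <- right[[1]] - left[[1]]
  dy <- right[[2]] - left[[2]]
  if (abs(dx) < 1e-12 && abs(dy) < 1e-12) {
    stop_posturekit("coincident landmarks in horizontal inclination", "degenerate_segment")
  }
  atan2(abs(dy), abs(dx)) * 180 / pi
}

#' Vertical inclination of a segment
#'
#' Absolute acute angle, in degrees, between the segment (image-plane
#' projection) and the image vertical axis: 0 for a plumb line.
#'
#' @param top,bottom Landmark coordinates: numeric `(x, y)` or `(x, y, z)`.
#' @return Degrees in `[0, 90]`.
#' @export
vertical_inclination <- function(top, bottom) {
  dx <- bottom[[1]] - top[[1]]
  dy <- bottom[[2]] - top[[2]]
  if (abs(dx) < 1e-12 && abs(dy) < 1e-12) {
    stop_posturekit("coincident landmarks in vertical inclination", "degenerate_segment")
  }
  atan2(abs(dx), abs(dy)) * 180 / pi
}

# image-plane (x, y) Euclidean distance
dist_xy <- function(p, q) {
  sqrt((p[[1]] - q[[1]])^2 + (p[[2]] - q[[2]])^2)
}
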