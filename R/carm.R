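# C-arm projection geometry.
#
# Patient frame is DICOM LPS (+x left, +y posterior, +z superior). The
# central beam of a pose (alpha, beta) runs source -> detector along
#   v = (sin a cos b, -cos a cos b, sin b),
# so AP (0, 0) looks along -y, LAO90 along +x, CRAN90 along +z. The detector
# row axis is the horizontal patient axis rotated by alpha,
#   u = (cos a, sin a, 0),
# which is orthogonal to v for every beta; the column axis w = v x u
# completes the right-handed frame (u, w, v).

.deg2rad <- function(d) d * pi / 180
.rad2deg <- function(r) r * 180 / pi
.normalize <- function(v) v / sqrt(sum(v^2))
.cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])

#' Central beam direction of a C-arm pose
#'
#' Unit vector from the x-ray source toward the detector in patient LPS
#' coordinates.
#'
#' @param pose a \linkS4class{CArmPose}.
#' @return numeric(3) unit vector.
#' @examples
#' viewingDirection(CArmPose(0, 0))   # c(0, -1, 0): frontal AP beam
#' @export
viewingDirection <- function(pose) {
  stopifnot(is(pose, "CArmPose"))
  a <- .deg2rad(pose@alpha_deg); b <- .deg2rad(pose@beta_deg)
  c(sin(a) * cos(b), -cos(a) * cos(b), sin(b))
}

#' Recover gantry angles from a beam direction
#'
#' Inverse of \code{\link{viewingDirection}}: beta = asin(v_z),
#' alpha = atan2(v_x, -v_y). At |beta| = 90 (beam along the patient axis)
#' alpha is degenerate and reported as 0.
#'
#' @param v numeric(3) unit vector.
#' @param sod_mm,sid_mm,pixel_spacing_mm geometry carried into the returned
#'   pose.
#' @return A \linkS4class{CArmPose}.
#' @export
poseFromDirection <- function(v, sod_mm = 765, sid_mm = 1100,
                              pixel_spacing_mm = c(0.2, 0.2)) {
  if (length(v) != 3 || !.is_unit(v, 1e-6))
    stop("v must be a unit 3-vector")
  vz <- max(-1, min(1, v[3]))
  beta <- asin(vz)
  alpha <- if (abs(abs(vz) - 1) < 1e-12) 0 else atan2(v[1], -v[2])
  if (alpha <= -pi + 1e-15) alpha <- pi   # atan2(-0, -1) branch
  CArmPose(.rad2deg(alpha), .rad2deg(beta), sod_mm, sid_mm, pixel_spacing_mm)
}

.detector_frame <- function(pose) {
  a <- .deg2rad(pose@alpha_deg)
  v <- viewingDirection(pose)
  u <- c(cos(a), sin(a), 0)
  w <- .cross3(v, u)
  list(u = u, w = w, v = v, source = -pose@sod_mm * v)
}

#' Perspective projection onto the detector
#'
#' Cone-beam projection: the source sits at -SOD along the beam from the
#' isocenter, the detector plane is orthogonal to the beam at distance SID
#' from the source. Returns in-plane detector coordinates (mm) relative to
#' the principal point. With \code{sid_mm = Inf} the projection is parallel
#' (magnification 1).
#'
#' @param pose a \linkS4class{CArmPose}.
#' @param p numeric(3) point (mm), or an n x 3 matrix of points.
#' @return numeric(2), or an n x 2 matrix.
#' @examples
#' projectPoint(CArmPose(-25, -25), c(0, 0, 0))  # isocenter -> (0, 0)
#' @export
projectPoint <- function(pose, p) {
  fr <- .detector_frame(pose)
  P <- if (is.matrix(p)) p else matrix(p, ncol = 3)
  d <- sweep(P, 2, fr$source)                       # source -> point
  depth <- drop(d %*% fr$v)
  if (is.infinite(pose@sid_mm)) {
    q <- cbind(drop(d %*% fr$u), drop(d %*% fr$w))
  } else {
    if (any(depth <= 0)) stop("point at or behind the x-ray source")
    if (any(depth >= pose@sid_mm)) stop("point at or beyond the detector")
    mag <- pose@sid_mm / depth
    q <- cbind(drop(d %*% fr$u) * mag, drop(d %*% fr$w) * mag)
  }
  if (is.matrix(p)) q else drop(q)
}

#' Back-project a detector point to its projection line
#'
#' The ray from the x-ray source through the given detector position,
#' oriented source -> detector. These are the projection lines whose
#' intersections with the surface mesh localize an annotation in 3D. In
#' parallel mode the ray through the detector point runs along the beam.
#'
#' @param pose a \linkS4class{CArmPose}.
#' @param q numeric(2) detector point (mm, relative to the principal point).
#' @return A \linkS4class{Ray}.
#' @export
backprojectLine <- function(pose, q) {
  stopifnot(length(q) == 2)
  fr <- .detector_frame(pose)
  if (is.infinite(pose@sid_mm)) {
    Ray(fr$source + q[1] * fr$u + q[2] * fr$w, fr$v)
  } else {
    det_pt <- fr$source + pose@sid_mm * fr$v + q[1] * fr$u + q[2] * fr$w
    Ray(fr$source, det_pt - fr$source)
  }
}

#' Angle between two C-arm viewing directions
#'
#' The 3D angle between the central beams, in degrees in \[0, 180\]. This is
#' the geometrically meaningful separation of two projections, not the
#' Euclidean distance in (alpha, beta) space.
#'
#' @param a,b \linkS4class{CArmPose} objects.
#' @return numeric(1) degrees.
#' @export
angularDifference <- function(a, b) {
  va <- viewingDirection(a); vb <- viewingDirection(b)
  # atan2 form: full precision near 0 and 180 where acos degrades
  .rad2deg(atan2(sqrt(sum(.cross3(va, vb)^2)), sum(va * vb)))
}
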