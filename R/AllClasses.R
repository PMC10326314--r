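#' @import methods
NULL

.unit_tol <- 1e-9

.is_unit <- function(v, tol = .unit_tol) abs(sqrt(sum(v^2)) - 1) <= tol

#' C-arm pose: gantry angulation and projective distances
#'
#' Describes one fluoroscopic imaging geometry: the primary (RAO/LAO) and
#' secondary (CRAN/CAUD) gantry angles, the source-to-isocenter distance
#' (SOD), the source-to-detector distance (SID) and the detector pixel pitch.
#' Angles follow the DICOM C-arm positioner convention: primary positive =
#' LAO, negative = RAO; secondary positive = CRAN, negative = CAUD. The
#' clinically recommended working projection RAO20-30/CAUD20-30 therefore
#' corresponds to \code{alpha} in \[-30, -20\] and \code{beta} in \[-30, -20\].
#'
#' @slot alpha_deg numeric(1), primary angulation in degrees.
#' @slot beta_deg numeric(1), secondary angulation in degrees.
#' @slot sod_mm numeric(1), source-to-isocenter distance (mm).
#' @slot sid_mm numeric(1), source-to-detector distance (mm); \code{Inf}
#'   selects the parallel-projection mode used for analytic tests.
#' @slot pixel_spacing_mm numeric(2), detector row/column pitch (mm).
#' @export
setClass("CArmPose", representation(
  alpha_deg = "numeric", beta_deg = "numeric",
  sod_mm = "numeric", sid_mm = "numeric", pixel_spacing_mm = "numeric"
))

setValidity("CArmPose", function(object) {
  msg <- character()
  a <- object@alpha_deg; b <- object@beta_deg
  if (length(a) != 1 || !is.finite(a) || a <= -180 || a > 180)
    msg <- c(msg, "alpha_deg must be a single value in (-180, 180]")
  if (length(b) != 1 || !is.finite(b) || b < -90 || b > 90)
    msg <- c(msg, "beta_deg must be a single value in [-90, 90]")
  if (!(object@sod_mm > 0)) msg <- c(msg, "sod_mm must be > 0")
  if (!(object@sid_mm > object@sod_mm)) msg <- c(msg, "sid_mm must exceed sod_mm")
  if (length(object@pixel_spacing_mm) != 2 || any(object@pixel_spacing_mm <= 0))
    msg <- c(msg, "pixel_spacing_mm must be two positive values")
  if (length(msg)) msg else TRUE
})

#' Construct a C-arm pose
#'
#' @param alpha_deg primary angulation (degrees, positive = LAO).
#' @param beta_deg secondary angulation (degrees, positive = CRAN).
#' @param sod_mm source-to-isocenter distance (mm).
#' @param sid_mm source-to-detector distance (mm); \code{Inf} for the
#'   parallel-projection mode.
#' @param pixel_spacing_mm detector pixel pitch, recycled to length 2.
#' @return A \linkS4class{CArmPose}.
#' @examples
#' CArmPose(-25, -25)  # RAO25/CAUD25
#' @export
CArmPose <- function(alpha_deg = 0, beta_deg = 0, sod_mm = 765,
                     sid_mm = 1100, pixel_spacing_mm = c(0.2, 0.2)) {
  new("CArmPose", alpha_deg = as.numeric(alpha_deg),
      beta_deg = as.numeric(beta_deg), sod_mm = as.numeric(sod_mm),
      sid_mm = as.numeric(sid_mm),
      pixel_spacing_mm = rep(as.numeric(pixel_spacing_mm), length.out = 2))
}

setMethod("show", "CArmPose", function(object) {
  lab_a <- if (object@alpha_deg < 0) sprintf("RAO%g", -object@alpha_deg)
           else sprintf("LAO%g", object@alpha_deg)
  lab_b <- if (object@beta_deg < 0) sprintf("CAUD%g", -object@beta_deg)
           else sprintf("CRAN%g", object@beta_deg)
  cat(sprintf("CArmPose %s/%s  (alpha=%.2f, beta=%.2f)  SOD=%g SID=%g mm\n",
              lab_a, lab_b, object@alpha_deg, object@beta_deg,
              object@sod_mm, object@sid_mm))
})

#' Projection ray
#'
#' A half-line in patient coordinates, oriented source-to-detector.
#'
#' @slot origin numeric(3), ray origin (mm).
#' @slot direction numeric(3), unit direction.
#' @export
setClass("Ray", representation(origin = "numeric", direction = "numeric"))

setValidity("Ray", function(object) {
  if (length(object@origin) != 3 || length(object@direction) != 3)
    return("origin and direction must be length-3")
  if (!.is_unit(object@direction)) return("direction must be a unit vector")
  TRUE
})

#' @rdname Ray-class
#' @param origin,direction ray origin and direction (direction is normalized).
#' @return A \linkS4class{Ray}.
#' @export
Ray <- function(origin, direction) {
  n <- sqrt(sum(direction^2))
  if (n == 0) stop("ray direction must be nonzero")
  new("Ray", origin = as.numeric(origin), direction = as.numeric(direction) / n)
}

#' Triangulated surface mesh
#'
#' Vertices in mm, patient (LPS) coordinates; faces as 1-based vertex index
#' triples. Intended to be watertight for sectioning and voxelization; the
#' constructor warns when boundary edges are present.
#'
#' @slot vertices numeric matrix, n x 3 (mm).
#' @slot faces integer matrix, m x 3 (1-based indices).
#' @export
setClass("SurfaceMesh", representation(vertices = "matrix", faces = "matrix"))

setValidity("SurfaceMesh", function(object) {
  v <- object@vertices; f <- object@faces
  if (ncol(v) != 3) return("vertices must be n x 3")
  if (ncol(f) != 3) return("faces must be m x 3")
  if (nrow(f) > 0) {
    if (min(f) < 1 || max(f) > nrow(v)) return("face indices out of range")
    a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
    b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
    cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                a[, 1] * b[, 2] - a[, 2] * b[, 1])
    area2 <- rowSums(cr^2)
    if (any(area2 <= (2 * 1e-12)^2)) return("degenerate (zero-area) faces present")
  }
  TRUE
})

#' @rdname SurfaceMesh-class
#' @param vertices n x 3 numeric matrix of vertex coordinates (mm).
#' @param faces m x 3 matrix of 1-based vertex indices.
#' @param check_watertight warn when the mesh has boundary edges.
#' @return A \linkS4class{SurfaceMesh}.
#' @export
SurfaceMesh <- function(vertices, faces, check_watertight = TRUE) {
  m <- new("SurfaceMesh", vertices = as.matrix(vertices),
           faces = matrix(as.integer(as.matrix(faces)), ncol = 3))
  if (check_watertight && !isWatertight(m))
    warning("mesh is not watertight; sectioning and voxelization may misbehave")
  m
}

#' @rdname SurfaceMesh-class
#' @param object,mesh a \code{SurfaceMesh}.
#' @export
setGeneric("meshVertices", function(mesh) standardGeneric("meshVertices"))
#' @rdname SurfaceMesh-class
#' @export
setMethod("meshVertices", "SurfaceMesh", function(mesh) mesh@vertices)
#' @rdname SurfaceMesh-class
#' @export
setGeneric("meshFaces", function(mesh) standardGeneric("meshFaces"))
#' @rdname SurfaceMesh-class
#' @export
setMethod("meshFaces", "SurfaceMesh", function(mesh) mesh@faces)

setMethod("show", "SurfaceMesh", function(object) {
  cat(sprintf("SurfaceMesh: %d vertices, %d faces%s\n",
              nrow(object@vertices), nrow(object@faces),
              if (isWatertight(object)) ", watertight" else " (open)"))
})

#' Rigid transform (rotation + translation)
#'
#' @slot rotation 3 x 3 orthonormal matrix with determinant +1.
#' @slot translation numeric(3) (mm).
#' @export
setClass("RigidTransform",
         representation(rotation = "matrix", translation = "numeric"))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3, 3))) return("rotation must be 3 x 3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-9) return("rotation not orthonormal")
  if (abs(det(R) - 1) > 1e-9) return("rotation must have det +1 (no reflection)")
  if (length(object@translation) != 3) return("translation must be length-3")
  TRUE
})

#' @rdname RigidTransform-class
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 translation (mm).
#' @return A \linkS4class{RigidTransform}.
#' @export
RigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = rotation,
      translation = as.numeric(translation))
}

#' Planar cross-section of a mesh
#'
#' One or more closed intersection loops of a plane with a surface, expressed
#' as 2D polygons in an orthonormal in-plane frame. Loops are ordered by
#' descending enclosed area.
#'
#' @slot plane_point numeric(3), a point on the plane (mm).
#' @slot plane_normal numeric(3), unit normal.
#' @slot in_plane_axes 3 x 2 matrix, orthonormal in-plane axes (columns).
#' @slot polygons list of k x 2 matrices, closed loops (first vertex not
#'   repeated) in plane coordinates (mm).
#' @export
setClass("PlanarSection", representation(
  plane_point = "numeric", plane_normal = "numeric",
  in_plane_axes = "matrix", polygons = "list"
))

setValidity("PlanarSection", function(object) {
  n <- object@plane_normal; A <- object@in_plane_axes
  if (!.is_unit(n)) return("plane_normal must be unit")
  if (!all(dim(A) == c(3, 2))) return("in_plane_axes must be 3 x 2")
  G <- crossprod(A)
  if (max(abs(G - diag(2))) > 1e-9) return("in-plane axes not orthonormal")
  if (max(abs(crossprod(A, n))) > 1e-9) return("in-plane axes not orthogonal to normal")
  for (p in object@polygons)
    if (!is.matrix(p) || ncol(p) != 2 || nrow(p) < 3)
      return("each polygon must be a k x 2 matrix with k >= 3")
  TRUE
})

setMethod("show", "PlanarSection", function(object) {
  cat(sprintf("PlanarSection: %d loop(s) on plane through (%.1f, %.1f, %.1f), normal (%.3f, %.3f, %.3f)\n",
              length(object@polygons), object@plane_point[1],
              object@plane_point[2], object@plane_point[3],
              object@plane_normal[1], object@plane_normal[2],
              object@plane_normal[3]))
  if (length(object@polygons))
    cat(sprintf("  largest loop: perimeter %.2f mm, area %.2f mm^2\n",
                polygonPerimeter(object@polygons[[1]]),
                polygonArea(object@polygons[[1]])))
})

#' Landing zone localized in 3D
#'
#' The pair of wall points obtained by intersecting the back-projected
#' annotation rays with the surface, plus the derived cross-section plane.
#'
#' @slot endpoint_a,endpoint_b numeric(3), wall points (mm).
#' @slot plane_point numeric(3), the midpoint.
#' @slot plane_normal numeric(3), unit normal of the landing plane.
#' @slot source_pose the \linkS4class{CArmPose} the annotation was made in.
#' @export
setClass("LandingZone", representation(
  endpoint_a = "numeric", endpoint_b = "numeric",
  plane_point = "numeric", plane_normal = "numeric",
  source_pose = "CArmPose"
))

setValidity("LandingZone", function(object) {
  if (!.is_unit(object@plane_normal)) return("plane_normal must be unit")
  seg <- object@endpoint_b - object@endpoint_a
  if (abs(sum(seg * object@plane_normal)) > 1e-9 * max(1, sqrt(sum(seg^2))))
    return("plane_normal must be orthogonal to the endpoint segment")
  TRUE
})

setMethod("show", "LandingZone", function(object) {
  d <- sqrt(sum((object@endpoint_b - object@endpoint_a)^2))
  cat(sprintf("LandingZone: endpoint span %.2f mm, midpoint (%.1f, %.1f, %.1f)\n",
              d, object@plane_point[1], object@plane_point[2],
              object@plane_point[3]))
})

#' 3D image volume
#'
#' Scalar voxel array with spacing, origin and axis orientation, using the
#' center-of-voxel convention: voxel (i, j, k) (0-based) sits at
#' \code{origin + direction \%*\% (spacing * c(i, j, k))}.
#'
#' @slot data 3D numeric array.
#' @slot spacing numeric(3), voxel pitch (mm).
#' @slot origin numeric(3), center of voxel (0,0,0) (mm).
#' @slot direction 3 x 3 orthonormal axis matrix (columns = voxel axes).
#' @export
setClass("ImageVolume", representation(
  data = "array", spacing = "numeric", origin = "numeric",
  direction = "matrix"
))

setValidity("ImageVolume", function(object) {
  if (length(dim(object@data)) != 3) return("data must be a 3D array")
  if (length(object@spacing) != 3 || any(object@spacing <= 0))
    return("spacing must be three positive values")
  if (length(object@origin) != 3) return("origin must be length-3")
  D <- object@direction
  if (!all(dim(D) == c(3, 3)) || max(abs(crossprod(D) - diag(3))) > 1e-6)
    return("direction must be 3 x 3 orthonormal")
  TRUE
})

#' @rdname ImageVolume-class
#' @param data,spacing,origin,direction slots, see class description.
#' @return An \linkS4class{ImageVolume}.
#' @export
ImageVolume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        direction = diag(3)) {
  new("ImageVolume", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin), direction = direction)
}

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("ImageVolume: %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3]))
})

#' Multiplanar reconstruction image
#'
#' A 2D reformat of an \linkS4class{ImageVolume} on an arbitrary plane.
#' Pixel (i, j) (0-based) maps to
#' \code{plane_point + i * spacing\[1\] * axes\[,1\] + j * spacing\[2\] * axes\[,2\]}
#' after centering.
#'
#' @slot data 2D numeric array.
#' @slot spacing numeric(2), in-plane pixel pitch (mm).
#' @slot plane_point numeric(3), 3D location of the image center (mm).
#' @slot plane_axes 3 x 2 orthonormal in-plane axes.
#' @export
setClass("MprImage", representation(
  data = "matrix", spacing = "numeric", plane_point = "numeric",
  plane_axes = "matrix"
))

setValidity("MprImage", function(object) {
  if (length(object@spacing) != 2 || any(object@spacing <= 0))
    return("spacing must be two positive values")
  A <- object@plane_axes
  if (!all(dim(A) == c(3, 2)) || max(abs(crossprod(A) - diag(2))) > 1e-9)
    return("plane_axes must be 3 x 2 orthonormal")
  TRUE
})

setMethod("show", "MprImage", function(object) {
  cat(sprintf("MprImage: %d x %d pixels, spacing (%g, %g) mm\n",
              nrow(object@data), ncol(object@data),
              object@spacing[1], object@spacing[2]))
})

#' Landing-zone sizing report
#'
#' All diameter metrics of one cross-section: maximum and minimum caliper
#' diameters, the perimeter-derived diameter p / pi, the area-derived
#' diameter 2 sqrt(a / pi), and the ovality d_max - d_min.
#'
#' @slot d_max_mm,d_min_mm,d_peri_mm,d_area_mm,ovality_mm lengths (mm).
#' @slot perimeter_mm,area_mm2 raw section measures.
#' @slot source character, provenance tag (e.g. "CMR-prospective" for d,
#'   "XR-located" for d').
#' @export
setClass("SizingReport", representation(
  d_max_mm = "numeric", d_min_mm = "numeric", d_peri_mm = "numeric",
  d_area_mm = "numeric", ovality_mm = "numeric",
  perimeter_mm = "numeric", area_mm2 = "numeric", source = "character"
))

setValidity("SizingReport", function(object) {
  v <- c(object@d_max_mm, object@d_min_mm, object@d_peri_mm,
         object@d_area_mm, object@perimeter_mm, object@area_mm2)
  if (any(v <= 0)) return("all metrics must be positive")
  if (object@d_min_mm > object@d_max_mm + 1e-9) return("d_min must not exceed d_max")
  if (object@ovality_mm < -1e-9) return("ovality must be >= 0")
  TRUE
})

setMethod("show", "SizingReport", function(object) {
  cat(sprintf(paste0("SizingReport [%s]\n",
                     "  d_max  %.2f mm   d_min %.2f mm   ovality %.2f mm\n",
                     "  d_peri %.2f mm   d_area %.2f mm  (p = %.2f mm, a = %.2f mm^2)\n"),
              object@source, object@d_max_mm, object@d_min_mm,
              object@ovality_mm, object@d_peri_mm, object@d_area_mm,
              object@perimeter_mm, object@area_mm2))
})

#' @rdname SizingReport-class
#' @param report a \code{SizingReport}.
#' @return one-row \code{data.frame} with all metrics.
#' @export
asSizingRow <- function(report) {
  data.frame(source = report@source, d_max_mm = report@d_max_mm,
             d_min_mm = report@d_min_mm, d_peri_mm = report@d_peri_mm,
             d_area_mm = report@d_area_mm, ovality_mm = report@ovality_mm,
             perimeter_mm = report@perimeter_mm, area_mm2 = report@area_mm2)
}

#' Parametric LAA-like phantom specification
#'
#' A tubular anatomy swept along a straight or circular-arc centerline with
#' elliptical cross-sections whose semi-axes taper linearly and whose
#' orientation may twist along the tube; the landing zone is a designated
#' normalized arc-length position with analytic ground truth.
#'
#' @slot centerline character, "straight" or "arc".
#' @slot length_mm tube length along the centerline (mm).
#' @slot arc_radius_mm centerline radius of curvature (arc only; mm).
#' @slot semi_a_mm,semi_b_mm numeric(2), semi-axis values at s = 0 and s = 1
#'   (linear taper; mm). a is the major, b the minor axis.
#' @slot twist_deg numeric(2), in-plane section rotation at s = 0 and s = 1.
#' @slot circumferential_segments,longitudinal_segments mesh resolution.
#' @slot landing_s normalized arc-length of the landing zone, in (0, 1).
#' @slot rng_seed integer seed for any stochastic downstream use.
#' @export
setClass("PhantomSpec", representation(
  centerline = "character", length_mm = "numeric", arc_radius_mm = "numeric",
  semi_a_mm = "numeric", semi_b_mm = "numeric", twist_deg = "numeric",
  circumferential_segments = "numeric", longitudinal_segments = "numeric",
  landing_s = "numeric", rng_seed = "numeric"
))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (!object@centerline %in% c("straight", "arc"))
    msg <- c(msg, "centerline must be 'straight' or 'arc'")
  if (!(object@length_mm > 0)) msg <- c(msg, "length_mm must be > 0")
  if (any(object@semi_a_mm <= 0) || any(object@semi_b_mm <= 0))
    msg <- c(msg, "semi-axes must be positive everywhere")
  if (any(object@semi_b_mm > object@semi_a_mm + 1e-12))
    msg <- c(msg, "semi_a must be the major axis (a >= b)")
  if (object@circumferential_segments < 16 || object@longitudinal_segments < 16)
    msg <- c(msg, "resolution must be at least 16 x 16")
  if (!(object@landing_s > 0 && object@landing_s < 1))
    msg <- c(msg, "landing_s must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' @rdname PhantomSpec-class
#' @param centerline,length_mm,arc_radius_mm,semi_a_mm,semi_b_mm,twist_deg
#'   geometry parameters, see class description; semi-axes and twist are
#'   recycled to length 2 (start/end values).
#' @param circumferential_segments,longitudinal_segments mesh resolution.
#' @param landing_s landing-zone position in (0, 1).
#' @param rng_seed integer seed.
#' @return A \linkS4class{PhantomSpec}.
#' @export
PhantomSpec <- function(centerline = "straight", length_mm = 60,
                        arc_radius_mm = Inf, semi_a_mm = 12, semi_b_mm = 10,
                        twist_deg = 0, circumferential_segments = 128,
                        longitudinal_segments = 64, landing_s = 0.5,
                        rng_seed = 1L) {
  new("PhantomSpec", centerline = centerline, length_mm = as.numeric(length_mm),
      arc_radius_mm = as.numeric(arc_radius_mm),
      semi_a_mm = rep(as.numeric(semi_a_mm), length.out = 2),
      semi_b_mm = rep(as.numeric(semi_b_mm), length.out = 2),
      twist_deg = rep(as.numeric(twist_deg), length.out = 2),
      circumferential_segments = circumferential_segments,
      longitudinal_segments = longitudinal_segments,
      landing_s = landing_s, rng_seed = as.numeric(rng_seed))
}

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(paste0("PhantomSpec: %s tube, length %g mm, a %g->%g mm, ",
                     "b %g->%g mm, twist %g->%g deg, %d x %d, landing at s=%.2f\n"),
              object@centerline, object@length_mm, object@semi_a_mm[1],
              object@semi_a_mm[2], object@semi_b_mm[1], object@semi_b_mm[2],
              object@twist_deg[1], object@twist_deg[2],
              object@circumferential_segments, object@longitudinal_segments,
              object@landing_s))
})
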