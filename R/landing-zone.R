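# Landing-zone localization: back-project the two fluoroscopic annotation
# endpoints, intersect the projection lines with the surface, pick the wall
# pair, build the cross-section plane, and measure on it.

#' Localize a 2D landing-zone annotation in 3D on the mesh
#'
#' Each annotation endpoint is back-projected to its projection line and
#' intersected with the surface; among all candidate hit pairs (one hit per
#' ray) the pair minimizing the absolute depth difference along the viewing
#' direction is selected - the two endpoints of a measured diameter lie on
#' opposite walls at the same depth. The landing plane is then built with
#' \code{\link{landingPlane}}.
#'
#' @param mesh a \linkS4class{SurfaceMesh} registered to the XR geometry.
#' @param pose the annotation's \linkS4class{CArmPose}.
#' @param q_a,q_b numeric(2) detector endpoints (mm, principal-point frame).
#' @return A \linkS4class{LandingZone}.
#' @export
localizeLandingZone <- function(mesh, pose, q_a, q_b) {
  ray_a <- backprojectLine(pose, q_a)
  ray_b <- backprojectLine(pose, q_b)
  hits_a <- intersectRayMesh(mesh, ray_a)
  hits_b <- intersectRayMesh(mesh, ray_b)
  if (nrow(hits_a) == 0) stop("ray A misses mesh")
  if (nrow(hits_b) == 0) stop("ray B misses mesh")
  v <- viewingDirection(pose)
  da <- drop(hits_a %*% v); db <- drop(hits_b %*% v)
  disp <- abs(outer(da, db, "-"))
  ij <- which(disp == min(disp), arr.ind = TRUE)[1, ]
  a <- hits_a[ij[1], ]; b <- hits_b[ij[2], ]
  pl <- landingPlane(a, b, v)
  new("LandingZone", endpoint_a = a, endpoint_b = b,
      plane_point = pl$plane_point, plane_normal = pl$plane_normal,
      source_pose = pose)
}

#' Cross-section plane through a localized diameter
#'
#' The plane containing both wall endpoints and the viewing direction:
#' normal = normalize((b - a) x view). Under the ideal tangential view both
#' the measured segment and the beam lie in the anatomical cross-section
#' plane, so this reconstructs it.
#'
#' @param endpoint_a,endpoint_b numeric(3) wall points (mm).
#' @param view_dir numeric(3) beam direction.
#' @return list with \code{plane_point} (midpoint) and \code{plane_normal}.
#' @export
landingPlane <- function(endpoint_a, endpoint_b, view_dir) {
  seg <- endpoint_b - endpoint_a
  if (sqrt(sum(seg^2)) < 1e-9) stop("endpoints coincide")
  n <- .cross3(seg, view_dir)
  if (sqrt(sum(n^2)) < 1e-9 * sqrt(sum(seg^2)) * sqrt(sum(view_dir^2)))
    stop("segment is parallel to the viewing direction")
  list(plane_point = (endpoint_a + endpoint_b) / 2, plane_normal = .normalize(n))
}

#' Measure the cross-section of a landing zone
#'
#' Sections the mesh with the landing plane and returns the section with the
#' loop whose (area) centroid is nearest the landing-zone midpoint promoted
#' to first position - in lobed anatomies the nearest loop is the anatomical
#' cross-section even if a larger lobe is also cut.
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @param zone a \linkS4class{LandingZone}.
#' @return A \linkS4class{PlanarSection} whose first polygon is the selected
#'   loop.
#' @export
measureCrossSection <- function(mesh, zone) {
  stopifnot(is(zone, "LandingZone"))
  sec <- planeSection(mesh, zone@plane_point, zone@plane_normal)
  mid2 <- drop(crossprod(sec@in_plane_axes, zone@plane_point - sec@plane_point))
  cent <- vapply(sec@polygons, .polygon_centroid, numeric(2))
  d2 <- colSums((cent - mid2)^2)
  ord <- order(d2)
  sec@polygons <- sec@polygons[ord]
  sec
}

.polygon_centroid <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- x[c(2:length(x), 1)]; yn <- y[c(2:length(y), 1)]
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(p))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# 3D coordinates of a section loop.
.loop3d <- function(section, which = 1) {
  p <- section@polygons[[which]]
  sweep(p %*% t(section@in_plane_axes), 2, section@plane_point, "+")
}

#' Diameter of a section as seen in a projection
#'
#' Orthogonally projects the selected loop onto the plane perpendicular to
#' the viewing direction of \code{pose} and returns the maximum pairwise
#' distance of the projected vertices: the apparent (possibly foreshortened)
#' diameter measured in that projection.
#'
#' @param section a \linkS4class{PlanarSection}.
#' @param pose a \linkS4class{CArmPose}.
#' @param which index of the loop to use (default the first/selected one).
#' @return numeric(1), mm.
#' @export
projectedDiameter <- function(section, pose, which = 1) {
  if (length(section@polygons) < which) stop("no such section loop")
  pts <- .loop3d(section, which)
  if (nrow(pts) < 3) stop("degenerate section loop")
  v <- viewingDirection(pose)
  proj <- pts - outer(drop(pts %*% v), v)
  max(stats::dist(proj))
}
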