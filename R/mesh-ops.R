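# Mesh geometry kernel: watertightness, rigid transforms, Kabsch point
# registration, ray-mesh and plane-mesh intersection, planar polygon metrics.

#' Test whether a mesh is watertight
#'
#' A closed (boundary-free) 2-manifold has every undirected edge shared by
#' exactly two faces. Watertightness is required for the even-parity ray
#' test used by voxelization and guarantees closed section loops.
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @return logical(1).
#' @export
isWatertight <- function(mesh) {
  f <- mesh@faces
  if (nrow(f) == 0) return(FALSE)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Apply a rigid transform to a mesh
#'
#' Maps every vertex x to R x + t; connectivity is unchanged.
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @param transform a \linkS4class{RigidTransform}.
#' @return transformed \linkS4class{SurfaceMesh}.
#' @export
applyTransform <- function(mesh, transform) {
  stopifnot(is(mesh, "SurfaceMesh"), is(transform, "RigidTransform"))
  v <- mesh@vertices %*% t(transform@rotation)
  v <- sweep(v, 2, transform@translation, "+")
  SurfaceMesh(v, mesh@faces, check_watertight = FALSE)
}

#' Least-squares rigid registration of paired point sets
#'
#' Kabsch/Umeyama alignment: the rotation and translation minimizing
#' sum ||R s_i + t - t_i||^2, computed from the SVD of the cross-covariance
#' with reflection correction (det(R) is forced to +1, so a mirrored target
#' is fit as well as a proper rotation allows, never by a reflection).
#' Stands in for the interactive mesh-to-XR registration step of the
#' clinical workflow.
#'
#' @param source,target n x 3 matrices of corresponding points, n >= 3,
#'   not collinear.
#' @return list with \code{transform} (a \linkS4class{RigidTransform}) and
#'   \code{rms_mm}, the root-mean-square residual.
#' @export
registerPoints <- function(source, target) {
  S <- as.matrix(source); Tg <- as.matrix(target)
  if (nrow(S) != nrow(Tg)) stop("point counts differ")
  if (nrow(S) < 3) stop("at least 3 point pairs required")
  cs <- colMeans(S); ct <- colMeans(Tg)
  S0 <- sweep(S, 2, cs); T0 <- sweep(Tg, 2, ct)
  sv <- svd(crossprod(S0, T0))
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1))
    stop("points are collinear; rotation is not determined")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- ct - drop(R %*% cs)
  res <- T0 - S0 %*% t(R)
  list(transform = RigidTransform(R, t_vec),
       rms_mm = sqrt(mean(rowSums(res^2))))
}

# Moller-Trumbore over all triangles, vectorized. Inclusive barycentric
# bounds (eps) keep hits on shared edges/vertices; duplicates from adjacent
# triangles are merged afterwards.
.ray_mesh_t <- function(mesh, origin, direction, eps = 1e-12) {
  v <- mesh@vertices; f <- mesh@faces
  p0 <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - p0
  e2 <- v[f[, 3], , drop = FALSE] - p0
  d <- direction
  pv <- cbind(d[2] * e2[, 3] - d[3] * e2[, 2],
              d[3] * e2[, 1] - d[1] * e2[, 3],
              d[1] * e2[, 2] - d[2] * e2[, 1])
  det <- rowSums(e1 * pv)
  ok <- abs(det) > 1e-14
  tv <- sweep(-p0, 2, origin, "+")         # origin - p0
  u <- rowSums(tv * pv) / det
  qv <- cbind(tv[, 2] * e1[, 3] - tv[, 3] * e1[, 2],
              tv[, 3] * e1[, 1] - tv[, 1] * e1[, 3],
              tv[, 1] * e1[, 2] - tv[, 2] * e1[, 1])
  tt <- rowSums(e2 * qv) / det
  vv <- d[1] * qv[, 1] + d[2] * qv[, 2] + d[3] * qv[, 3]
  vv <- vv / det
  hit <- ok & u >= -eps & vv >= -eps & (u + vv) <= 1 + eps & tt > 1e-9
  tt[hit]
}

#' Intersect a ray with a surface mesh
#'
#' All ray-triangle intersections, sorted by distance from the ray origin.
#' Hits closer than \code{dedup_mm} to each other (grazing hits on shared
#' edges or vertices) are merged.
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @param ray a \linkS4class{Ray}.
#' @param dedup_mm merge tolerance for coincident hits (mm).
#' @return n x 3 matrix of hit points (0 rows when the ray misses).
#' @export
intersectRayMesh <- function(mesh, ray, dedup_mm = 1e-6) {
  stopifnot(is(mesh, "SurfaceMesh"), is(ray, "Ray"))
  tt <- sort(.ray_mesh_t(mesh, ray@origin, ray@direction))
  if (length(tt) > 1) tt <- tt[c(TRUE, diff(tt) > dedup_mm)]
  if (length(tt) == 0) return(matrix(numeric(0), ncol = 3))
  outer(tt, ray@direction) + matrix(ray@origin, length(tt), 3, byrow = TRUE)
}

# Orthonormal in-plane axes for a unit normal (deterministic choice).
.plane_axes <- function(normal) {
  ref <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  a1 <- .normalize(.cross3(ref, normal))
  a2 <- .cross3(normal, a1)
  cbind(a1, a2)
}

#' Cut a mesh with a plane
#'
#' Computes all closed intersection loops of the plane with the surface and
#' returns them as 2D polygons in an orthonormal in-plane frame, ordered by
#' descending enclosed area. Lobed anatomies can legitimately produce
#' several loops; selection is left to the caller.
#'
#' @param mesh a watertight \linkS4class{SurfaceMesh}.
#' @param plane_point numeric(3), a point on the plane.
#' @param plane_normal numeric(3), plane normal (normalized internally).
#' @return A \linkS4class{PlanarSection}.
#' @export
planeSection <- function(mesh, plane_point, plane_normal) {
  stopifnot(is(mesh, "SurfaceMesh"))
  n <- .normalize(plane_normal)
  v <- mesh@vertices; f <- mesh@faces
  sd <- drop(sweep(v, 2, plane_point) %*% n)
  scale <- max(abs(sd), 1)
  # nudge vertices lying exactly on the plane so every crossing is transversal
  on_plane <- abs(sd) < 1e-12 * scale
  sd[on_plane] <- 1e-12 * scale
  s1 <- sd[f[, 1]]; s2 <- sd[f[, 2]]; s3 <- sd[f[, 3]]
  crossing <- (pmin(s1, s2, s3) < 0) & (pmax(s1, s2, s3) > 0)
  if (!any(crossing)) stop("plane does not intersect the mesh")
  fc <- f[crossing, , drop = FALSE]
  segs <- vector("list", nrow(fc))
  for (i in seq_len(nrow(fc))) {
    idx <- fc[i, ]; sv <- sd[idx]
    pts <- matrix(NA_real_, 0, 3)
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      a <- sv[e[1]]; b <- sv[e[2]]
      if ((a < 0) != (b < 0)) {
        w <- a / (a - b)
        pts <- rbind(pts, (1 - w) * v[idx[e[1]], ] + w * v[idx[e[2]], ])
      }
    }
    segs[[i]] <- pts
  }
  axes <- .plane_axes(n)
  to2d <- function(p) drop(crossprod(axes, p - plane_point))
  ends <- t(vapply(segs, function(s) c(to2d(s[1, ]), to2d(s[2, ])),
                   numeric(4)))
  loops <- .chain_segments(ends)
  areas <- vapply(loops, function(p) abs(polygonArea(p)), numeric(1))
  loops <- loops[order(-areas)]
  new("PlanarSection", plane_point = as.numeric(plane_point),
      plane_normal = n, in_plane_axes = axes, polygons = loops)
}

# Chain 2D segments (n x 4: x1 y1 x2 y2) into closed loops by snapping
# endpoints onto a tolerance grid.
.chain_segments <- function(ends, tol = 1e-9) {
  scale <- max(abs(ends), 1)
  key <- function(x, y) paste(round(x / (tol * scale)), round(y / (tol * scale)))
  k1 <- key(ends[, 1], ends[, 2]); k2 <- key(ends[, 3], ends[, 4])
  n <- nrow(ends)
  used <- logical(n)
  # adjacency: endpoint key -> segment indices
  adj <- split(rep(seq_len(n), 2), c(k1, k2))
  loops <- list()
  for (start in seq_len(n)) {
    if (used[start]) next
    used[start] <- TRUE
    loop <- list(ends[start, 1:2])
    cur_key <- k2[start]; cur_pt <- ends[start, 3:4]
    start_key <- k1[start]
    repeat {
      if (identical(cur_key, start_key)) break
      cand <- adj[[cur_key]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0) { loop <- NULL; break }  # open chain: drop
      nxt <- cand[1]
      used[nxt] <- TRUE
      loop[[length(loop) + 1]] <- cur_pt
      if (identical(k1[nxt], cur_key)) {
        cur_key <- k2[nxt]; cur_pt <- ends[nxt, 3:4]
      } else {
        cur_key <- k1[nxt]; cur_pt <- ends[nxt, 1:2]
      }
    }
    if (!is.null(loop) && length(loop) >= 3)
      loops[[length(loops) + 1]] <- do.call(rbind, loop)
  }
  if (length(loops) == 0) stop("no closed intersection loop found")
  loops
}

#' Planar polygon metrics
#'
#' Perimeter, enclosed (shoelace) area, maximum caliper diameter and minimum
#' rotating-calipers width of a closed, non-self-intersecting 2D loop. The
#' diameter and width are computed on the convex hull: the maximal chord of
#' a closed region equals that of its hull, and hull-based calipers match
#' how such diameters are measured clinically.
#'
#' @param poly k x 2 matrix of loop vertices (closed implicitly; the first
#'   vertex is not repeated).
#' @return \code{polygonPerimeter}/\code{polygonArea}/\code{polygonMinWidth}:
#'   numeric(1); \code{polygonMaxDiameter}: list with \code{diameter_mm},
#'   \code{direction} (unit 2-vector) and \code{endpoints} (2 x 2 matrix).
#' @examples
#' sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
#' polygonPerimeter(sq)            # 4
#' polygonArea(sq)                 # 1
#' polygonMaxDiameter(sq)$diameter_mm  # sqrt(2)
#' polygonMinWidth(sq)             # 1
#' @export
polygonPerimeter <- function(poly) {
  p <- .check_poly(poly)
  d <- p[c(2:nrow(p), 1), ] - p
  sum(sqrt(rowSums(d^2)))
}

#' @rdname polygonPerimeter
#' @export
polygonArea <- function(poly) {
  p <- .check_poly(poly)
  x <- p[, 1]; y <- p[, 2]
  xn <- x[c(2:length(x), 1)]; yn <- y[c(2:length(y), 1)]
  abs(sum(x * yn - xn * y)) / 2
}

.check_poly <- function(poly) {
  p <- as.matrix(poly)
  if (ncol(p) != 2 || nrow(p) < 3) stop("polygon must be a k x 2 matrix, k >= 3")
  if (any(!is.finite(p))) stop("polygon has non-finite vertices")
  p
}

.convex_hull <- function(p) {
  h <- grDevices::chull(p[, 1], p[, 2])
  if (length(h) < 3) stop("degenerate polygon: convex hull has fewer than 3 vertices")
  p[rev(h), , drop = FALSE]  # chull returns clockwise; use CCW
}

#' @rdname polygonPerimeter
#' @export
polygonMaxDiameter <- function(poly) {
  h <- .convex_hull(.check_poly(poly))
  dmat <- as.matrix(stats::dist(h))
  ij <- which(dmat == max(dmat), arr.ind = TRUE)[1, ]
  e <- h[ij, , drop = FALSE]
  dir <- .normalize(c(e[2, ] - e[1, ], 0))[1:2]
  list(diameter_mm = dmat[ij[1], ij[2]], direction = dir, endpoints = e)
}

#' @rdname polygonPerimeter
#' @export
polygonMinWidth <- function(poly) {
  h <- .convex_hull(.check_poly(poly))
  k <- nrow(h)
  w <- Inf
  for (i in seq_len(k)) {
    e <- h[if (i == k) 1 else i + 1, ] - h[i, ]
    len <- sqrt(sum(e^2))
    if (len < 1e-14) next
    nrm <- c(-e[2], e[1]) / len
    d <- drop(sweep(h, 2, h[i, ]) %*% nrm)
    w <- min(w, max(d) - min(d))
  }
  w
}
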