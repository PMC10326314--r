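# Synthetic LAA-like phantoms with analytic ground truth.
#
# A phantom is an elliptical profile swept along a straight or circular-arc
# centerline with linear semi-axis taper and optional twist, capped at both
# ends (watertight). Every quantity measured downstream - section plane,
# diameters, perimeter, area, ovality, the optimal tangential view - has a
# closed-form or quadrature value at the designated landing position, so
# mesh-based measurements can be validated by parameter recovery rather
# than against restricted patient data.

# Centerline frame at normalized arc length s: point, tangent, and the two
# (untwisted) section axes.
.phantom_frame <- function(spec, s) {
  L <- spec@length_mm
  if (spec@centerline == "straight") {
    p <- c(0, 0, s * L); t <- c(0, 0, 1); e1 <- c(1, 0, 0)
  } else {
    Rc <- spec@arc_radius_mm
    th <- s * L / Rc
    p <- Rc * c(1 - cos(th), 0, sin(th))
    t <- c(sin(th), 0, cos(th))
    e1 <- c(cos(th), 0, -sin(th))
  }
  list(point = p, tangent = t, e1 = e1, e2 = c(0, 1, 0))
}

.phantom_profile <- function(spec, s) {
  lin <- function(v) (1 - s) * v[1] + s * v[2]
  list(a = lin(spec@semi_a_mm), b = lin(spec@semi_b_mm),
       psi = .deg2rad(lin(spec@twist_deg)))
}

.ellipse_perimeter <- function(a, b) {
  stats::integrate(function(t) sqrt(a^2 * sin(t)^2 + b^2 * cos(t)^2),
                   0, 2 * pi, rel.tol = 1e-10)$value
}

#' Generate a phantom mesh and its analytic ground truth
#'
#' Deterministic for a given spec. The ground truth at \code{landing_s} is
#' computed from the parametric definition, never from the mesh.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return list of class \code{"Phantom"}: \code{mesh}
#'   (\linkS4class{SurfaceMesh}), \code{truth} (list: \code{plane_point},
#'   \code{plane_normal}, \code{dmax_direction}, \code{d_max_mm},
#'   \code{d_min_mm}, \code{area_mm2}, \code{perimeter_mm}, \code{d_peri_mm},
#'   \code{d_area_mm}, \code{ovality_mm}, \code{endpoint_a}, \code{endpoint_b},
#'   \code{tangential_pose}) and \code{spec}.
#' @examples
#' ph <- generatePhantom(PhantomSpec(semi_a_mm = 15, semi_b_mm = 10))
#' ph$truth$d_area_mm   # 2 * sqrt(150) = 24.49
#' @export
generatePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  if (spec@centerline == "arc" &&
      spec@arc_radius_mm <= max(spec@semi_a_mm))
    stop("self-intersecting sweep: arc radius must exceed the largest semi-axis")
  nc <- as.integer(spec@circumferential_segments)
  nl <- as.integer(spec@longitudinal_segments)
  phi <- 2 * pi * (seq_len(nc) - 1) / nc
  verts <- matrix(NA_real_, (nl + 1) * nc + 2, 3)
  for (i in 0:nl) {
    s <- i / nl
    fr <- .phantom_frame(spec, s)
    pr <- .phantom_profile(spec, s)
    u1 <- cos(pr$psi) * fr$e1 + sin(pr$psi) * fr$e2
    u2 <- -sin(pr$psi) * fr$e1 + cos(pr$psi) * fr$e2
    ring <- outer(pr$a * cos(phi), u1) + outer(pr$b * sin(phi), u2)
    verts[i * nc + seq_len(nc), ] <- sweep(ring, 2, fr$point, "+")
  }
  c0 <- (nl + 1) * nc + 1L; c1 <- c0 + 1L
  verts[c0, ] <- .phantom_frame(spec, 0)$point
  verts[c1, ] <- .phantom_frame(spec, 1)$point
  faces <- matrix(NA_integer_, 2 * nl * nc + 2 * nc, 3)
  row <- 1L
  for (i in 0:(nl - 1)) {
    j <- seq_len(nc); jn <- c(2:nc, 1L)
    a <- i * nc + j; b <- i * nc + jn
    cth <- (i + 1) * nc + j; dth <- (i + 1) * nc + jn
    faces[row:(row + nc - 1), ] <- cbind(a, b, dth)
    row <- row + nc
    faces[row:(row + nc - 1), ] <- cbind(a, dth, cth)
    row <- row + nc
  }
  j <- seq_len(nc); jn <- c(2:nc, 1L)
  faces[row:(row + nc - 1), ] <- cbind(j, c0, jn); row <- row + nc
  top <- nl * nc
  faces[row:(row + nc - 1), ] <- cbind(top + j, top + jn, c1)
  mesh <- SurfaceMesh(verts, faces, check_watertight = FALSE)

  s <- spec@landing_s
  fr <- .phantom_frame(spec, s)
  pr <- .phantom_profile(spec, s)
  u1 <- cos(pr$psi) * fr$e1 + sin(pr$psi) * fr$e2
  perim <- .ellipse_perimeter(pr$a, pr$b)
  truth <- list(
    plane_point = fr$point, plane_normal = fr$tangent, dmax_direction = u1,
    d_max_mm = 2 * pr$a, d_min_mm = 2 * pr$b,
    area_mm2 = pi * pr$a * pr$b, perimeter_mm = perim,
    d_peri_mm = perim / pi, d_area_mm = 2 * sqrt(pr$a * pr$b),
    ovality_mm = 2 * (pr$a - pr$b),
    endpoint_a = fr$point - pr$a * u1, endpoint_b = fr$point + pr$a * u1,
    tangential_pose = optimalAngulation(fr$tangent, u1)$chosen)
  structure(list(mesh = mesh, truth = truth, spec = spec),
            class = "Phantom")
}

#' @export
print.Phantom <- function(x, ...) {
  cat("Phantom with ground truth at s =", x$spec@landing_s, "\n")
  print(x$spec)
  cat(sprintf("  truth: d_max %.2f, d_min %.2f, d_peri %.2f, d_area %.2f mm\n",
              x$truth$d_max_mm, x$truth$d_min_mm, x$truth$d_peri_mm,
              x$truth$d_area_mm))
  invisible(x)
}

#' Rigidly place a phantom for a target working projection
#'
#' Rotates and translates the phantom so that its landing-zone midpoint sits
#' at the isocenter and the ideal tangential beam of the landing section
#' coincides with the viewing direction of \code{target_pose}. Ground truth
#' is transformed alongside the mesh.
#'
#' @param phantom from \code{\link{generatePhantom}}.
#' @param target_pose a \linkS4class{CArmPose}.
#' @return the transformed phantom.
#' @export
placePhantom <- function(phantom, target_pose) {
  tr <- phantom$truth
  v_t <- viewingDirection(target_pose)
  # deterministic in-plane reference for the rotated max-diameter direction
  ref <- if (abs(v_t[1]) < 0.9) c(1, 0, 0) else c(0, 0, 1)
  d_t <- .normalize(ref - sum(ref * v_t) * v_t)
  n_t <- .cross3(d_t, v_t)                       # n x d = v
  v_c <- .normalize(.cross3(tr$plane_normal, tr$dmax_direction))
  A <- cbind(tr$dmax_direction, tr$plane_normal, v_c)
  B <- cbind(d_t, n_t, v_t)
  R <- B %*% t(A)
  trans <- -drop(R %*% tr$plane_point)
  rigid <- RigidTransform(R, trans)
  mv <- function(p) drop(R %*% p) + trans
  rot <- function(p) drop(R %*% p)
  tr2 <- tr
  tr2$plane_point <- mv(tr$plane_point)
  tr2$plane_normal <- rot(tr$plane_normal)
  tr2$dmax_direction <- rot(tr$dmax_direction)
  tr2$endpoint_a <- mv(tr$endpoint_a)
  tr2$endpoint_b <- mv(tr$endpoint_b)
  tr2$tangential_pose <- optimalAngulation(tr2$plane_normal,
                                           tr2$dmax_direction)$chosen
  structure(list(mesh = applyTransform(phantom$mesh, rigid), truth = tr2,
                 spec = phantom$spec, placement = rigid),
            class = "Phantom")
}

# Run code with a temporary, seeded RNG state.
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a fluoroscopic landing-zone annotation
#'
#' Projects the phantom's true maximal-diameter wall endpoints onto the
#' detector under the given pose, pulls each endpoint inward along the
#' annotated segment by \code{inset_mm}, and optionally adds isotropic 2D
#' Gaussian noise. The inset makes the annotation consistent with the
#' faceted mesh silhouette: the mesh is an inscribed approximation of the
#' analytic surface, so a ray through the exact analytic silhouette point
#' can graze past the facets.
#'
#' @param phantom a placed phantom.
#' @param pose annotation \linkS4class{CArmPose}.
#' @param endpoint_noise_mm isotropic Gaussian sd per detector coordinate.
#' @param seed integer seed (used only when noise > 0).
#' @param inset_mm inward shift of each endpoint along the segment (detector
#'   mm).
#' @return list: \code{q_a}, \code{q_b} (detector mm), \code{pose}.
#' @export
simulateAnnotation <- function(phantom, pose, endpoint_noise_mm = 0,
                               seed = 1L, inset_mm = 0.05) {
  tr <- phantom$truth
  qa <- projectPoint(pose, tr$endpoint_a)
  qb <- projectPoint(pose, tr$endpoint_b)
  if (endpoint_noise_mm > 0) {
    noise <- .with_seed(seed, stats::rnorm(4, 0, endpoint_noise_mm))
    qa <- qa + noise[1:2]; qb <- qb + noise[3:4]
  }
  # inset applied after the noise, along the (noisy) annotated segment
  seg <- qb - qa
  len <- sqrt(sum(seg^2))
  if (len <= 2 * inset_mm) stop("annotated segment shorter than twice the inset")
  dir <- seg / len
  list(q_a = qa + inset_mm * dir, q_b = qb - inset_mm * dir, pose = pose)
}

#' Voxelize a watertight mesh into a binary volume
#'
#' Center-of-voxel inside test by even-odd parity of axis-parallel ray
#' crossings, on an axis-aligned grid enclosing the mesh with padding.
#' Default spacing 1.3 mm mirrors the isotropic resolution of the CMR
#' acquisitions the phantoms emulate.
#'
#' @param mesh a watertight \linkS4class{SurfaceMesh}.
#' @param spacing_mm isotropic voxel pitch (mm).
#' @param padding_mm bounding-box padding (mm).
#' @return An \linkS4class{ImageVolume} with 0/1 voxels.
#' @export
voxelize <- function(mesh, spacing_mm = 1.3, padding_mm = 10) {
  stopifnot(is(mesh, "SurfaceMesh"))
  if (nrow(mesh@faces) == 0) stop("empty mesh")
  if (!isWatertight(mesh)) stop("voxelization requires a watertight mesh")
  v <- mesh@vertices
  lo <- apply(v, 2, min) - padding_mm
  hi <- apply(v, 2, max) + padding_mm
  n <- pmax(2L, as.integer(ceiling((hi - lo) / spacing_mm)))
  xs <- lo[1] + (seq_len(n[1]) - 0.5) * spacing_mm
  ys <- lo[2] + (seq_len(n[2]) - 0.5) * spacing_mm
  zs <- lo[3] + (seq_len(n[3]) - 0.5) * spacing_mm
  occ <- array(0, n)
  for (k in seq_len(n[3])) for (j in seq_len(n[2])) {
    tt <- sort(.ray_mesh_t(mesh, c(lo[1] - 1, ys[j], zs[k]), c(1, 0, 0)))
    if (length(tt) == 0) next
    if (length(tt) > 1) tt <- tt[c(TRUE, diff(tt) > 1e-6)]
    cross_x <- lo[1] - 1 + tt
    occ[, j, k] <- findInterval(xs, cross_x) %% 2
  }
  ImageVolume(occ, spacing = rep(spacing_mm, 3),
              origin = c(xs[1], ys[1], zs[1]))
}

#' Simulate a multi-reader, multi-modality measurement panel
#'
#' Per-case true landing-zone diameters are drawn from the phantom family
#' (Gaussian around a clinically typical LAA landing-zone diameter). Each
#' reader reports truth + reader bias + Gaussian noise (the ratings matrix
#' for ICC); the studied modality (series A) additionally carries a
#' systematic bias relative to the reference modality (series B), the
#' default negative value emulating the underestimation of LAA diameters by
#' projection- and echo-based measurement.
#'
#' @param n_cases number of subjects (>= 2).
#' @param n_readers number of raters.
#' @param subject_mean_mm,subject_sd_mm Gaussian diameter distribution of
#'   the phantom family (mm).
#' @param reader_bias_mm sd of the per-reader systematic bias (mm).
#' @param reader_noise_mm sd of per-rating noise (mm).
#' @param modality_bias_mm systematic bias of modality A vs B (mm).
#' @param modality_noise_mm per-measurement noise of either modality (mm).
#' @param seed integer seed.
#' @return list: \code{ratings} (n x k matrix), \code{values_a},
#'   \code{values_b} (paired modality series; \code{blandAltman(values_a,
#'   values_b)} recovers \code{modality_bias_mm}), \code{truth_mm}.
#' @export
simulateReaderPanel <- function(n_cases, n_readers = 3,
                                subject_mean_mm = 22, subject_sd_mm = 3,
                                reader_bias_mm = 0.5, reader_noise_mm = 1,
                                modality_bias_mm = -2, modality_noise_mm = 1,
                                seed = 1L) {
  if (n_cases < 2) stop("need at least 2 cases")
  if (any(c(reader_bias_mm, reader_noise_mm, modality_noise_mm) < 0))
    stop("noise and bias-spread parameters must be >= 0")
  .with_seed(seed, {
    truth <- stats::rnorm(n_cases, subject_mean_mm, subject_sd_mm)
    biases <- stats::rnorm(n_readers, 0, reader_bias_mm)
    ratings <- outer(truth, biases, "+") +
      matrix(stats::rnorm(n_cases * n_readers, 0, reader_noise_mm),
             n_cases, n_readers)
    values_a <- truth + modality_bias_mm +
      stats::rnorm(n_cases, 0, modality_noise_mm)
    values_b <- truth + stats::rnorm(n_cases, 0, modality_noise_mm)
    list(ratings = ratings, values_a = values_a, values_b = values_b,
         truth_mm = truth)
  })
}

#' Icosphere test mesh
#'
#' Geodesic sphere by icosahedron subdivision; a convenient watertight
#' analytic test surface.
#'
#' @param subdivisions subdivision depth (0 = icosahedron).
#' @param radius_mm sphere radius.
#' @param center numeric(3).
#' @return A \linkS4class{SurfaceMesh}.
#' @export
icosphereMesh <- function(subdivisions = 3, radius_mm = 1,
                          center = c(0, 0, 0)) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    mid_cache <- new.env()
    nf <- matrix(NA_integer_, 4 * nrow(f), 3)
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      if (!is.null(mid_cache[[key]])) return(mid_cache[[key]])
      m <- .normalize(v[i, ] + v[j, ])
      v <<- rbind(v, m)
      mid_cache[[key]] <- nrow(v)
      nrow(v)
    }
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf[(4 * i - 3):(4 * i), ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(cc, ca, bc), c(ab, bc, ca))
    }
    f <- nf
  }
  SurfaceMesh(sweep(v * radius_mm, 2, as.numeric(center), "+"), f,
              check_watertight = FALSE)
}
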