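test_that("mesh file round trips preserve geometry across dialects", {
  m <- icosphereMesh(2, 7.5, center = c(1, -2, 3))
  paths <- list(stl_bin = withr::local_tempfile(fileext = ".stl"),
                stl_asc = withr::local_tempfile(fileext = ".stl"),
                ply = withr::local_tempfile(fileext = ".ply"))
  writeMesh(m, paths$stl_bin, "stl_binary")
  writeMesh(m, paths$stl_asc, "stl_ascii")
  writeMesh(m, paths$ply, "ply")
  for (p in paths) {
    m2 <- readMesh(p)
    expect_equal(nrow(m2@faces), nrow(m@faces))
    # vertex multiset identical up to float precision (binary STL: float32)
    expect_lt(max(abs(sort(m2@vertices) - sort(m@vertices))), 1e-5)
    expect_true(isWatertight(m2))
  }
  # the two STL dialects agree with each other
  expect_lt(max(abs(sort(readMesh(paths$stl_bin)@vertices) -
                      sort(readMesh(paths$stl_asc)@vertices))), 1e-5)
  empty <- withr::local_tempfile()
  file.create(empty)
  expect_error(readMesh(empty), "empty")
})

test_that("rigid transforms are isometries and compose as expected", {
  m <- icosphereMesh(1, 5)
  t0 <- RigidTransform()
  expect_equal(applyTransform(m, t0)@vertices, m@vertices)
  tr <- RigidTransform(translation = c(5, -3, 2))
  expect_equal(colMeans(applyTransform(m, tr)@vertices) - colMeans(m@vertices),
               c(5, -3, 2))
  set.seed(21)
  R <- random_rotation()
  rt <- RigidTransform(R, rnorm(3, sd = 10))
  m2 <- applyTransform(m, rt)
  i <- sample(nrow(m@vertices), 30); j <- sample(nrow(m@vertices), 30)
  d1 <- sqrt(rowSums((m@vertices[i, ] - m@vertices[j, ])^2))
  d2 <- sqrt(rowSums((m2@vertices[i, ] - m2@vertices[j, ])^2))
  expect_equal(d1, d2, tolerance = 1e-9)
  expect_error(RigidTransform(diag(c(-1, 1, 1))), "det")
})

test_that("point registration recovers exact rigid motions and rejects reflections", {
  set.seed(5)
  S <- matrix(rnorm(36, sd = 20), ncol = 3)
  expect_equal(registerPoints(S, S)$rms_mm, 0, tolerance = 1e-9)
  R <- random_rotation(); tv <- c(4, -7, 2)
  Tg <- S %*% t(R) + matrix(tv, nrow(S), 3, byrow = TRUE)
  reg <- registerPoints(S, Tg)
  expect_lt(reg$rms_mm, 1e-9)
  expect_lt(max(abs(reg$transform@rotation - R)), 1e-9)
  expect_lt(max(abs(reg$transform@translation - tv)), 1e-9)
  # mirrored target: rotation stays proper, residual strictly positive
  Tm <- S %*% diag(c(-1, 1, 1))
  regm <- registerPoints(S, Tm)
  expect_equal(det(regm$transform@rotation), 1, tolerance = 1e-9)
  expect_gt(regm$rms_mm, 0.1)
  expect_error(registerPoints(S[1:2, ], Tg[1:2, ]), "3 point")
  line <- cbind(1:5, 0, 0)
  expect_error(registerPoints(line, line + 1), "collinear")
})

test_that("ray-mesh intersection matches the analytic sphere and parity", {
  sph <- icosphereMesh(4, 1)
  h <- intersectRayMesh(sph, Ray(c(-5, 0, 0), c(1, 0, 0)))
  expect_equal(nrow(h), 2)
  expect_equal(h[1, ], c(-1, 0, 0), tolerance = 5e-3)  # chordal tolerance
  expect_equal(h[2, ], c(1, 0, 0), tolerance = 5e-3)
  expect_equal(nrow(intersectRayMesh(sph, Ray(c(-5, 3, 0), c(1, 0, 0)))), 0)
  # even hit parity for exterior rays through a watertight tube
  tube <- generatePhantom(PhantomSpec(circumferential_segments = 32,
                                      longitudinal_segments = 16))$mesh
  set.seed(9)
  for (i in 1:40) {
    orig <- c(200, 0, 30) + rnorm(3, sd = 5)
    target <- c(0, rnorm(1, sd = 6), runif(1, 5, 55))
    h <- intersectRayMesh(tube, Ray(orig, target - orig))
    expect_true(nrow(h) %% 2 == 0)
  }
})

test_that("hit ordering and brute-force triangle agreement on a tube", {
  tube <- generatePhantom(PhantomSpec(circumferential_segments = 24,
                                      longitudinal_segments = 16))$mesh
  ray <- Ray(c(-50, 3, 30), c(1, 0.05, 0.01))
  h <- intersectRayMesh(tube, ray)
  expect_gte(nrow(h), 2)
  t_h <- drop((h - matrix(ray@origin, nrow(h), 3, byrow = TRUE)) %*%
                ray@direction)
  expect_true(all(diff(t_h) > 0))  # sorted by distance
  # brute force: per-triangle Moller-Trumbore in plain loops
  v <- meshVertices(tube); f <- meshFaces(tube)
  ts <- c()
  for (i in seq_len(nrow(f))) {
    p0 <- v[f[i, 1], ]; e1 <- v[f[i, 2], ] - p0; e2 <- v[f[i, 3], ] - p0
    pv <- c(ray@direction[2] * e2[3] - ray@direction[3] * e2[2],
            ray@direction[3] * e2[1] - ray@direction[1] * e2[3],
            ray@direction[1] * e2[2] - ray@direction[2] * e2[1])
    det <- sum(e1 * pv)
    if (abs(det) < 1e-12) next
    tv <- ray@origin - p0
    uu <- sum(tv * pv) / det
    qv <- c(tv[2] * e1[3] - tv[3] * e1[2], tv[3] * e1[1] - tv[1] * e1[3],
            tv[1] * e1[2] - tv[2] * e1[1])
    vv <- sum(ray@direction * qv) / det
    tt <- sum(e2 * qv) / det
    if (uu >= 0 && vv >= 0 && uu + vv <= 1 && tt > 0) ts <- c(ts, tt)
  }
  ts <- sort(ts); ts <- ts[c(TRUE, diff(ts) > 1e-6)]
  expect_equal(t_h, ts, tolerance = 1e-9)
})

test_that("plane sections reproduce analytic perimeters and areas", {
  # axis-aligned unit cube cut at z = 0.5 -> unit square loop
  cv <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  cf <- rbind(c(1,3,4), c(1,4,2), c(5,6,8), c(5,8,7), c(1,2,6), c(1,6,5),
              c(3,7,8), c(3,8,4), c(1,5,7), c(1,7,3), c(2,4,8), c(2,8,6))
  cube <- SurfaceMesh(cv, cf)
  sec <- planeSection(cube, c(0.5, 0.5, 0.5), c(0, 0, 1))
  expect_equal(length(sec@polygons), 1)
  expect_equal(polygonPerimeter(sec@polygons[[1]]), 4, tolerance = 1e-9)
  expect_equal(polygonArea(sec@polygons[[1]]), 1, tolerance = 1e-9)
  # sphere radius 10 through the center -> great circle (1% mesh tolerance)
  sph <- icosphereMesh(4, 10)
  secs <- planeSection(sph, c(0, 0, 0), c(0.3, -0.5, 0.81))
  expect_equal(polygonPerimeter(secs@polygons[[1]]), 2 * pi * 10,
               tolerance = 0.01)
  expect_equal(polygonArea(secs@polygons[[1]]), pi * 100, tolerance = 0.01)
  expect_error(planeSection(sph, c(0, 0, 20), c(0, 0, 1)), "intersect")
})

test_that("polygon metrics match analytic shapes", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(polygonPerimeter(sq), 4)
  expect_equal(polygonArea(sq), 1)
  expect_equal(polygonMaxDiameter(sq)$diameter_mm, sqrt(2))
  expect_equal(polygonMinWidth(sq), 1)
  # near-circle: 4096-gon of radius 10
  circ <- ellipse_poly(10, 10)
  expect_equal(polygonPerimeter(circ), 2 * pi * 10, tolerance = 1e-3)
  expect_equal(polygonArea(circ), pi * 100, tolerance = 1e-3)
  expect_equal(polygonMaxDiameter(circ)$diameter_mm, 20, tolerance = 1e-3)
  expect_equal(polygonMinWidth(circ), 20, tolerance = 1e-3)
  # ellipse 15 x 10: area, calipers exact; perimeter vs chord-sum oracle
  ell <- ellipse_poly(15, 10)
  expect_equal(polygonArea(ell), pi * 150, tolerance = 1e-4)
  expect_equal(polygonMaxDiameter(ell)$diameter_mm, 30, tolerance = 1e-4)
  expect_equal(polygonMinWidth(ell), 20, tolerance = 1e-4)
  expect_equal(polygonPerimeter(ell), ellipse_perimeter_oracle(15, 10),
               tolerance = 1e-4)
  expect_error(polygonArea(rbind(c(0, 0), c(1, 1))), "k >= 3")
})

test_that("rotating-calipers width equals brute force and metrics are rigid-motion invariant", {
  set.seed(17)
  for (i in 1:100) {
    poly <- random_convex_poly()
    expect_equal(polygonMinWidth(poly), brute_min_width(poly),
                 tolerance = 1e-6)
    expect_gte(polygonMaxDiameter(poly)$diameter_mm,
               polygonMinWidth(poly) - 1e-12)
    # rigid motion in the plane
    th <- runif(1, 0, 2 * pi); off <- rnorm(2, sd = 40)
    R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
    p2 <- sweep(poly %*% t(R), 2, off, "+")
    expect_equal(polygonMaxDiameter(p2)$diameter_mm,
                 polygonMaxDiameter(poly)$diameter_mm, tolerance = 1e-9)
    expect_equal(polygonMinWidth(p2), polygonMinWidth(poly),
                 tolerance = 1e-6)
  }
})
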