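make_placed_phantom <- function(spec = PhantomSpec(semi_a_mm = 15,
                                                   semi_b_mm = 10),
                                pose = CArmPose(-25, -25)) {
  placePhantom(generatePhantom(spec), pose)
}

test_that("landing plane construction follows the segment-beam cross product", {
  pl <- landingPlane(c(0, 0, 0), c(20, 0, 0), c(0, 0, 1))
  expect_equal(pl$plane_point, c(10, 0, 0))
  expect_equal(abs(pl$plane_normal), c(0, 1, 0))
  expect_error(landingPlane(c(1, 1, 1), c(1, 1, 1), c(0, 0, 1)), "coincide")
  expect_error(landingPlane(c(0, 0, 0), c(0, 0, 5), c(0, 0, 1)), "parallel")
})

test_that("noiseless annotations localize to the true wall points", {
  ph <- make_placed_phantom()
  pose <- ph$truth$tangential_pose
  ann <- simulateAnnotation(ph, pose)
  zone <- localizeLandingZone(ph$mesh, pose, ann$q_a, ann$q_b)
  err_a <- sqrt(sum((zone@endpoint_a - ph$truth$endpoint_a)^2))
  err_b <- sqrt(sum((zone@endpoint_b - ph$truth$endpoint_b)^2))
  expect_lt(err_a, 1.3)  # within one voxel of the emulated acquisition
  expect_lt(err_b, 1.3)
  # plane normal within 5 degrees of the anatomical section normal
  cosang <- abs(sum(zone@plane_normal * ph$truth$plane_normal))
  expect_lt(acos(min(1, cosang)) * 180 / pi, 5)
})

test_that("rays that miss the silhouette are reported per endpoint", {
  ph <- make_placed_phantom()
  pose <- ph$truth$tangential_pose
  ann <- simulateAnnotation(ph, pose)
  expect_error(localizeLandingZone(ph$mesh, pose, ann$q_a + c(500, 0),
                                   ann$q_b), "ray A misses")
  expect_error(localizeLandingZone(ph$mesh, pose, ann$q_a,
                                   ann$q_b + c(500, 0)), "ray B misses")
})

test_that("depth-disparity selection picks the opposite-wall pair at equal depth", {
  # symmetric circular tube viewed tangentially: chosen hits at equal depth
  ph <- make_placed_phantom(PhantomSpec(semi_a_mm = 10, semi_b_mm = 10))
  pose <- ph$truth$tangential_pose
  ann <- simulateAnnotation(ph, pose)
  zone <- localizeLandingZone(ph$mesh, pose, ann$q_a, ann$q_b)
  v <- viewingDirection(pose)
  expect_lt(abs(sum(zone@endpoint_a * v) - sum(zone@endpoint_b * v)), 0.05)
})

test_that("measureCrossSection returns the loop nearest the midpoint", {
  ph <- make_placed_phantom()
  pose <- ph$truth$tangential_pose
  ann <- simulateAnnotation(ph, pose)
  zone <- localizeLandingZone(ph$mesh, pose, ann$q_a, ann$q_b)
  sec <- measureCrossSection(ph$mesh, zone)
  r <- sizingFromSection(sec, source = "XR-located")
  expect_equal(r@d_max_mm, ph$truth$d_max_mm, tolerance = 0.05)
  expect_equal(r@d_min_mm, ph$truth$d_min_mm, tolerance = 0.05)
  # two-lobed scene: a second, larger tube far from the midpoint must not win
  far <- applyTransform(ph$mesh, RigidTransform(translation = c(90, 0, 0)))
  vv <- rbind(meshVertices(ph$mesh), meshVertices(far))
  ff <- rbind(meshFaces(ph$mesh), meshFaces(far) + nrow(meshVertices(ph$mesh)))
  two <- SurfaceMesh(vv, ff)
  sec2 <- measureCrossSection(two, zone)
  expect_gte(length(sec2@polygons), 2)
  cen <- colMeans(sec2@polygons[[1]])
  mid2 <- drop(crossprod(sec2@in_plane_axes, zone@plane_point - sec2@plane_point))
  expect_lt(sqrt(sum((cen - mid2)^2)), 20)
})

test_that("projected diameter is bounded by the caliper diameter with edge-on equality", {
  ph <- make_placed_phantom()
  pose <- ph$truth$tangential_pose
  ann <- simulateAnnotation(ph, pose)
  zone <- localizeLandingZone(ph$mesh, pose, ann$q_a, ann$q_b)
  sec <- measureCrossSection(ph$mesh, zone)
  dmax <- polygonMaxDiameter(sec@polygons[[1]])$diameter_mm
  # tangential pose: view orthogonal to the max diameter -> no foreshortening
  expect_equal(projectedDiameter(sec, pose), dmax, tolerance = 1e-6)
  # any other pose can only shorten it
  set.seed(31)
  for (i in 1:10) {
    pr <- CArmPose(runif(1, -179, 180), runif(1, -89, 89))
    expect_lte(projectedDiameter(sec, pr), dmax + 1e-9)
  }
  # viewing along the major axis leaves the minor axis: ellipse 30 x 20
  dir3 <- ph$truth$dmax_direction
  pose_along <- poseFromDirection(dir3)
  expect_equal(projectedDiameter(sec, pose_along), ph$truth$d_min_mm,
               tolerance = 0.05)
})

test_that("MPR reproduces affine fields exactly and handles outside planes", {
  grid <- array(0, c(12, 14, 16))
  for (k in 1:16) grid[, , k] <- k - 1   # f(x, y, z) = z on the lattice
  vol <- ImageVolume(grid, spacing = c(1, 1, 1), origin = c(0, 0, 0))
  mpr <- mprResample(vol, c(5.5, 6.5, 5), diag(3)[, 1:2], fov_mm = 8,
                     spacing_mm = 1)
  expect_true(all(abs(mpr@data - 5) < 1e-12))
  # oblique plane through an affine field f = 2x - y + 3z + 4
  aff <- array(0, c(20, 20, 20))
  ix <- slice.index(aff, 1) - 1; iy <- slice.index(aff, 2) - 1
  iz <- slice.index(aff, 3) - 1
  aff <- 2 * ix - iy + 3 * iz + 4
  vol2 <- ImageVolume(aff, spacing = c(1, 1, 1), origin = c(0, 0, 0))
  n <- c(1, 1, 1) / sqrt(3)
  a1 <- c(1, -1, 0) / sqrt(2); a2 <- c(1, 1, -2) / sqrt(6)
  ctr <- c(9.5, 9.5, 9.5)
  mpr2 <- mprResample(vol2, ctr, cbind(a1, a2), fov_mm = 6, spacing_mm = 0.7)
  # expected: affine field evaluated at each pixel's 3D position
  d <- dim(mpr2@data)
  for (i in c(1, d[1])) for (j in c(1, d[2])) {
    p <- ctr + (i - 1 - (d[1] - 1) / 2) * 0.7 * a1 +
      (j - 1 - (d[2] - 1) / 2) * 0.7 * a2
    expect_equal(mpr2@data[i, j], 2 * p[1] - p[2] + 3 * p[3] + 4,
                 tolerance = 1e-9)
  }
  # plane fully outside -> all fill
  mpr3 <- mprResample(vol, c(100, 100, 100), diag(3)[, 1:2], fov_mm = 5,
                      spacing_mm = 1, fill = -7)
  expect_true(all(mpr3@data == -7))
})

test_that("MPR of a voxelized sphere shows a disc of the right diameter", {
  vol <- voxelize(icosphereMesh(3, 10), spacing_mm = 1.3)
  ctr <- vol@origin + vol@spacing * (dim(vol@data) - 1) / 2
  # sphere is centered at the origin; reformat through its center
  mpr <- mprResample(vol, c(0, 0, 0), diag(3)[, 1:2], fov_mm = 40,
                     spacing_mm = 0.5)
  on_rows <- which(mpr@data >= 0.5, arr.ind = TRUE)
  ext <- (apply(on_rows, 2, max) - apply(on_rows, 2, min)) * 0.5
  expect_lt(max(abs(ext - 20)), 2 * 1.3)
})

test_that("MPR export writes PNG and NIfTI", {
  vol <- ImageVolume(array(runif(8 * 8 * 8), c(8, 8, 8)))
  mpr <- mprResample(vol, c(3.5, 3.5, 3.5), diag(3)[, 1:2], fov_mm = 6,
                     spacing_mm = 1)
  png_f <- withr::local_tempfile(fileext = ".png")
  writeMprImage(mpr, png_f)
  expect_gt(file.size(png_f), 0)
  nii_f <- withr::local_tempfile(fileext = ".nii.gz")
  writeMprImage(mpr, nii_f)
  back <- readImageVolume(nii_f)
  expect_equal(back@data[, , 1], mpr@data, tolerance = 1e-6)
})

test_that("NIfTI volume round trip preserves data and world geometry", {
  arr <- array(rnorm(6 * 7 * 8), c(6, 7, 8))
  vol <- ImageVolume(arr, spacing = c(1.3, 1.3, 1.3), origin = c(-10, 5, 2))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  writeImageVolume(vol, f)
  got <- readImageVolume(f)
  expect_equal(got@data, arr, tolerance = 1e-6)
  expect_equal(got@spacing, vol@spacing, tolerance = 1e-6)
  expect_equal(got@origin, vol@origin, tolerance = 1e-5)
  expect_equal(got@direction, diag(3), tolerance = 1e-6)
})
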