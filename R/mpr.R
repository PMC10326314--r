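# Multiplanar reconstruction: trilinear resampling of an image volume on an
# arbitrary plane, plus NIfTI import/export of volumes.

#' Resample a volume on an arbitrary plane (MPR)
#'
#' Trilinear interpolation of the volume at every pixel's 3D position; the
#' reformat is centered on \code{plane_point}. Trilinear interpolation
#' reproduces any affine intensity field exactly at points strictly inside
#' the volume; pixels sampling outside the volume get \code{fill}.
#'
#' @param volume an \linkS4class{ImageVolume}.
#' @param plane_point numeric(3), center of the reformat (mm).
#' @param plane_axes 3 x 2 orthonormal in-plane axes.
#' @param fov_mm field of view (mm), recycled to length 2.
#' @param spacing_mm output pixel pitch (mm), recycled to length 2.
#' @param fill value for pixels outside the volume.
#' @return An \linkS4class{MprImage}.
#' @export
mprResample <- function(volume, plane_point, plane_axes, fov_mm = 60,
                        spacing_mm = 0.5, fill = 0) {
  stopifnot(is(volume, "ImageVolume"))
  A <- as.matrix(plane_axes)
  if (!all(dim(A) == c(3, 2)) || max(abs(crossprod(A) - diag(2))) > 1e-9)
    stop("plane_axes must be 3 x 2 orthonormal")
  fov <- rep(fov_mm, length.out = 2)
  sp <- rep(spacing_mm, length.out = 2)
  if (any(sp <= 0)) stop("spacing must be positive")
  nx <- max(2L, floor(fov[1] / sp[1]) + 1L)
  ny <- max(2L, floor(fov[2] / sp[2]) + 1L)
  cx <- (seq_len(nx) - 1 - (nx - 1) / 2) * sp[1]
  cy <- (seq_len(ny) - 1 - (ny - 1) / 2) * sp[2]
  g <- as.matrix(expand.grid(u = cx, v = cy))
  pts <- sweep(g %*% t(A), 2, as.numeric(plane_point), "+")
  vals <- .trilinear(volume, pts, fill)
  new("MprImage", data = matrix(vals, nx, ny), spacing = sp,
      plane_point = as.numeric(plane_point), plane_axes = A)
}

# Trilinear interpolation at world points (n x 3), center-of-voxel
# convention, 0-based continuous indices.
.trilinear <- function(volume, pts, fill = 0) {
  D <- volume@direction; sp <- volume@spacing
  local <- sweep(pts, 2, volume@origin) %*% D   # (x - o) . axis_k
  idx <- sweep(local, 2, sp, "/")
  dm <- dim(volume@data)
  i0 <- floor(idx)
  fr <- idx - i0
  inside <- idx[, 1] >= 0 & idx[, 1] <= dm[1] - 1 &
            idx[, 2] >= 0 & idx[, 2] <= dm[2] - 1 &
            idx[, 3] >= 0 & idx[, 3] <= dm[3] - 1
  out <- rep(as.numeric(fill), nrow(pts))
  if (!any(inside)) return(out)
  i0 <- i0[inside, , drop = FALSE]
  fr <- fr[inside, , drop = FALSE]
  # clamp the upper neighbor for points exactly on the last slice
  i1 <- pmin(i0 + 1, matrix(dm - 1, nrow(i0), 3, byrow = TRUE))
  at <- function(ix, iy, iz) volume@data[cbind(ix + 1, iy + 1, iz + 1)]
  fx <- fr[, 1]; fy <- fr[, 2]; fz <- fr[, 3]
  val <-
    at(i0[, 1], i0[, 2], i0[, 3]) * (1 - fx) * (1 - fy) * (1 - fz) +
    at(i1[, 1], i0[, 2], i0[, 3]) * fx       * (1 - fy) * (1 - fz) +
    at(i0[, 1], i1[, 2], i0[, 3]) * (1 - fx) * fy       * (1 - fz) +
    at(i1[, 1], i1[, 2], i0[, 3]) * fx       * fy       * (1 - fz) +
    at(i0[, 1], i0[, 2], i1[, 3]) * (1 - fx) * (1 - fy) * fz +
    at(i1[, 1], i0[, 2], i1[, 3]) * fx       * (1 - fy) * fz +
    at(i0[, 1], i1[, 2], i1[, 3]) * (1 - fx) * fy       * fz +
    at(i1[, 1], i1[, 2], i1[, 3]) * fx       * fy       * fz
  out[inside] <- val
  out
}

#' Read / write an image volume as NIfTI
#'
#' Volumes are held internally in the DICOM LPS frame used by the XR
#' geometry; NIfTI xforms are RAS, so the first two world axes are negated
#' on both read and write.
#'
#' @param path a NIfTI file (.nii or .nii.gz).
#' @return \code{readImageVolume}: an \linkS4class{ImageVolume}.
#' @export
readImageVolume <- function(path) {
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  M <- unclass(xf)[1:3, 1:3]
  o <- unclass(xf)[1:3, 4]
  M[1:2, ] <- -M[1:2, ]; o[1:2] <- -o[1:2]   # RAS -> LPS
  sp <- sqrt(colSums(M^2))
  dm <- c(dim(img), 1, 1)[1:3]   # single-slice images come back 2D
  ImageVolume(array(as.numeric(img), dim = dm),
              spacing = sp, origin = o, direction = sweep(M, 2, sp, "/"))
}

#' @rdname readImageVolume
#' @param volume an \linkS4class{ImageVolume}.
#' @export
writeImageVolume <- function(volume, path) {
  M <- sweep(volume@direction, 2, volume@spacing, "*")
  o <- volume@origin
  M[1:2, ] <- -M[1:2, ]; o[1:2] <- -o[1:2]   # LPS -> RAS
  xf <- rbind(cbind(M, o), c(0, 0, 0, 1))
  img <- RNifti::asNifti(volume@data)
  img <- RNifti::`sform<-`(img, structure(xf, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Export an MPR image as PNG (windowed) or NIfTI
#'
#' @param mpr an \linkS4class{MprImage}.
#' @param path output path (.png or .nii/.nii.gz).
#' @param window intensity range mapped to black..white for PNG; default the
#'   data range.
#' @return \code{path}, invisibly.
#' @export
writeMprImage <- function(mpr, path, window = NULL) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (is.null(window)) window <- range(mpr@data)
    if (diff(window) == 0) window <- window + c(0, 1)
    z <- pmin(pmax((mpr@data - window[1]) / diff(window), 0), 1)
    grDevices::png(path, width = nrow(z), height = ncol(z))
    op <- graphics::par(mar = c(0, 0, 0, 0))
    graphics::image(z, col = grDevices::gray.colors(256, 0, 1),
                    axes = FALSE, useRaster = TRUE)
    graphics::par(op)
    grDevices::dev.off()
  } else {
    arr <- array(mpr@data, dim = c(dim(mpr@data), 1))
    d <- dim(mpr@data)
    orig <- mpr@plane_point -
      (d[1] - 1) / 2 * mpr@spacing[1] * mpr@plane_axes[, 1] -
      (d[2] - 1) / 2 * mpr@spacing[2] * mpr@plane_axes[, 2]
    vol <- ImageVolume(arr, spacing = c(mpr@spacing, 1),
                       origin = orig,
                       direction = cbind(mpr@plane_axes,
                                         .cross3(mpr@plane_axes[, 1],
                                                 mpr@plane_axes[, 2])))
    writeImageVolume(vol, path)
  }
  invisible(path)
}
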