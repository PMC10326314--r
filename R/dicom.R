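# Minimal DICOM attribute I/O for x-ray geometry.
#
# Fluoroscopy systems store the projection geometry of every acquired frame
# in the image header: positioner primary/secondary angles, the
# source-to-patient and source-to-detector distances and the detector pixel
# pitch. Only those five attributes are needed here, so this file implements
# a small explicit-VR little-endian element walker (plus an implicit-VR
# fallback) rather than a general DICOM stack. Sequences and pixel data are
# skipped, not interpreted.

.dicom_tags <- list(
  PositionerPrimaryAngle   = c(0x0018L, 0x1510L),
  PositionerSecondaryAngle = c(0x0018L, 0x1511L),
  DistanceSourceToPatient  = c(0x0018L, 0x1111L),
  DistanceSourceToDetector = c(0x0018L, 0x1110L),
  ImagerPixelSpacing       = c(0x0018L, 0x1164L)
)

.long_vrs <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

.read_dicom_elements <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) == 0) stop("empty file: ", path)
  pos <- 1L
  if (length(raw) >= 132 && rawToChar(raw[129:132]) == "DICM") pos <- 133L
  out <- list()
  u16 <- function(i) readBin(raw[i:(i + 1)], "integer", size = 2,
                             endian = "little", signed = FALSE)
  u32 <- function(i) readBin(raw[i:(i + 3)], "integer", size = 4,
                             endian = "little")
  while (pos + 7L <= length(raw)) {
    group <- u16(pos); elem <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    explicit <- grepl("^[A-Z]{2}$", vr)
    if (explicit && vr %in% .long_vrs) {
      len <- u32(pos + 8L); val_at <- pos + 12L
    } else if (explicit) {
      len <- u16(pos + 6L); val_at <- pos + 8L
    } else {
      len <- u32(pos + 4L); val_at <- pos + 8L; vr <- NA_character_
    }
    if (len < 0 || val_at + len - 1L > length(raw) + 1L) break
    key <- sprintf("%04x,%04x", group, elem)
    out[[key]] <- if (len > 0) raw[val_at:(val_at + len - 1L)] else raw(0)
    pos <- val_at + len
  }
  out
}

#' Read the C-arm geometry from a DICOM x-ray image
#'
#' Extracts PositionerPrimaryAngle, PositionerSecondaryAngle,
#' DistanceSourceToPatient, DistanceSourceToDetector and ImagerPixelSpacing
#' and returns them as a \linkS4class{CArmPose}. Signs follow the DICOM
#' positioner definition (primary positive = LAO, secondary positive = CRAN).
#'
#' @param path path to a DICOM file (explicit or implicit VR little endian).
#' @return A \linkS4class{CArmPose}.
#' @export
readXRGeometry <- function(path) {
  if (!file.exists(path)) stop("file not readable: ", path)
  els <- .read_dicom_elements(path)
  get_ds <- function(name) {
    tag <- .dicom_tags[[name]]
    key <- sprintf("%04x,%04x", tag[1], tag[2])
    v <- els[[key]]
    if (is.null(v) || length(v) == 0) stop(name, " absent")
    as.numeric(strsplit(trimws(rawToChar(v)), "\\\\")[[1]])
  }
  CArmPose(alpha_deg = get_ds("PositionerPrimaryAngle"),
           beta_deg = get_ds("PositionerSecondaryAngle"),
           sod_mm = get_ds("DistanceSourceToPatient"),
           sid_mm = get_ds("DistanceSourceToDetector"),
           pixel_spacing_mm = get_ds("ImagerPixelSpacing"))
}

.dicom_element <- function(group, elem, vr, value_chr) {
  val <- charToRaw(value_chr)
  if (length(val) %% 2 == 1)
    val <- c(val, if (vr == "UI") as.raw(0) else charToRaw(" "))
  c(writeBin(c(group, elem), raw(), size = 2, endian = "little"),
    charToRaw(vr),
    writeBin(length(val), raw(), size = 2, endian = "little"),
    val)
}

#' Write a minimal DICOM file carrying a C-arm geometry
#'
#' Emits an explicit-VR little-endian file with a standard preamble and the
#' five geometry attributes read back by \code{\link{readXRGeometry}}.
#' Intended for round-trip testing and for exporting poses to DICOM-aware
#' tools; it is not a complete image object.
#'
#' @param pose a \linkS4class{CArmPose}.
#' @param path output path.
#' @param omit character vector of attribute names to leave out (testing).
#' @return \code{path}, invisibly.
#' @export
writeXRGeometry <- function(pose, path, omit = character()) {
  stopifnot(is(pose, "CArmPose"))
  fmt <- function(x) sub("\\.?0+$", "", sprintf("%.6f", x))
  vals <- list(
    PositionerPrimaryAngle   = fmt(pose@alpha_deg),
    PositionerSecondaryAngle = fmt(pose@beta_deg),
    DistanceSourceToPatient  = fmt(pose@sod_mm),
    DistanceSourceToDetector = fmt(pose@sid_mm),
    ImagerPixelSpacing = paste(fmt(pose@pixel_spacing_mm[1]),
                               fmt(pose@pixel_spacing_mm[2]), sep = "\\")
  )
  meta <- .dicom_element(0x0002L, 0x0010L, "UI", "1.2.840.10008.1.2.1")
  meta_len <- c(writeBin(c(0x0002L, 0x0000L), raw(), size = 2, endian = "little"),
                charToRaw("UL"),
                writeBin(4L, raw(), size = 2, endian = "little"),
                writeBin(length(meta), raw(), size = 4, endian = "little"))
  # dataset elements must be in ascending tag order
  order_names <- names(.dicom_tags)[order(vapply(.dicom_tags, function(t)
    t[1] * 65536 + t[2], numeric(1)))]
  body <- raw(0)
  for (nm in order_names) {
    if (nm %in% omit) next
    tag <- .dicom_tags[[nm]]
    body <- c(body, .dicom_element(tag[1], tag[2], "DS", vals[[nm]]))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta_len, meta, body), con)
  invisible(path)
}

#' Serialize a pose to JSON / read it back
#'
#' @param pose a \linkS4class{CArmPose}.
#' @param path JSON file path.
#' @return \code{writePoseJson}: \code{path} invisibly;
#'   \code{readPoseJson}: a \linkS4class{CArmPose}.
#' @export
writePoseJson <- function(pose, path) {
  jsonlite::write_json(list(alpha_deg = pose@alpha_deg,
                            beta_deg = pose@beta_deg, sod_mm = pose@sod_mm,
                            sid_mm = pose@sid_mm,
                            pixel_spacing_mm = pose@pixel_spacing_mm),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writePoseJson
#' @export
readPoseJson <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  CArmPose(x$alpha_deg, x$beta_deg, x$sod_mm, x$sid_mm, x$pixel_spacing_mm)
}
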