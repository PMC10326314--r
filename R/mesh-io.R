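# STL and PLY surface I/O. Vertices are welded on read (STL stores one
# triangle soup; identical corner coordinates are merged exactly).

.weld_vertices <- function(tri_coords) {
  # tri_coords: (3*m) x 3 matrix, consecutive triples are triangles
  key <- paste(tri_coords[, 1], tri_coords[, 2], tri_coords[, 3], sep = "|")
  idx <- match(key, unique(key))
  verts <- tri_coords[!duplicated(key), , drop = FALSE]
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  list(vertices = verts, faces = faces)
}

.read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80)
  n_tri <- readBin(con, "integer", size = 4, endian = "little")
  if (!length(n_tri) || n_tri <= 0) stop("unreadable or empty STL: ", path)
  rec <- readBin(con, "raw", n = n_tri * 50)
  if (length(rec) < n_tri * 50) stop("truncated binary STL: ", path)
  m <- matrix(rec, nrow = 50)
  float_rows <- 13:48  # 9 vertex floats after the 3 normal floats
  vals <- readBin(as.raw(m[float_rows, ]), "double", size = 4,
                  n = 9L * n_tri, endian = "little")
  coords <- matrix(vals, ncol = 3, byrow = TRUE)
  .weld_vertices(coords)
}

.read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0 || length(vl) %% 3 != 0)
    stop("unreadable or empty STL: ", path)
  nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x)
    as.numeric(x[2:4])))
  .weld_vertices(nums)
}

.read_ply_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3 || trimws(lines[1]) != "ply")
    stop("not a PLY file: ", path)
  hdr_end <- match("end_header", trimws(lines))
  if (is.na(hdr_end)) stop("malformed PLY header: ", path)
  hdr <- lines[seq_len(hdr_end)]
  nv <- as.integer(sub(".*element vertex\\s+", "",
                       grep("element vertex", hdr, value = TRUE)[1]))
  nf <- as.integer(sub(".*element face\\s+", "",
                       grep("element face", hdr, value = TRUE)[1]))
  if (is.na(nv) || is.na(nf) || nv == 0) stop("unreadable or empty PLY: ", path)
  body <- lines[(hdr_end + 1):length(lines)]
  verts <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                                 function(x) as.numeric(x[1:3])))
  faces <- do.call(rbind, lapply(strsplit(trimws(body[nv + seq_len(nf)]), "\\s+"),
                                 function(x) as.integer(x[2:4]) + 1L))
  list(vertices = verts, faces = faces)
}

#' Read a triangulated surface from STL or PLY
#'
#' Binary and ASCII STL and ASCII PLY are supported; the format is sniffed
#' from the file content, not the extension. Coordinates are taken as mm in
#' patient coordinates.
#'
#' @param path input file.
#' @return A \linkS4class{SurfaceMesh}.
#' @export
readMesh <- function(path) {
  if (!file.exists(path) || file.size(path) == 0)
    stop("unreadable or empty file: ", path)
  head_raw <- readBin(path, "raw", n = 80)
  head_chr <- rawToChar(head_raw[head_raw != as.raw(0)])
  parts <- if (grepl("^ply", head_chr)) .read_ply_ascii(path)
  else if (grepl("^\\s*solid", head_chr) &&
           any(grepl("facet", readLines(path, n = 20, warn = FALSE))))
    .read_stl_ascii(path)
  else .read_stl_binary(path)
  SurfaceMesh(parts$vertices, parts$faces)
}

#' Write a surface mesh to STL or PLY
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @param path output file.
#' @param format "stl_binary", "stl_ascii" or "ply"; default inferred from
#'   the extension (.stl -> binary STL, .ply -> ASCII PLY).
#' @return \code{path}, invisibly.
#' @export
writeMesh <- function(mesh, path, format = c("auto", "stl_binary",
                                             "stl_ascii", "ply")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.ply$", path, ignore.case = TRUE)) "ply"
              else "stl_binary"
  v <- mesh@vertices; f <- mesh@faces
  if (format == "ply") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(v)),
                 "property float x", "property float y", "property float z",
                 sprintf("element face %d", nrow(f)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  } else if (format == "stl_ascii") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid mesh", con)
    for (i in seq_len(nrow(f))) {
      tri <- v[f[i, ], , drop = FALSE]
      n <- .normalize(.cross3(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ]))
      writeLines(c(sprintf("  facet normal %.9g %.9g %.9g", n[1], n[2], n[3]),
                   "    outer loop",
                   sprintf("      vertex %.9g %.9g %.9g",
                           tri[, 1], tri[, 2], tri[, 3]),
                   "    endloop", "  endfacet"), con)
    }
    writeLines("endsolid mesh", con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(f))) {
      tri <- v[f[i, ], , drop = FALSE]
      n <- .normalize(.cross3(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ]))
      writeBin(as.numeric(c(n, t(tri))), con, size = 4, endian = "little")
      writeBin(raw(2), con)
    }
  }
  invisible(path)
}
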