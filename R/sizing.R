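# Landing-zone sizing: the four diameters used for occluder selection.
#
# d_max / d_min are caliper diameters of the cross-section contour;
# d_peri = p / pi is the diameter of the circle with the contour's
# perimeter p; d_area = 2 sqrt(a / pi) that of the circle with its area a.
# On a circular section all four coincide; their spread quantifies
# non-circularity, summarized as ovality = d_max - d_min.

#' Sizing metrics of a cross-section
#'
#' Computes d_max, d_min (convex-hull calipers), d_peri = perimeter / pi,
#' d_area = 2 sqrt(area / pi) and ovality = d_max - d_min for the selected
#' loop of a planar section. Perimeter and area are measured on the raw
#' contour; calipers on its convex hull.
#'
#' @param section a \linkS4class{PlanarSection}.
#' @param which loop index (default 1, the selected/largest loop).
#' @param source provenance tag stored in the report ("CMR-prospective" for
#'   planning measurements d, "XR-located" for accuracy measurements d').
#' @return A \linkS4class{SizingReport}.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 513)[-513]
#' circ <- cbind(10 * cos(th), 10 * sin(th))
#' sec <- new("PlanarSection", plane_point = c(0, 0, 0),
#'            plane_normal = c(0, 0, 1),
#'            in_plane_axes = diag(3)[, 1:2], polygons = list(circ))
#' sizingFromSection(sec)  # all diameters 20 mm
#' @export
sizingFromSection <- function(section, which = 1, source = "CMR-prospective") {
  stopifnot(is(section, "PlanarSection"))
  if (length(section@polygons) < which) stop("no such section loop")
  poly <- section@polygons[[which]]
  p <- polygonPerimeter(poly)
  a <- polygonArea(poly)
  if (a <= 0 || p <= 0) stop("degenerate section loop")
  dmax <- polygonMaxDiameter(poly)$diameter_mm
  dmin <- polygonMinWidth(poly)
  new("SizingReport", d_max_mm = dmax, d_min_mm = dmin,
      d_peri_mm = p / pi, d_area_mm = 2 * sqrt(a / pi),
      ovality_mm = ovality(dmax, dmin), perimeter_mm = p, area_mm2 = a,
      source = source)
}

#' Ovality of a cross-section
#'
#' The difference between the maximal and minimal diameter; zero for a
#' circular landing zone. Larger ovality goes with larger disagreement
#' between the maximum diameter and single-projection measurements.
#'
#' @param d_max,d_min diameters (mm), \code{d_max >= d_min > 0}.
#' @return numeric(1), mm.
#' @export
ovality <- function(d_max, d_min) {
  if (any(d_min <= 0)) stop("diameters must be positive")
  if (any(d_min > d_max + 1e-12)) stop("d_min exceeds d_max")
  d_max - d_min
}

#' Look up a device size from a sizing chart
#'
#' Charts are user-supplied (vendor charts are calibrated for TEE-based
#' measurements and are deliberately not shipped): a data frame with
#' columns \code{lower_mm}, \code{upper_mm}, \code{label} defining
#' non-overlapping half-open intervals \[lower, upper).
#'
#' @param diameter_mm measured diameter (mm).
#' @param chart data frame as described, or a path to a CSV/YAML file with
#'   those columns.
#' @return character(1): the matching label, or \code{"no device"} when the
#'   diameter falls outside every interval.
#' @export
deviceLookup <- function(diameter_mm, chart) {
  if (is.character(chart) && length(chart) == 1) {
    chart <- if (grepl("\\.ya?ml$", chart, ignore.case = TRUE))
      do.call(rbind, lapply(yaml::read_yaml(chart), as.data.frame))
    else utils::read.csv(chart)
  }
  req <- c("lower_mm", "upper_mm", "label")
  if (!all(req %in% names(chart))) stop("chart must have columns ",
                                        paste(req, collapse = ", "))
  ch <- chart[order(chart$lower_mm), ]
  if (any(ch$upper_mm <= ch$lower_mm)) stop("malformed chart: empty interval")
  if (nrow(ch) > 1 && any(ch$lower_mm[-1] < ch$upper_mm[-nrow(ch)] - 1e-12))
    stop("malformed chart: overlapping intervals")
  hit <- which(diameter_mm >= ch$lower_mm & diameter_mm < ch$upper_mm)
  if (length(hit) == 0) "no device" else as.character(ch$label[hit[1]])
}
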