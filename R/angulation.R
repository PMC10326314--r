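# Optimal C-arm angulation prediction.
#
# A projection shows the landing zone without foreshortening when the beam
# lies in the cross-section plane and is orthogonal to the maximal diameter:
# the section is seen edge-on and d_max projects at true length. That beam
# is +/- normalize(plane_normal x dmax_direction); the sign ambiguity is
# resolved toward the center of the clinically recommended working range
# (RAO25/CAUD25).

.recommended_center <- function() CArmPose(-25, -25)

#' Predict the optimal C-arm angulation for a landing zone
#'
#' @param plane_normal numeric(3) unit normal of the cross-section plane.
#' @param dmax_direction numeric(3) unit direction of the maximal diameter,
#'   lying in the plane (orthogonal to the normal within 1e-6).
#' @param reference optional \linkS4class{CArmPose} a delta is reported
#'   against (e.g. the periprocedurally used angulation).
#' @param range_cfg recommended range passed to
#'   \code{\link{inRecommendedRange}}.
#' @return list of class \code{"AngulationResult"}: \code{solutions} (two
#'   antiparallel \linkS4class{CArmPose}s), \code{chosen}, \code{in_recommended},
#'   and \code{delta_to_reference_deg} (NA without a reference).
#' @export
optimalAngulation <- function(plane_normal, dmax_direction, reference = NULL,
                              range_cfg = recommendedRange()) {
  if (!.is_unit(plane_normal, 1e-6) || !.is_unit(dmax_direction, 1e-6))
    stop("plane_normal and dmax_direction must be unit vectors")
  if (abs(sum(plane_normal * dmax_direction)) > 1e-6)
    stop("dmax_direction must lie in the section plane")
  v <- .normalize(.cross3(plane_normal, dmax_direction))
  sols <- list(poseFromDirection(v), poseFromDirection(-v))
  ref_v <- viewingDirection(.recommended_center())
  ang <- vapply(sols, function(p) sum(viewingDirection(p) * ref_v), numeric(1))
  chosen <- sols[[which.max(ang)]]
  res <- list(
    solutions = sols,
    chosen = chosen,
    in_recommended = inRecommendedRange(chosen, range_cfg),
    delta_to_reference_deg = if (is.null(reference)) NA_real_
                             else angularDifference(chosen, reference))
  class(res) <- "AngulationResult"
  res
}

#' @export
print.AngulationResult <- function(x, ...) {
  cat(sprintf("AngulationResult: chosen alpha=%.1f beta=%.1f (%s recommended range)\n",
              x$chosen@alpha_deg, x$chosen@beta_deg,
              if (x$in_recommended) "inside" else "outside"))
  if (!is.na(x$delta_to_reference_deg))
    cat(sprintf("  delta to reference: %.1f deg\n", x$delta_to_reference_deg))
  invisible(x)
}

#' The clinically recommended angulation range
#'
#' Default RAO20-30/CAUD20-30, i.e. alpha in \[-30, -20\] and beta in
#' \[-30, -20\] in the DICOM sign convention.
#'
#' @param alpha_range,beta_range closed intervals (degrees).
#' @return list with \code{alpha_range} and \code{beta_range}.
#' @export
recommendedRange <- function(alpha_range = c(-30, -20),
                             beta_range = c(-30, -20)) {
  if (length(alpha_range) != 2 || length(beta_range) != 2 ||
      diff(alpha_range) < 0 || diff(beta_range) < 0)
    stop("ranges must be increasing length-2 intervals")
  list(alpha_range = alpha_range, beta_range = beta_range)
}

#' Is a pose inside the recommended angulation range?
#'
#' Closed-interval membership in both angles.
#'
#' @param pose a \linkS4class{CArmPose}.
#' @param range_cfg from \code{\link{recommendedRange}}.
#' @return logical(1).
#' @export
inRecommendedRange <- function(pose, range_cfg = recommendedRange()) {
  if (!all(c("alpha_range", "beta_range") %in% names(range_cfg)))
    stop("malformed range configuration")
  a <- range_cfg$alpha_range; b <- range_cfg$beta_range
  pose@alpha_deg >= a[1] && pose@alpha_deg <= a[2] &&
    pose@beta_deg >= b[1] && pose@beta_deg <= b[2]
}

#' Classify agreement between predicted and used angulation
#'
#' Two angulations are considered different when their 3D viewing-direction
#' angle exceeds the threshold (default 10 degrees, the rounded upper bound
#' of the observed inter-reader variability of the prediction). The
#' threshold comparison is strict: exactly 10 degrees still agrees.
#'
#' @param predicted,used \linkS4class{CArmPose} objects.
#' @param threshold_deg numeric(1), degrees.
#' @return \code{"agree"} or \code{"differ"}.
#' @export
classifyAgreement <- function(predicted, used, threshold_deg = 10) {
  # tiny slack so a difference of exactly the threshold classifies as agree
  # regardless of floating-point representation
  if (angularDifference(predicted, used) > threshold_deg + 1e-9)
    "differ" else "agree"
}

#' Confusion matrix of predicted vs used angulation classes
#'
#' Cross-tabulates whether the predicted and the clinically used angulation
#' fall in the recommended range, as percentages of all cases (rounded to
#' whole percent for display; raw counts retained).
#'
#' @param predicted_in,used_in logical vectors, one element per case.
#' @return list with \code{counts} and \code{percent} (2 x 2 matrices, rows =
#'   used angulation recommended yes/no, columns = predicted) and \code{n}.
#' @export
confusionMatrix <- function(predicted_in, used_in) {
  if (length(predicted_in) == 0 || length(predicted_in) != length(used_in))
    stop("need equal-length non-empty classification vectors")
  lv <- c("recommended", "different")
  fu <- factor(ifelse(used_in, lv[1], lv[2]), levels = lv)
  fp <- factor(ifelse(predicted_in, lv[1], lv[2]), levels = lv)
  counts <- table(used = fu, predicted = fp)
  res <- list(counts = unclass(counts),
              percent = round(100 * unclass(counts) / length(used_in)),
              n = length(used_in))
  class(res) <- "AngulationConfusion"
  res
}

#' @export
print.AngulationConfusion <- function(x, ...) {
  p <- x$percent
  cat("Predicted vs clinically chosen C-arm angulation (% of",
      x$n, "cases)\n")
  cat(sprintf("%-22s %12s %14s\n", "Clinically chosen", "Recommended",
              "Different >10°"))
  cat(sprintf("%-22s %11d%% %13d%%\n", "Recommended", p[1, 1], p[1, 2]))
  cat(sprintf("%-22s %11d%% %13d%%\n", "Different >10°", p[2, 1], p[2, 2]))
  invisible(x)
}
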