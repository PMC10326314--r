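# Batch workflows binding the stages together:
#   runAccuracy  - localize XR annotations on the mesh and compare the
#                  mesh-measured d' diameters with the XR measurements;
#   runPlanning  - size prospectively chosen landing planes, predict the
#                  optimal angulation and classify it against the used one;
#   runPhantomStudy - full synthetic study exercising both workflows on
#                  generated phantoms with ground truth.
# One failing case is logged and skipped, never aborts a batch.

.write_manifest <- function(out_dir, config) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tmp <- tempfile()
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  manifest <- list(
    config = config,
    config_md5 = unname(tools::md5sum(tmp)),
    package_version = as.character(utils::packageVersion("laaplan")))
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(NULL)
}

.per_case <- function(cases, fn) {
  ok <- list(); failures <- character()
  for (cs in cases) {
    id <- if (!is.null(cs$id)) cs$id else length(ok) + 1
    res <- tryCatch(fn(cs), error = function(e) e)
    if (inherits(res, "error")) {
      warning("case ", id, " skipped: ", conditionMessage(res))
      failures <- c(failures, sprintf("%s: %s", id, conditionMessage(res)))
    } else ok[[as.character(id)]] <- res
  }
  list(results = ok, failures = failures)
}

#' Accuracy workflow: measure at the XR-annotated landing zone
#'
#' For every case the detector annotation is localized on the registered
#' mesh, the landing plane sectioned, and the d' metrics (d'_max, d'_min,
#' d'_proj, ovality) measured; when XR reference diameters are supplied the
#' d'_max-vs-d_XR and d'_proj-vs-d_XR agreement statistics are computed.
#'
#' @param cases list of per-case lists with elements \code{id}, \code{mesh}
#'   (\linkS4class{SurfaceMesh}), \code{pose} (\linkS4class{CArmPose}),
#'   \code{q_a}, \code{q_b} (detector mm) and optionally \code{d_xr_mm}.
#' @param out_dir optional output directory (CSV tables + manifest).
#' @return list: \code{sizing} (per-case data.frame), \code{agreement}
#'   (from \code{\link{agreementTable}}, or NULL), \code{failures},
#'   \code{ok} (TRUE when no case failed).
#' @export
runAccuracy <- function(cases, out_dir = NULL) {
  if (length(cases) == 0) stop("no cases supplied")
  run <- .per_case(cases, function(cs) {
    zone <- localizeLandingZone(cs$mesh, cs$pose, cs$q_a, cs$q_b)
    sec <- measureCrossSection(cs$mesh, zone)
    rep <- sizingFromSection(sec, source = "XR-located")
    row <- asSizingRow(rep)
    row$d_proj_mm <- projectedDiameter(sec, cs$pose)
    row$d_xr_mm <- if (!is.null(cs$d_xr_mm)) cs$d_xr_mm else NA_real_
    list(row = row, zone = zone)
  })
  rows <- do.call(rbind, lapply(names(run$results), function(id)
    cbind(case_id = id, run$results[[id]]$row)))
  agreement <- NULL
  if (!is.null(rows) && all(!is.na(rows$d_xr_mm)) && nrow(rows) >= 3) {
    agreement <- agreementTable(list(
      "d'_max vs. d_XR" = list(a = rows$d_max_mm, b = rows$d_xr_mm),
      "d'_proj vs. d_XR" = list(a = rows$d_proj_mm, b = rows$d_xr_mm)))
  }
  if (!is.null(out_dir)) {
    .write_manifest(out_dir, list(workflow = "accuracy",
                                  n_cases = length(cases)))
    utils::write.csv(rows, file.path(out_dir, "sizing_accuracy.csv"),
                     row.names = FALSE)
    if (!is.null(agreement))
      utils::write.csv(agreement, file.path(out_dir, "agreement.csv"),
                       row.names = FALSE)
  }
  list(sizing = rows, agreement = agreement, failures = run$failures,
       ok = length(run$failures) == 0)
}

#' Planning workflow: size a prospective landing plane and predict the view
#'
#' For every case the user-specified landing plane is sectioned, the d
#' metrics computed, the optimal C-arm angulation predicted from the section
#' and classified against the periprocedurally used pose (recommended-range
#' membership and the >10 degree rule).
#'
#' @param cases list of per-case lists: \code{id}, \code{mesh},
#'   \code{plane_point}, \code{plane_normal}, optionally \code{used_pose}
#'   (\linkS4class{CArmPose}) and \code{d_xr_mm}.
#' @param threshold_deg agreement threshold (degrees).
#' @param range_cfg from \code{\link{recommendedRange}}.
#' @param out_dir optional output directory.
#' @return list: \code{sizing}, \code{angulation} (per-case data.frame),
#'   \code{confusion} (when used poses given), \code{agreement} (when XR
#'   diameters given), \code{failures}, \code{ok}.
#' @export
runPlanning <- function(cases, threshold_deg = 10,
                        range_cfg = recommendedRange(), out_dir = NULL) {
  if (length(cases) == 0) stop("no cases supplied")
  run <- .per_case(cases, function(cs) {
    sec <- planeSection(cs$mesh, cs$plane_point, cs$plane_normal)
    # keep the loop nearest the requested plane point (lobed anatomies)
    mid2 <- drop(crossprod(sec@in_plane_axes,
                           as.numeric(cs$plane_point) - sec@plane_point))
    cent <- vapply(sec@polygons, .polygon_centroid, numeric(2))
    sec@polygons <- sec@polygons[order(colSums((cent - mid2)^2))]
    rep <- sizingFromSection(sec, source = "CMR-prospective")
    dm <- polygonMaxDiameter(sec@polygons[[1]])
    dir3 <- .normalize(drop(sec@in_plane_axes %*% dm$direction))
    ang <- optimalAngulation(sec@plane_normal, dir3,
                             reference = cs$used_pose, range_cfg = range_cfg)
    arow <- data.frame(
      pred_alpha_deg = ang$chosen@alpha_deg,
      pred_beta_deg = ang$chosen@beta_deg,
      pred_in_recommended = ang$in_recommended,
      used_alpha_deg = if (!is.null(cs$used_pose)) cs$used_pose@alpha_deg else NA,
      used_beta_deg = if (!is.null(cs$used_pose)) cs$used_pose@beta_deg else NA,
      used_in_recommended = if (!is.null(cs$used_pose))
        inRecommendedRange(cs$used_pose, range_cfg) else NA,
      delta_deg = ang$delta_to_reference_deg,
      label = if (!is.null(cs$used_pose))
        classifyAgreement(ang$chosen, cs$used_pose, threshold_deg)
      else NA_character_)
    srow <- asSizingRow(rep)
    srow$d_xr_mm <- if (!is.null(cs$d_xr_mm)) cs$d_xr_mm else NA_real_
    list(sizing = srow, angulation = arow)
  })
  ids <- names(run$results)
  sizing <- do.call(rbind, lapply(ids, function(id)
    cbind(case_id = id, run$results[[id]]$sizing)))
  angulation <- do.call(rbind, lapply(ids, function(id)
    cbind(case_id = id, run$results[[id]]$angulation)))
  confusion <- NULL
  if (!is.null(angulation) && all(!is.na(angulation$used_in_recommended)))
    confusion <- confusionMatrix(angulation$pred_in_recommended,
                                 angulation$used_in_recommended)
  agreement <- NULL
  if (!is.null(sizing) && all(!is.na(sizing$d_xr_mm)) && nrow(sizing) >= 3)
    agreement <- agreementTable(list(
      "d_max vs. d_XR" = list(a = sizing$d_max_mm, b = sizing$d_xr_mm),
      "d_peri vs. d_XR" = list(a = sizing$d_peri_mm, b = sizing$d_xr_mm),
      "d_area vs. d_XR" = list(a = sizing$d_area_mm, b = sizing$d_xr_mm)))
  if (!is.null(out_dir)) {
    .write_manifest(out_dir, list(workflow = "planning",
                                  n_cases = length(cases),
                                  threshold_deg = threshold_deg))
    utils::write.csv(sizing, file.path(out_dir, "sizing_planning.csv"),
                     row.names = FALSE)
    utils::write.csv(angulation, file.path(out_dir, "angulation.csv"),
                     row.names = FALSE)
    if (!is.null(confusion))
      jsonlite::write_json(confusion[c("counts", "percent", "n")],
                           file.path(out_dir, "confusion.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  list(sizing = sizing, angulation = angulation, confusion = confusion,
       agreement = agreement, failures = run$failures,
       ok = length(run$failures) == 0)
}

# Seeded family of phantom specs in the clinical LAA size range.
.study_specs <- function(n_cases, seed) {
  .with_seed(seed, lapply(seq_len(n_cases), function(i) {
    a <- stats::runif(1, 8, 15)
    ratio <- stats::runif(1, 0.6, 1)
    taper <- stats::runif(1, 0.85, 1)   # shared so a >= b along the tube
    PhantomSpec(
      centerline = "straight",
      length_mm = stats::runif(1, 50, 70),
      semi_a_mm = c(a, a * taper),
      semi_b_mm = c(a * ratio, a * ratio * taper),
      twist_deg = c(0, stats::runif(1, -20, 20)),
      landing_s = stats::runif(1, 0.35, 0.65),
      rng_seed = i)
  }))
}

#' Full synthetic phantom study
#'
#' Generates a cohort of phantoms in the clinical LAA size range, places
#' each at a working projection sampled inside the recommended range,
#' simulates the fluoroscopic annotation (optionally noisy), runs the
#' accuracy and planning workflows, and simulates a three-reader panel for
#' the interrater reliability analysis. With zero noise the study is a
#' ground-truth round trip: agreement biases vanish up to mesh resolution
#' and the angulation confusion matrix is fully concordant.
#'
#' @param n_cases number of phantom cases.
#' @param seed master integer seed; all per-case seeds derive from it.
#' @param annotation_noise_mm detector annotation noise sd (mm).
#' @param reader_noise_mm,reader_bias_mm reader panel parameters (mm).
#' @param out_dir optional output directory.
#' @return list: \code{accuracy}, \code{planning} (workflow outputs),
#'   \code{icc} (reader panel ICC(2,1)), \code{truth} (per-case ground
#'   truth data.frame), \code{seed}.
#' @export
runPhantomStudy <- function(n_cases = 13, seed = 7,
                            annotation_noise_mm = 0, reader_noise_mm = 1,
                            reader_bias_mm = 0.5, out_dir = NULL) {
  if (n_cases < 2) stop("need at least 2 cases")
  specs <- .study_specs(n_cases, seed)
  poses <- .with_seed(seed + 1,
    lapply(seq_len(n_cases), function(i)
      CArmPose(stats::runif(1, -30, -20), stats::runif(1, -30, -20))))
  acc_cases <- list(); plan_cases <- list(); truth_rows <- list()
  for (i in seq_len(n_cases)) {
    ph <- placePhantom(generatePhantom(specs[[i]]), poses[[i]])
    pose <- ph$truth$tangential_pose
    # the inward inset grows with the noise level (a reader marking the
    # inner lumen edge conservatively), keeping the grazing projection
    # lines inside the silhouette for ~98% of annotations
    ann <- simulateAnnotation(ph, pose, endpoint_noise_mm = annotation_noise_mm,
                              seed = seed + 100 + i,
                              inset_mm = 0.05 + 2 * annotation_noise_mm)
    # XR measurement: annotated detector span scaled back to isocenter depth
    d_xr <- sqrt(sum((ann$q_b - ann$q_a)^2)) * pose@sod_mm / pose@sid_mm
    acc_cases[[i]] <- list(id = i, mesh = ph$mesh, pose = pose,
                           q_a = ann$q_a, q_b = ann$q_b, d_xr_mm = d_xr)
    plan_cases[[i]] <- list(id = i, mesh = ph$mesh,
                            plane_point = ph$truth$plane_point,
                            plane_normal = ph$truth$plane_normal,
                            used_pose = pose, d_xr_mm = d_xr)
    truth_rows[[i]] <- data.frame(
      case_id = i, d_max_mm = ph$truth$d_max_mm,
      d_min_mm = ph$truth$d_min_mm, d_peri_mm = ph$truth$d_peri_mm,
      d_area_mm = ph$truth$d_area_mm, ovality_mm = ph$truth$ovality_mm,
      alpha_deg = pose@alpha_deg, beta_deg = pose@beta_deg)
  }
  accuracy <- runAccuracy(acc_cases,
                          out_dir = if (is.null(out_dir)) NULL
                                    else file.path(out_dir, "accuracy"))
  planning <- runPlanning(plan_cases,
                          out_dir = if (is.null(out_dir)) NULL
                                    else file.path(out_dir, "planning"))
  panel <- simulateReaderPanel(n_cases, reader_noise_mm = reader_noise_mm,
                               reader_bias_mm = reader_bias_mm,
                               seed = seed + 2)
  icc <- icc21(panel$ratings)
  truth <- do.call(rbind, truth_rows)
  if (!is.null(out_dir)) {
    .write_manifest(out_dir, list(workflow = "phantom-study",
                                  n_cases = n_cases, seed = seed,
                                  annotation_noise_mm = annotation_noise_mm))
    utils::write.csv(truth, file.path(out_dir, "ground_truth.csv"),
                     row.names = FALSE)
  }
  list(accuracy = accuracy, planning = planning, icc = icc, truth = truth,
       seed = seed)
}
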