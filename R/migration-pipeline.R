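# Per-patient longitudinal analysis: exam-level reconstruction, marker- and
# EGS-based implant-to-bone migration, head-taper slip in the taper frame,
# RSA quality gating and cohort summaries.

#' RSA quality thresholds
#'
#' The standard gates applied to every analysed exam pair: calibration error
#' (translation) <= 0.05 mm, focus error <= 0.5 mm, condition number <= 100,
#' rigid-body error <= 0.35 mm. Boundaries are inclusive.
#'
#' @param max_calibration_error,max_focus_error,max_condition_number,max_rigid_body_error
#'   the four gate values.
#' @return named list of class `quality_thresholds`.
#' @export
quality_thresholds <- function(max_calibration_error = 0.05,
                               max_focus_error = 0.5,
                               max_condition_number = 100,
                               max_rigid_body_error = 0.35) {
  th <- list(max_calibration_error = max_calibration_error,
             max_focus_error = max_focus_error,
             max_condition_number = max_condition_number,
             max_rigid_body_error = max_rigid_body_error)
  stopifnot(all(unlist(th) > 0))
  structure(th, class = "quality_thresholds")
}

#' Apply the RSA quality gates
#'
#' Pure threshold comparison (inclusive `<=`), reported per criterion.
#'
#' @param metrics named list/vector with `calibration_error`, `focus_error`,
#'   `condition_number`, `rigid_body_error`. `NA` entries pass (metric not
#'   applicable).
#' @param thresholds a [quality_thresholds()].
#' @return named logical vector with one element per criterion plus
#'   attribute `pass` (overall).
#' @export
quality_gate <- function(metrics, thresholds = quality_thresholds()) {
  m <- as.list(metrics)
  chk <- function(value, max) is.null(value) || is.na(value) || value <= max
  out <- c(calibration_error = chk(m$calibration_error, thresholds$max_calibration_error),
           focus_error = chk(m$focus_error, thresholds$max_focus_error),
           condition_number = chk(m$condition_number, thresholds$max_condition_number),
           rigid_body_error = chk(m$rigid_body_error, thresholds$max_rigid_body_error))
  attr(out, "pass") <- all(out)
  out
}

#' Analyse a single exam: calibration, reconstruction, EGS fits
#'
#' Calibrates both views from the exam's calibration-box observations,
#' stereo-reconstructs bone markers, implant markers and the stem-tip
#' landmark, fits the ball-head sphere to the head contours of both views
#' and the taper cone to the silhouette lines.
#'
#' @param exam an `rsa_exam` (see [generate_patient()] /
#'   [read_exam_json()]).
#' @param box the [calibration_box()] model used at acquisition.
#' @param head_radius known ball-head radius, mm (taken from the exam meta
#'   if present).
#' @return list of class `exam_analysis`: `cal` (two `view_calibration`),
#'   3D `bone`, `implant`, `tip`, `head` (sphere fit), `cone`
#'   (`cone_model`), `crossing` (per-marker crossing distances) and
#'   `metrics` (worst-view calibration and focus errors).
#' @export
analyze_exam <- function(exam, box, head_radius = NULL) {
  stopifnot(inherits(exam, "rsa_exam"))
  if (is.null(head_radius)) head_radius <- exam$meta$head_radius %||% 14
  v1 <- exam$views[[1]]; v2 <- exam$views[[2]]
  cal <- lapply(exam$views, function(v) calibrate_view(box, v$fiducials, v$controls))

  rec <- function(field) {
    m1 <- apply_planar_map(cal[[1]]$film_transform, v1$markers[[field]])
    m2 <- apply_planar_map(cal[[2]]$film_transform, v2$markers[[field]])
    reconstruct_point(cal[[1]], cal[[2]], m1, m2)
  }
  bone <- rec("bone"); implant <- rec("implant"); tip <- rec("tip")
  head <- fit_sphere_center(cal,
                            list(apply_planar_map(cal[[1]]$film_transform, v1$head_contour),
                                 apply_planar_map(cal[[2]]$film_transform, v2$head_contour)),
                            head_radius)
  fit_silhouette_cone <- function(field) {
    fit_cone_axis(cal, lapply(seq_along(exam$views), function(k) {
      lapply(exam$views[[k]][[field]], function(seg) {
        apply_planar_map(cal[[k]]$film_transform, seg)
      })
    }))
  }
  cone <- fit_silhouette_cone("taper_silhouette")
  stem_axis <- fit_silhouette_cone("stem_silhouette")
  structure(list(
    cal = cal, bone = bone$positions, implant = implant$positions,
    tip = as.numeric(tip$positions[1, ]), head = head, cone = cone,
    stem_axis = stem_axis,
    crossing = c(bone$crossing_distances, implant$crossing_distances),
    metrics = list(calibration_error = max(vapply(cal, `[[`, numeric(1), "calibration_error")),
                   focus_error = max(vapply(cal, `[[`, numeric(1), "focus_error")))),
    class = "exam_analysis")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Analyse every exam of a patient series
#'
#' @param series a `patient_series`.
#' @param box calibration box; defaults to the one stored in the series.
#' @return the series with an `analysis` element (named like `visits`).
#' @export
analyze_series <- function(series, box = NULL) {
  stopifnot(inherits(series, "patient_series"))
  box <- box %||% series$box
  series$analysis <- lapply(series$visits, analyze_exam, box = box,
                            head_radius = series$head_radius)
  series
}

series_analysis <- function(series) {
  if (is.null(series$analysis)) series <- analyze_series(series)
  series
}

# virtual markers of one analysed exam (EGS pipeline): P3 projects the head
# centre onto the stem-body (cylinder) axis line
exam_virtual_markers <- function(an) {
  construct_virtual_markers(an$head$center, an$stem_axis$axis_point,
                            an$stem_axis$axis_direction, an$tip)
}

#' Implant-to-bone migration between the reference and a follow-up exam
#'
#' Patient repositioning is removed through the bone-marker rigid transform;
#' the implant transform is then fitted between the reference implant body
#' and the repositioning-corrected follow-up body. Three methods share this
#' machinery:
#' \describe{
#'   \item{`marker`}{rigid body = the 3 tantalum implant markers; reference
#'     point = their centroid.}
#'   \item{`egs`}{rigid body = the 3 virtual markers (head centre, stem tip,
#'     axis projection); reference point = their centroid. Head-taper slip
#'     deforms this body, so its result is slip-sensitive by design.}
#'   \item{`egs_corrected`}{the `egs` transform with translations
#'     re-expressed at the tantalum-marker centroid via
#'     [correct_reference_point()].}
#' }
#'
#' @param series a `patient_series` (analysed or not).
#' @param visit follow-up visit in months (must exist in the series).
#' @param method `"marker"`, `"egs"` or `"egs_corrected"`.
#' @param thresholds a [quality_thresholds()].
#' @param gate if `TRUE` (default) failing records are flagged
#'   (`gated_out = TRUE` with reasons); values are still reported.
#' @return list of class `migration_sixdof`: `Tx`, `Ty`, `Tz` (mm), `Rx`,
#'   `Ry`, `Rz` (degrees), `reference_point`, `quality`
#'   (condition_number, rigid_body_error, calibration_error, focus_error),
#'   `gate`, `gated_out`, `method`, `visit_months`.
#' @export
implant_to_bone_migration <- function(series, visit,
                                      method = c("marker", "egs", "egs_corrected"),
                                      thresholds = quality_thresholds(),
                                      gate = TRUE) {
  method <- match.arg(method)
  series <- series_analysis(series)
  ref <- series$analysis[[format(0)]]
  fu <- series$analysis[[format(visit)]]
  if (is.null(ref) || is.null(fu)) stop("visit not found in series")

  bone_fit <- fit_rigid_body(ref$bone, fu$bone)
  unpose <- invert_transform(bone_fit$transform)

  if (method == "marker") {
    ref_pts <- ref$implant
    fu_pts <- apply_transform(unpose, fu$implant)
  } else {
    vm_ref <- exam_virtual_markers(ref)
    vm_fu <- exam_virtual_markers(fu)
    ref_pts <- rbind(vm_ref$P1, vm_ref$P2, vm_ref$P3)
    fu_pts <- apply_transform(unpose, rbind(vm_fu$P1, vm_fu$P2, vm_fu$P3))
  }
  fit <- fit_rigid_body(ref_pts, fu_pts)
  ref_point <- colMeans(ref_pts)
  trans <- migration_of_point(fit$transform, ref_point)
  if (method == "egs_corrected") {
    marker_cent <- colMeans(ref$implant)
    trans <- correct_reference_point(fit$transform, trans, ref_point, marker_cent)
    ref_point <- marker_cent
  }
  ang <- euler_angles(fit$transform)

  metrics <- list(
    calibration_error = max(ref$metrics$calibration_error, fu$metrics$calibration_error),
    focus_error = max(ref$metrics$focus_error, fu$metrics$focus_error),
    condition_number = max(condition_number(ref$bone), condition_number(ref_pts)),
    rigid_body_error = max(bone_fit$rigid_body_error, fit$rigid_body_error))
  g <- quality_gate(metrics, thresholds)
  gated_out <- gate && !attr(g, "pass")

  structure(list(Tx = trans[1], Ty = trans[2], Tz = trans[3],
                 Rx = unname(ang["Rx"]), Ry = unname(ang["Ry"]), Rz = unname(ang["Rz"]),
                 reference_point = as.numeric(ref_point),
                 quality = metrics, gate = g, gated_out = gated_out,
                 gate_reasons = names(g)[!g],
                 method = method, visit_months = visit,
                 patient_id = series$patient_id),
            class = "migration_sixdof")
}

#' Head-taper migration (slip) at a follow-up visit
#'
#' Relative motion of the ball head with respect to the stem, expressed in
#' the reference exam's taper frame (Y along the taper axis, X medial, Z
#' anterior). With `T` the stem-marker rigid transform from reference to
#' follow-up, the slip vector in the reference exam is
#' `T^-1(h_fu) - h_ref`, which removes all stem motion (implant-to-bone
#' migration and repositioning) from the result. Visit 0 returns exact
#' zeros.
#'
#' @param series a `patient_series`.
#' @param visit months.
#' @return list of class `head_taper_migration`: `visit_months`, `dx`,
#'   `dy`, `dz` (mm, taper frame), `frame` (the reference
#'   [build_taper_frame()]), `stem_rbe` (stem fit residual).
#' @export
head_taper_migration <- function(series, visit) {
  series <- series_analysis(series)
  ref <- series$analysis[[format(0)]]
  frame <- build_taper_frame(ref$cone, ref$implant, series$side %||% "right")
  if (visit == 0) {
    return(structure(list(visit_months = 0, dx = 0, dy = 0, dz = 0,
                          frame = frame, stem_rbe = 0,
                          patient_id = series$patient_id),
                     class = "head_taper_migration"))
  }
  fu <- series$analysis[[format(visit)]]
  if (is.null(fu)) stop("visit not found in series")
  stem_fit <- fit_rigid_body(ref$implant, fu$implant)
  h_back <- apply_transform(invert_transform(stem_fit$transform), fu$head$center)
  slip <- vector_in_frame(frame, h_back - ref$head$center)
  structure(list(visit_months = visit,
                 dx = unname(slip["x"]), dy = unname(slip["y"]), dz = unname(slip["z"]),
                 frame = frame, stem_rbe = stem_fit$rigid_body_error,
                 patient_id = series$patient_id),
            class = "head_taper_migration")
}

#' Migration table for a study (long format)
#'
#' One row per patient, follow-up visit and method, matching the migration
#' CSV schema: `patient_id, visit_months, method, Tx, Ty, Tz, Rx, Ry, Rz,
#' CN, RBE, pass`.
#'
#' @param study a `phantom_study`, or a list of (analysed) `patient_series`.
#' @param methods subset of `c("marker", "egs", "egs_corrected")`.
#' @param thresholds a [quality_thresholds()].
#' @return a data.frame.
#' @export
migration_table <- function(study, methods = c("marker", "egs", "egs_corrected"),
                            thresholds = quality_thresholds()) {
  patients <- if (inherits(study, "phantom_study")) study$patients else study
  rows <- list()
  for (series in patients) {
    series <- series_analysis(series)
    months <- vapply(series$visits, function(e) e$meta$visit_months, numeric(1))
    for (m in months[months > 0]) {
      for (meth in methods) {
        r <- implant_to_bone_migration(series, m, meth, thresholds)
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = series$patient_id, visit_months = m, method = meth,
          Tx = r$Tx, Ty = r$Ty, Tz = r$Tz, Rx = r$Rx, Ry = r$Ry, Rz = r$Rz,
          CN = r$quality$condition_number, RBE = r$quality$rigid_body_error,
          pass = !r$gated_out)
      }
    }
  }
  do.call(rbind, rows)
}

#' Head-taper migration table for a study
#'
#' One row per patient and visit: `patient_id, visit_months, dx, dy, dz,
#' head_neck_length, stem_rbe`.
#'
#' @inheritParams migration_table
#' @return a data.frame.
#' @export
headtaper_table <- function(study) {
  patients <- if (inherits(study, "phantom_study")) study$patients else study
  rows <- list()
  for (series in patients) {
    series <- series_analysis(series)
    months <- vapply(series$visits, function(e) e$meta$visit_months, numeric(1))
    for (m in months) {
      r <- head_taper_migration(series, m)
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = series$patient_id, visit_months = m,
        dx = r$dx, dy = r$dy, dz = r$dz,
        head_neck_length = series$head_neck_length %||% NA_character_,
        stem_rbe = r$stem_rbe)
    }
  }
  do.call(rbind, rows)
}

#' Descriptive statistics (both SD conventions)
#'
#' Mean plus the population SD (divisor n) and sample SD (divisor n-1).
#' In-vitro impaction tables are conventionally reported as mean +-
#' population SD rounded to integer micrometres; use
#' `round(mean)`/`round(sd_population)` for that style.
#'
#' @param values numeric vector, length >= 1.
#' @return list with `mean`, `sd_population`, `sd_sample` (`NA` for n = 1),
#'   `n`.
#' @examples
#' descriptive_stats(c(160, 155, 160, 173, 160))  # 162 +- 6 after rounding
#' @export
descriptive_stats <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 1L || anyNA(values)) stop("need at least one non-missing value")
  n <- length(values)
  m <- mean(values)
  list(mean = m,
       sd_population = sqrt(mean((values - m)^2)),
       sd_sample = if (n > 1L) stats::sd(values) else NA_real_,
       n = n)
}

#' Cohort summary of head-taper migration
#'
#' Per-visit mean +- SD of each slip component (available-case analysis),
#' optionally grouped by head-neck length, plus the migration rate: the 3D
#' magnitude of the mean slip vector at the final visit divided by the
#' follow-up in years (per-axis rates are also emitted).
#'
#' @param ht a [headtaper_table()] data.frame.
#' @param group_by `"none"` or `"head_neck_length"`.
#' @return list with `summary` (data.frame: group, visit_months, n, and
#'   mean/sd per component), `rate_mm_per_year`, `rate_per_axis`,
#'   `group_counts`.
#' @export
cohort_summary <- function(ht, group_by = c("none", "head_neck_length")) {
  group_by <- match.arg(group_by)
  ht$group <- if (group_by == "none") "all" else ht$head_neck_length
  rows <- list()
  for (g in unique(ht$group)) {
    sub <- ht[ht$group == g, ]
    for (m in sort(unique(sub$visit_months))) {
      s <- sub[sub$visit_months == m, ]
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, visit_months = m, n = nrow(s),
        dx_mean = mean(s$dx), dx_sd = stats::sd(s$dx),
        dy_mean = mean(s$dy), dy_sd = stats::sd(s$dy),
        dz_mean = mean(s$dz), dz_sd = stats::sd(s$dz))
    }
  }
  summary <- do.call(rbind, rows)
  final <- max(ht$visit_months)
  fin <- ht[ht$visit_months == final, ]
  mean_vec <- c(mean(fin$dx), mean(fin$dy), mean(fin$dz))
  years <- final / 12
  per_patient <- table(ht$group[ht$visit_months == final])
  list(summary = summary,
       rate_mm_per_year = vnorm(mean_vec) / years,
       rate_per_axis = stats::setNames(mean_vec / years, c("x", "y", "z")),
       group_counts = per_patient)
}

#' In-vitro impaction migration table
#'
#' Loads the bundled per-junction head-taper migration measurements (n = 5
#' CoCr taper / ceramic head pairs; micrometres of migration along the taper
#' axis after impaction at 2 kN, after a subsequent 4 kN impaction, and in
#' total).
#'
#' @return data.frame with columns `junction`, `imp_0_2kN`, `imp_2_4kN`,
#'   `total`.
#' @export
impaction_table <- function() {
  utils::read.csv(system.file("extdata", "impaction_migration_um.csv",
                              package = "rsataper"))
}
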