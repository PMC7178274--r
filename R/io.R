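# Exam JSON dialect, ground-truth JSON, study run directories and the CSV
# outputs. All coordinates are mm in the film frame (after mapping) for 2D
# and the calibration-box frame for 3D.

#' Write an exam to JSON
#'
#' Schema: `{"views": [{"fiducials": [[u,v],...], "controls": [[u,v],...],
#' "markers": {"bone": [...], "implant": [...], "tip": [[u,v]]},
#' "head_contour": [[u,v],...], "taper_silhouette": [[[u,v],[u,v]], ...],
#' "stem_silhouette": [[[u,v],[u,v]], ...]}
#' x2], "meta": {...}}`. The `tip` landmark (lowest point of the stem tip)
#' extends the marker block so that the EGS virtual marker P2 can be
#' reconstructed.
#'
#' @param exam an `rsa_exam`.
#' @param path output file.
#' @export
write_exam_json <- function(exam, path) {
  stopifnot(inherits(exam, "rsa_exam"))
  views <- lapply(exam$views, function(v) {
    list(fiducials = unname(as_points2(v$fiducials)),
         controls = unname(as_points2(v$controls)),
         markers = list(bone = unname(as_points2(v$markers$bone)),
                        implant = unname(as_points2(v$markers$implant)),
                        tip = unname(as_points2(v$markers$tip))),
         head_contour = unname(as_points2(v$head_contour)),
         taper_silhouette = lapply(v$taper_silhouette,
                                   function(s) unname(as_points2(s))),
         stem_silhouette = lapply(v$stem_silhouette,
                                  function(s) unname(as_points2(s))))
  })
  jsonlite::write_json(list(views = views, meta = exam$meta), path,
                       digits = NA, auto_unbox = TRUE, pretty = FALSE)
  invisible(path)
}

#' Read an exam from JSON
#' @param path file written by [write_exam_json()].
#' @return an `rsa_exam`.
#' @export
read_exam_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = TRUE,
                           simplifyDataFrame = FALSE)
  views <- lapply(x$views, function(v) {
    list(fiducials = as_points2(v$fiducials),
         controls = as_points2(v$controls),
         markers = list(bone = as_points2(v$markers$bone),
                        implant = as_points2(v$markers$implant),
                        tip = as_points2(v$markers$tip)),
         head_contour = as_points2(v$head_contour),
         taper_silhouette = as_segment_list(v$taper_silhouette),
         stem_silhouette = as_segment_list(v$stem_silhouette))
  })
  structure(list(views = views, meta = as.list(x$meta)), class = "rsa_exam")
}

# jsonlite may simplify a list of equally-sized segments to a 3D array
as_segment_list <- function(x) {
  if (is.array(x) && length(dim(x)) == 3L) {
    return(lapply(seq_len(dim(x)[1]), function(i) as_points2(x[i, , ])))
  }
  lapply(x, as_points2)
}

#' Write a phantom study to a run directory
#'
#' Layout: `<dir>/manifest.json` (schema versions, seed, config digest),
#' one `<patient>/exam_<months>.json` per visit and a matching
#' `<patient>/truth_<months>.json` carrying the ground-truth migration
#' parameters and slip vector.
#'
#' @param study a [generate_study()] result.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "phantom_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (series in study$patients) {
    pdir <- file.path(dir, series$patient_id)
    dir.create(pdir, showWarnings = FALSE)
    for (key in names(series$visits)) {
      write_exam_json(series$visits[[key]],
                      file.path(pdir, sprintf("exam_%s.json", key)))
      gt <- series$ground_truth[[key]]
      jsonlite::write_json(
        list(visit_months = gt$visit_months,
             migration = as.list(gt$migration),
             slip = as.list(gt$slip)),
        file.path(pdir, sprintf("truth_%s.json", key)),
        digits = NA, auto_unbox = TRUE)
    }
  }
  cfg <- study$config
  manifest <- list(schema_version = "1.0",
                   generator = "rsataper",
                   seed = cfg$seed,
                   n_patients = cfg$n_patients,
                   schedule = cfg$schedule,
                   noise_sigma_2d = cfg$noise_sigma_2d,
                   patients = names(study$patients))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a study run directory back into patient series
#'
#' Reconstructs `patient_series` objects (exams and ground truth) from a
#' [write_study()] directory. The calibration box is not serialized with
#' the exams and must be supplied (the acquisition-time box model).
#'
#' @param dir run directory.
#' @param box a [calibration_box()].
#' @return list of `patient_series`.
#' @export
read_study <- function(dir, box = calibration_box()) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  lapply(manifest$patients, function(pid) {
    pdir <- file.path(dir, pid)
    files <- list.files(pdir, "^exam_.*\\.json$")
    months <- sort(as.numeric(sub("^exam_(.*)\\.json$", "\\1", files)))
    visits <- list(); truth <- list()
    for (m in months) {
      key <- format(m)
      visits[[key]] <- read_exam_json(file.path(pdir, sprintf("exam_%s.json", key)))
      tf <- file.path(pdir, sprintf("truth_%s.json", key))
      if (file.exists(tf)) {
        truth[[key]] <- jsonlite::read_json(tf, simplifyVector = TRUE)
      }
    }
    meta <- visits[[1]]$meta
    structure(list(patient_id = pid, side = meta$side %||% "right",
                   head_neck_length = meta$head_neck_length %||% NA_character_,
                   head_radius = meta$head_radius %||% 14,
                   box = box, visits = visits, ground_truth = truth),
              class = "patient_series")
  })
}

#' Write the migration / head-taper / comparison CSV outputs
#'
#' @param df a data.frame from [migration_table()], [headtaper_table()] or
#'   [interchangeability_analysis()].
#' @param path output CSV path.
#' @export
write_result_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
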