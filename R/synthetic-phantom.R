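# Ground-truth-paired synthetic RSA phantom: a cemented stem with three
# tantalum markers, a 28 mm ball head on a 5.611-degree taper, bone markers,
# a uniplanar two-focus scene with a two-plane calibration box, the standard
# long-term follow-up schedule, and programmed implant-to-bone migration and
# head-taper slip trajectories with i.i.d. Gaussian digitization noise.

DEFAULT_SCHEDULE <- c(0, 1.5, 3, 6, 12, 24, 60, 120)
# three-phase embedding pattern: slow to 6 months, fast 6-24 months, plateau
FIG5_FRACTIONS <- c(0, 0.05, 0.10, 0.20, 0.60, 0.90, 0.97, 1.0)

#' Default stem + head geometry in the stem's local frame
#'
#' Local frame: stem shaft along y (tip at the caudal end), +x medial for a
#' right hip. The neck/taper axis is inclined 54 degrees from the proximal
#' shaft direction (caput-collum-diaphyseal angle 126 degrees) and carries
#' the ball head; the stem body is modelled as a slightly conical wedge
#' (its axis line is the Fig-4 "cylinder" axis used for the virtual
#' markers). Units mm. Head-neck length moves the head centre along the
#' taper axis.
#'
#' @param head_neck_length `"S"`, `"M"` or `"L"`.
#' @return list with `implant_markers` (3 x 3), `stem_tip`, `head_center`,
#'   `taper` and `body` cone descriptions (apex / open direction /
#'   half-angle / visible `s_range`).
#' @export
stem_model <- function(head_neck_length = "M") {
  offset <- c(S = 2, M = 4, L = 6)[[head_neck_length]]
  ccd <- 126
  neck_dir <- c(sin(deg2rad(180 - ccd)), cos(deg2rad(180 - ccd)), 0)  # medial-cranial
  neck_base <- c(0, -45, 0)
  taper_apex <- neck_base + 55 * neck_dir
  list(
    implant_markers = rbind(c(15, -50, 6), c(-12, -75, -5), c(5, -110, 8)),
    stem_tip = c(0, -140, 0),
    head_center = taper_apex - offset * neck_dir,
    taper = list(apex = taper_apex, open_direction = -neck_dir,
                 half_angle = 5.611 / 2, s_range = c(20, 32)),
    body = list(apex = c(0, -190, 0), open_direction = c(0, 1, 0),
                half_angle = 2, s_range = c(60, 140))
  )
}

#' Phantom study configuration
#'
#' The stated world of the synthetic cohort. Geometry defaults follow the
#' uniplanar setup (140 cm film-focus distance, 40 degree beam intersection,
#' two-plane calibration box), the follow-up schedule is
#' \{0, 1.5, 3, 6, 12, 24, 60, 120\} months, the taper half-angle is
#' 5.611/2 degrees and the head radius 14 mm. The default total head-taper
#' slip of (0.10, -0.12, -0.21) mm reaches ~0.26 mm 3D magnitude at 10
#' years, i.e. ~0.026 mm/year.
#'
#' @param n_patients number of synthetic patients.
#' @param seed integer RNG seed; the generator is deterministic per
#'   (config, seed).
#' @param schedule follow-up months, starting at 0 (the reference exam).
#' @param scene a [scene_geometry()].
#' @param box a [calibration_box()].
#' @param head_radius ball-head radius, mm.
#' @param bone_markers n x 3 matrix of bone marker positions (global mm).
#' @param stem_pose rigid placement of the stem local frame in the global
#'   (calibration box) frame.
#' @param total_migration list with `translation` (mm) and `rotation_deg`
#'   totals for the implant-to-bone trajectory.
#' @param total_slip 3-vector, total head-taper slip in the taper frame
#'   (x medial, y along the taper axis, z anterior), mm.
#' @param migration_pattern,slip_pattern trajectory shapes, see
#'   [default_slip_trajectory()].
#' @param noise_sigma_2d SD of the i.i.d. Gaussian noise added to every
#'   digitized marker, landmark and silhouette coordinate, mm.
#' @param noise_sigma_box SD of the digitization noise on the
#'   calibration-box (fiducial/control) observations, mm. Box markers are
#'   high-contrast beads and digitize more precisely than implant contours;
#'   the default `min(0.01, noise_sigma_2d)` keeps the calibration-error and
#'   focus-error gates meaningful at contour noise up to 0.05 mm while a
#'   zero-noise world stays exactly noiseless.
#' @param repositioning_trans,repositioning_rot per-visit patient
#'   repositioning ranges (uniform, +-), mm and degrees.
#' @param marker_jitter_sd per-patient SD of marker placement jitter, mm.
#' @param amplitude_sdlog sdlog of the per-patient lognormal trajectory
#'   amplitude multiplier (meanlog = -sdlog^2/2 so the mean is 1).
#' @param head_neck_mix probabilities (or counts) for the S/M/L head-neck
#'   groups.
#' @param side `"right"` or `"left"`.
#' @param contour_points head silhouette points per view.
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(n_patients = 20,
                           seed = 1L,
                           schedule = DEFAULT_SCHEDULE,
                           scene = scene_geometry(),
                           box = calibration_box(),
                           head_radius = 14,
                           bone_markers = rbind(c(-35, 20, 150), c(30, -10, 185),
                                                c(-20, -60, 165), c(25, -90, 150),
                                                c(-30, -120, 180), c(10, 40, 160)),
                           stem_pose = rigid_transform(rotation_from_euler(3, 5, -8),
                                                       c(8, 30, 170)),
                           total_migration = list(translation = c(0.05, -0.15, 0.05),
                                                  rotation_deg = c(0.1, 0.2, -0.1)),
                           total_slip = c(0.10, -0.12, -0.21),
                           migration_pattern = "fig5_like",
                           slip_pattern = "fig5_like",
                           noise_sigma_2d = 0.05,
                           noise_sigma_box = min(0.01, noise_sigma_2d),
                           repositioning_trans = 10,
                           repositioning_rot = 1.5,
                           marker_jitter_sd = 1.0,
                           amplitude_sdlog = 0.3,
                           head_neck_mix = c(S = 1, M = 1, L = 1) / 3,
                           side = "right",
                           contour_points = 64) {
  stopifnot(schedule[1] == 0, !is.unsorted(schedule, strictly = TRUE),
            noise_sigma_2d >= 0, noise_sigma_box >= 0, n_patients >= 1,
            head_radius > 0)
  cfg <- structure(as.list(environment()), class = "phantom_config")
  cfg$bone_markers <- as_points3(bone_markers, "bone_markers")
  if (nrow(cfg$bone_markers) < 3L) stop("need at least 3 bone markers")
  cfg
}

#' Per-visit slip (or migration) trajectory
#'
#' `fig5_like` scales a total vector by the declared fraction table
#' \{0, .05, .10, .20, .60, .90, .97, 1\} anchored at the default schedule
#' (piecewise-linear interpolation in months for other schedules): slow
#' embedding to 6 months, the majority of the motion between 6 and 24
#' months, then a plateau. `linear` ramps uniformly; `zero` is the null
#' trajectory. Each component is monotone in magnitude by construction.
#'
#' @param total_slip 3-vector, total at the final visit (mm, taper frame).
#' @param pattern `"fig5_like"`, `"linear"` or `"zero"`.
#' @param schedule visit months (first must be 0).
#' @return matrix `length(schedule)` x 3, one slip vector per visit.
#' @export
default_slip_trajectory <- function(total_slip,
                                    pattern = c("fig5_like", "linear", "zero"),
                                    schedule = DEFAULT_SCHEDULE) {
  pattern <- match.arg(pattern)
  stopifnot(length(total_slip) == 3L, schedule[1] == 0)
  f <- switch(pattern,
    zero = rep(0, length(schedule)),
    linear = schedule / max(schedule),
    fig5_like = stats::approx(DEFAULT_SCHEDULE, FIG5_FRACTIONS,
                              xout = pmin(schedule, max(DEFAULT_SCHEDULE)),
                              rule = 2)$y)
  outer(f, as.numeric(total_slip))
}

#' Per-patient variation draws
#'
#' Samples, for each patient: a marker-placement jitter (i.i.d. Gaussian,
#' `marker_jitter_sd`), lognormal amplitude multipliers for the migration
#' and slip trajectories (mean 1), a head-neck length group from
#' `head_neck_mix`, and a per-patient RNG seed. Uses and advances the
#' current RNG state; call inside a `set.seed()` context for
#' reproducibility.
#'
#' @param config a [phantom_config()].
#' @return list of per-patient parameter lists.
#' @export
inject_patient_variation <- function(config) {
  n <- config$n_patients
  mix <- config$head_neck_mix / sum(config$head_neck_mix)
  sdlog <- config$amplitude_sdlog
  meanlog <- -sdlog^2 / 2
  groups <- sample(names(mix), n, replace = TRUE, prob = mix)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  lapply(seq_len(n), function(i) {
    list(patient_id = sprintf("P%03d", i),
         head_neck_length = groups[i],
         amp_migration = if (sdlog > 0) stats::rlnorm(1, meanlog, sdlog) else 1,
         amp_slip = if (sdlog > 0) stats::rlnorm(1, meanlog, sdlog) else 1,
         marker_jitter = matrix(stats::rnorm(9, 0, config$marker_jitter_sd), 3, 3),
         bone_jitter = matrix(stats::rnorm(3 * nrow(config$bone_markers), 0,
                                           config$marker_jitter_sd),
                              nrow(config$bone_markers), 3),
         seed = seeds[i])
  })
}

# uniform random small rigid transform (patient repositioning)
random_repositioning <- function(trans_range, rot_range) {
  rigid_transform(
    rotation_from_euler(stats::runif(1, -rot_range, rot_range),
                        stats::runif(1, -rot_range, rot_range),
                        stats::runif(1, -rot_range, rot_range)),
    stats::runif(3, -trans_range, trans_range))
}

add_noise <- function(x, sigma) {
  if (sigma <= 0) return(x)
  x + matrix(stats::rnorm(length(x), 0, sigma), nrow(x), ncol(x))
}

#' Generate one synthetic patient series
#'
#' Applies, per visit: the programmed implant-to-bone transform (about the
#' implant-marker centroid) to the stem and head, the head-taper slip (in
#' the reference taper frame, carried by the stem rotation) to the head
#' only, and a random patient repositioning to everything; then projects
#' every marker and silhouette through both foci and adds Gaussian 2D noise.
#'
#' @param config a [phantom_config()].
#' @param variation one element of [inject_patient_variation()]'s result.
#' @return a `patient_series`: `visits` (named list of `rsa_exam`),
#'   `ground_truth` (per visit: migration parameters, slip vector, stem
#'   transform), plus ids and the scene/box used.
#' @export
generate_patient <- function(config, variation) {
  set.seed(variation$seed)
  stem <- stem_model(variation$head_neck_length)
  stem$implant_markers <- stem$implant_markers + variation$marker_jitter
  bone <- config$bone_markers + variation$bone_jitter

  # place stem in the global frame
  g <- function(p) apply_transform(config$stem_pose, p)
  gd <- function(d) as.numeric(config$stem_pose$rotation %*% d)
  markers0 <- g(stem$implant_markers)
  tip0 <- g(stem$stem_tip)
  head0 <- g(stem$head_center)
  taper0 <- list(apex = as.numeric(g(stem$taper$apex)),
                 open = gd(stem$taper$open_direction),
                 half_angle = stem$taper$half_angle,
                 s_range = stem$taper$s_range)
  body0 <- list(apex = as.numeric(g(stem$body$apex)),
                open = gd(stem$body$open_direction),
                half_angle = stem$body$half_angle,
                s_range = stem$body$s_range)
  cone0 <- structure(list(axis_point = taper0$apex, axis_direction = -taper0$open,
                          half_angle = taper0$half_angle), class = "cone_model")
  frame0 <- build_taper_frame(cone0, markers0, config$side)
  cm <- colMeans(markers0)

  mig <- default_slip_trajectory(config$total_migration$translation,
                                 config$migration_pattern, config$schedule) *
    variation$amp_migration
  rot <- default_slip_trajectory(config$total_migration$rotation_deg,
                                 config$migration_pattern, config$schedule) *
    variation$amp_migration
  slip <- default_slip_trajectory(config$total_slip, config$slip_pattern,
                                  config$schedule) * variation$amp_slip

  visits <- list(); truth <- list()
  for (v in seq_along(config$schedule)) {
    months <- config$schedule[v]
    Rm <- rotation_from_euler(rot[v, 1], rot[v, 2], rot[v, 3])
    mig_t <- function(p) {
      p <- as_points3(p)
      sweep(sweep(p, 2, cm) %*% t(Rm), 2, cm + mig[v, ], `+`)
    }
    markers_v <- mig_t(markers0)
    tip_v <- as.numeric(mig_t(tip0))
    head_v <- as.numeric(mig_t(head0)) +
      as.numeric(Rm %*% (frame0$basis %*% slip[v, ]))
    cones_v <- lapply(list(taper0, body0), function(cn) {
      list(apex = as.numeric(mig_t(cn$apex)), open = as.numeric(Rm %*% cn$open),
           half_angle = cn$half_angle, s_range = cn$s_range)
    })

    # the reference exam defines the global frame; repositioning applies to
    # the follow-ups only
    pose <- if (months == 0) rigid_transform() else
      random_repositioning(config$repositioning_trans, config$repositioning_rot)
    lab <- function(p) apply_transform(pose, p)
    bone_l <- lab(bone); markers_l <- lab(markers_v)
    tip_l <- as.numeric(lab(tip_v)); head_l <- as.numeric(lab(head_v))
    cones_l <- lapply(cones_v, function(cn) {
      list(apex = as.numeric(lab(cn$apex)),
           open = as.numeric(pose$rotation %*% cn$open),
           half_angle = cn$half_angle, s_range = cn$s_range)
    })

    views <- lapply(1:2, function(k) {
      f <- config$scene$foci[k, ]
      sil <- lapply(cones_l, function(cn) {
        cone_silhouette(f, cn$apex, cn$open, cn$half_angle, cn$s_range)
      })
      s <- config$noise_sigma_2d
      sb <- config$noise_sigma_box
      list(
        fiducials = add_noise(config$box$fiducials[, 1:2, drop = FALSE], sb),
        controls = add_noise(project_from_focus(f, config$box$controls), sb),
        markers = list(
          bone = add_noise(project_from_focus(f, bone_l), s),
          implant = add_noise(project_from_focus(f, markers_l), s),
          tip = add_noise(project_from_focus(f, tip_l), s)),
        head_contour = add_noise(
          sphere_silhouette(f, head_l, config$head_radius, config$contour_points), s),
        taper_silhouette = lapply(sil[[1]], add_noise, sigma = s),
        stem_silhouette = lapply(sil[[2]], add_noise, sigma = s))
    })
    key <- format(months)
    visits[[key]] <- structure(
      list(views = views,
           meta = list(patient_id = variation$patient_id, visit_months = months,
                       side = config$side,
                       head_neck_length = variation$head_neck_length,
                       head_radius = config$head_radius)),
      class = "rsa_exam")
    truth[[key]] <- list(
      visit_months = months,
      migration = c(Tx = mig[v, 1], Ty = mig[v, 2], Tz = mig[v, 3],
                    Rx = rot[v, 1], Ry = rot[v, 2], Rz = rot[v, 3]),
      slip = c(x = slip[v, 1], y = slip[v, 2], z = slip[v, 3]),
      stem_markers = markers_l, head_center = head_l,
      repositioning = pose)
  }
  structure(list(patient_id = variation$patient_id,
                 side = config$side,
                 head_neck_length = variation$head_neck_length,
                 head_radius = config$head_radius,
                 box = config$box,
                 visits = visits,
                 ground_truth = truth),
            class = "patient_series")
}

#' Generate a synthetic phantom study
#'
#' Deterministic per (config, seed): draws per-patient variation, then
#' generates each patient from a dedicated seed stream.
#'
#' @param config a [phantom_config()].
#' @return object of class `phantom_study`: `config`, `patients` (list of
#'   `patient_series`).
#' @examples
#' st <- generate_study(phantom_config(n_patients = 2, noise_sigma_2d = 0))
#' names(st$patients[[1]]$visits)
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(config$seed)
  variations <- inject_patient_variation(config)
  patients <- lapply(variations, function(v) generate_patient(config, v))
  names(patients) <- vapply(patients, `[[`, character(1), "patient_id")
  structure(list(config = config, patients = patients), class = "phantom_study")
}
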