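# Uniplanar RSA imaging geometry: two X-ray foci above a film plane (z = 0),
# a two-plane calibration box, central projection, view calibration and
# stereo reconstruction. The global coordinate frame is the calibration-box
# frame: +x medial, +y cranial, +z anterior (right hip); left hips are
# mirrored in x at ingest.

#' Uniplanar RSA scene geometry
#'
#' Two X-ray sources ("foci") above the film plane `z = 0`, placed
#' symmetrically so that the central rays (focus to box centre at the origin)
#' intersect at `intersection_angle`. The film-focus distance is the
#' perpendicular distance from each focus to the film plane.
#'
#' @param film_focus_distance perpendicular focus height above the film, mm.
#'   Default 1400 mm.
#' @param intersection_angle angle between the two central rays, degrees.
#'   Default 40.
#' @return an object of class `scene_geometry` with elements `foci`
#'   (2 x 3 matrix, one focus per row), `film_focus_distance` and
#'   `intersection_angle`.
#' @examples
#' sc <- scene_geometry()
#' sc$foci
#' @export
scene_geometry <- function(film_focus_distance = 1400, intersection_angle = 40) {
  stopifnot(film_focus_distance > 0, intersection_angle > 0, intersection_angle < 180)
  half <- deg2rad(intersection_angle / 2)
  x <- film_focus_distance * tan(half)
  foci <- rbind(c(x, 0, film_focus_distance),
                c(-x, 0, film_focus_distance))
  obj <- structure(list(foci = foci,
                        film_focus_distance = film_focus_distance,
                        intersection_angle = intersection_angle),
                   class = "scene_geometry")
  # invariant: central rays meet at the requested angle
  r1 <- unitize(-foci[1, ]); r2 <- unitize(-foci[2, ])
  ang <- rad2deg(acos(min(1, max(-1, sum(r1 * r2)))))
  stopifnot(abs(ang - intersection_angle) < 1e-9)
  obj
}

#' Two-plane calibration box model
#'
#' A calibration box carries fiducial markers in the film plane (`z = 0`) and
#' control markers in an elevated plane (`z = control_height`). Fiducials
#' define the planar film mapping; control markers define rays that recover
#' the focus position. The true layout of commercial boxes is proprietary;
#' any non-degenerate two-plane layout satisfies the mathematics, and the
#' default is a 3 x 3 grid in each plane.
#'
#' @param fiducial_pitch grid spacing of the fiducial plane, mm.
#' @param control_pitch grid spacing of the control plane, mm.
#' @param control_height height of the control plane above the film, mm.
#' @param n_grid points per grid side (`n_grid^2` markers per plane).
#' @return object of class `calibration_box` with `fiducials` and `controls`
#'   (n x 3 matrices) and `control_height`.
#' @export
calibration_box <- function(fiducial_pitch = 60, control_pitch = 55,
                            control_height = 200, n_grid = 3) {
  stopifnot(n_grid >= 2, control_height > 0)
  g <- function(pitch, z) {
    s <- (seq_len(n_grid) - (n_grid + 1) / 2) * pitch
    xy <- as.matrix(expand.grid(x = s, y = s))
    cbind(xy, z = z)
  }
  fid <- g(fiducial_pitch, 0)
  ctl <- g(control_pitch, control_height)
  validate_box(structure(list(fiducials = fid, controls = ctl,
                              control_height = control_height),
                         class = "calibration_box"))
}

validate_box <- function(box) {
  fid <- as_points3(box$fiducials, "fiducials")
  ctl <- as_points3(box$controls, "controls")
  if (nrow(fid) < 4L || nrow(ctl) < 4L) {
    stop("calibration box needs at least 4 fiducial and 4 control markers")
  }
  if (any(abs(fid[, 3]) > 1e-9)) stop("fiducial markers must lie in the film plane z = 0")
  rank2 <- function(p) {
    s <- svd(scale(p[, 1:2], scale = FALSE))$d
    sum(s > 1e-9 * max(s, 1))
  }
  if (rank2(fid) < 2L || rank2(ctl) < 2L) stop("calibration markers must be non-collinear")
  box$fiducials <- fid
  box$controls <- ctl
  box
}

#' Central projection onto the film plane
#'
#' Projects 3D points through one of the scene's foci onto the film plane
#' `z = 0`. The focus, the object point and the (embedded) film point are
#' collinear.
#'
#' @param geometry a [scene_geometry()].
#' @param focus_index 1 or 2, selecting the focus.
#' @param point a 3-vector or n x 3 matrix of points (mm), strictly below the
#'   focus height.
#' @return an n x 2 matrix of film coordinates (mm); a single point yields a
#'   1 x 2 matrix.
#' @examples
#' sc <- scene_geometry()
#' project_point(sc, 1, c(0, 0, 0))  # film-plane points project to themselves
#' @export
project_point <- function(geometry, focus_index, point) {
  stopifnot(inherits(geometry, "scene_geometry"), focus_index %in% c(1L, 2L))
  project_from_focus(geometry$foci[focus_index, ], point)
}

# projection through an arbitrary focus position (used after calibration)
project_from_focus <- function(focus, point) {
  pts <- as_points3(point)
  dz <- focus[3] - pts[, 3]
  if (any(dz <= 0)) stop("degenerate projection: point at or above the focus height")
  t <- focus[3] / dz
  cbind(focus[1] + t * (pts[, 1] - focus[1]),
        focus[2] + t * (pts[, 2] - focus[2]))
}

#' Calibrate one X-ray view from calibration-box observations
#'
#' Fits the planar mapping from digitized 2D coordinates to film-plane mm
#' coordinates on the fiducial markers (least squares; affine by default,
#' projective optional), then recovers the focus position as the
#' least-squares intersection of the control rays (each ray joins a control
#' marker's known 3D position to its mapped film image). Correspondence is by
#' index and counts must match the box model.
#'
#' Quality metrics follow the RSA convention: `calibration_error` is the RMS
#' 2D residual of the fiducials after the film mapping, and `focus_error` is
#' the RMS perpendicular distance from the fitted focus to the control rays.
#'
#' @param box a [calibration_box()].
#' @param observed_fiducials n x 2 digitized fiducial coordinates.
#' @param observed_controls m x 2 digitized control coordinates.
#' @param model `"affine"` (6 dof, default — the film lies in the fiducial
#'   plane so an affinity suffices) or `"projective"` (8 dof homography).
#' @return object of class `view_calibration` with `film_transform` (3 x 3
#'   homogeneous matrix mapping digitized to film coordinates),
#'   `focus_position`, `calibration_error` and `focus_error` (mm).
#' @export
calibrate_view <- function(box, observed_fiducials, observed_controls,
                           model = c("affine", "projective")) {
  model <- match.arg(model)
  box <- validate_box(box)
  obs_f <- as_points2(observed_fiducials, "observed fiducials")
  obs_c <- as_points2(observed_controls, "observed controls")
  if (nrow(obs_f) != nrow(box$fiducials) || nrow(obs_c) != nrow(box$controls)) {
    stop("observation counts must match the calibration box model")
  }
  if (nrow(obs_f) < 4L || nrow(obs_c) < 4L) {
    stop("insufficient calibration: need at least 4 fiducials and 4 controls")
  }

  H <- fit_planar_map(obs_f, box$fiducials[, 1:2], model)
  mapped_f <- apply_planar_map(H, obs_f)
  cal_err <- sqrt(mean(rowSums((mapped_f - box$fiducials[, 1:2])^2)))

  mapped_c <- apply_planar_map(H, obs_c)
  origins <- cbind(mapped_c, 0)
  dirs <- box$controls - origins
  if (any(sqrt(rowSums(dirs^2)) < 1e-9)) {
    stop("ill-conditioned calibration: control ray of zero length")
  }
  sol <- tryCatch(
    least_squares_line_intersection(origins, dirs),
    error = function(e) stop("ill-conditioned calibration: ", conditionMessage(e))
  )
  focus <- sol$point
  d <- vapply(seq_len(nrow(origins)), function(i) {
    point_line_distance(focus, origins[i, ], unitize(dirs[i, ]))
  }, numeric(1))
  focus_err <- sqrt(mean(d^2))
  if (focus[3] < 1) {
    # a physical focus sits far above the film; a fit in or below the film
    # plane means the control rays carried no depth information
    stop("ill-conditioned calibration: recovered focus at or below the film plane")
  }

  structure(list(film_transform = H, focus_position = focus,
                 calibration_error = cal_err, focus_error = focus_err,
                 model = model),
            class = "view_calibration")
}

# least-squares 2D map from src to dst; affine (lm per coordinate) or
# projective (normalized DLT)
fit_planar_map <- function(src, dst, model) {
  if (model == "affine") {
    X <- cbind(1, src)
    beta <- qr.solve(X, dst)   # 3 x 2
    H <- rbind(cbind(t(beta[2:3, , drop = FALSE]), beta[1, ]), c(0, 0, 1))
    return(H)
  }
  # projective: direct linear transform with mean/scale normalization
  norm_t <- function(p) {
    mu <- colMeans(p)
    s <- sqrt(2) / mean(sqrt(rowSums(sweep(p, 2, mu)^2)))
    rbind(c(s, 0, -s * mu[1]), c(0, s, -s * mu[2]), c(0, 0, 1))
  }
  Ts <- norm_t(src); Td <- norm_t(dst)
  s <- apply_planar_map(Ts, src); d <- apply_planar_map(Td, dst)
  n <- nrow(s)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    x <- c(s[i, ], 1); u <- d[i, 1]; v <- d[i, 2]
    A[2 * i - 1, ] <- c(-x, 0, 0, 0, u * x)
    A[2 * i, ] <- c(0, 0, 0, -x, v * x)
  }
  h <- svd(A)$v[, 9]
  H <- matrix(h, 3, 3, byrow = TRUE)
  H <- solve(Td) %*% H %*% Ts
  H / H[3, 3]
}

apply_planar_map <- function(H, pts) {
  pts <- as_points2(pts)
  ph <- cbind(pts, 1) %*% t(H)
  ph[, 1:2, drop = FALSE] / ph[, 3]
}

#' Reconstruct a 3D point from a calibrated stereo pair
#'
#' Back-projects one film point per view through its focus and returns the
#' midpoint of the common perpendicular of the two rays, together with the
#' crossing distance (shortest distance between the rays) as a per-point
#' quality metric.
#'
#' @param cal1,cal2 [calibrate_view()] results for the two views.
#' @param image1,image2 2-vectors (or n x 2 matrices) of film-frame mm
#'   coordinates (already mapped).
#' @return for single points, a list with `position` (3-vector) and
#'   `crossing_distance` (mm); for matrices, a list with `positions` (n x 3)
#'   and `crossing_distances`.
#' @export
reconstruct_point <- function(cal1, cal2, image1, image2) {
  stopifnot(inherits(cal1, "view_calibration"), inherits(cal2, "view_calibration"))
  m1 <- as_points2(image1); m2 <- as_points2(image2)
  stopifnot(nrow(m1) == nrow(m2))
  n <- nrow(m1)
  pos <- matrix(NA_real_, n, 3)
  cd <- numeric(n)
  for (i in seq_len(n)) {
    r <- triangulate_rays(cal1$focus_position, c(m1[i, ], 0),
                          cal2$focus_position, c(m2[i, ], 0))
    pos[i, ] <- r$position
    cd[i] <- r$crossing_distance
  }
  if (n == 1L && is.null(dim(image1))) {
    list(position = pos[1, ], crossing_distance = cd[1])
  } else {
    list(positions = pos, crossing_distances = cd)
  }
}

# midpoint of the common perpendicular of rays (o1 -> p1) and (o2 -> p2)
triangulate_rays <- function(o1, p1, o2, p2) {
  d1 <- unitize(p1 - o1); d2 <- unitize(p2 - o2)
  w <- o1 - o2
  a <- 1; b <- sum(d1 * d2); c2 <- 1
  d <- sum(d1 * w); e <- sum(d2 * w)
  den <- a * c2 - b * b
  if (den < 1e-14) stop("no intersection: rays are (near) parallel")
  s <- (b * e - c2 * d) / den
  t <- (a * e - b * d) / den
  q1 <- o1 + s * d1
  q2 <- o2 + t * d2
  list(position = (q1 + q2) / 2, crossing_distance = vnorm(q1 - q2))
}
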