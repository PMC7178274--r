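# Rigid-body migration kinematics: SVD point registration, RSA quality
# numbers (condition number, rigid-body error), Euler decomposition and
# reference-point handling.

#' Construct a rigid transform
#'
#' @param rotation 3x3 proper orthogonal matrix.
#' @param translation 3-vector, mm.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9) {
    stop("rotation must be proper orthogonal (R'R = I, det = +1)")
  }
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#' @param transform a [rigid_transform()].
#' @param points 3-vector or n x 3 matrix.
#' @return transformed points, same shape convention as [as_points3] output.
#' @export
apply_transform <- function(transform, points) {
  p <- as_points3(points)
  out <- p %*% t(transform$rotation) +
    matrix(transform$translation, nrow(p), 3, byrow = TRUE)
  if (is.null(dim(points))) out[1, ] else out
}

#' Invert a rigid transform
#' @param transform a [rigid_transform()].
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% transform$translation))
}

#' Least-squares rigid-body registration (SVD)
#'
#' Finds the rotation and translation mapping `ref_points` onto `fu_points`
#' in the least-squares sense via the SVD of the cross-covariance of the
#' centred point sets (Kabsch/Arun). Reflections are corrected by flipping
#' the sign of the last singular vector so that `det(R) = +1`. The
#' `rigid_body_error` is the RMS residual after the fitted transform; large
#' values signal marker instability (or, in the EGS pipeline, head-taper
#' slip).
#'
#' @param ref_points,fu_points matched n x 3 matrices, n >= 3, non-collinear.
#' @return list with `transform` (a [rigid_transform()]) and
#'   `rigid_body_error` (mm).
#' @export
fit_rigid_body <- function(ref_points, fu_points) {
  P <- as_points3(ref_points, "ref_points")
  Q <- as_points3(fu_points, "fu_points")
  if (nrow(P) != nrow(Q)) stop("point sets must have matching sizes")
  if (nrow(P) < 3L) stop("need at least 3 matched points")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  s <- svd(Pc)$d
  if (s[2] < 1e-9 * max(s[1], 1)) stop("degenerate configuration: points are collinear")
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  D <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% D %*% t(sv$u)
  t <- cq - as.numeric(R %*% cp)
  tr <- rigid_transform(R, t)
  res <- apply_transform(tr, P) - Q
  list(transform = tr, rigid_body_error = sqrt(mean(rowSums(res^2))))
}

#' RSA condition number of a marker configuration
#'
#' `CN = 100 / sigma_2`, where `sigma_2` is the middle singular value (mm) of
#' the centroid-centred configuration matrix. Collinear marker sets leave the
#' rotation about the line unobservable and return `Inf` (failing the usual
#' `CN <= 100` gate); scaling the marker cloud by a factor k divides CN by k.
#'
#' @param points n x 3 marker positions, n >= 3.
#' @return dimensionless scalar.
#' @export
condition_number <- function(points) {
  P <- as_points3(points)
  if (nrow(P) < 3L) stop("need at least 3 points")
  s <- svd(sweep(P, 2, colMeans(P)))$d
  if (s[2] <= 0) return(Inf)
  100 / s[2]
}

#' Euler angles of a rigid transform (z-y-x convention)
#'
#' Decomposes `R = Rz(Rz.) %*% Ry(Ry.) %*% Rx(Rx.)` — the x rotation applied
#' first — and returns degrees about the medial-lateral (Rx), cranial-caudal
#' (Ry) and anterior-posterior (Rz) axes. Configurations adjacent to gimbal
#' lock (`|Ry| -> 90` degrees) are flagged via the `"gimbal"` attribute, not
#' errored.
#'
#' @param transform a [rigid_transform()] (or a bare 3x3 rotation matrix).
#' @return named numeric vector `c(Rx, Ry, Rz)` in degrees, with attribute
#'   `gimbal` (logical).
#' @export
euler_angles <- function(transform) {
  R <- if (inherits(transform, "rigid_transform")) transform$rotation else as.matrix(transform)
  sy <- -R[3, 1]
  sy <- min(1, max(-1, sy))
  ry <- asin(sy)
  gimbal <- abs(abs(sy) - 1) < 1e-9
  if (gimbal) {
    # Ry = +-90: only rx + rz (or rx - rz) observable; put it all in Rx
    rx <- atan2(-R[2, 3], R[2, 2])
    rz <- 0
  } else {
    rx <- atan2(R[3, 2], R[3, 3])
    rz <- atan2(R[2, 1], R[1, 1])
  }
  out <- c(Rx = rad2deg(rx), Ry = rad2deg(ry), Rz = rad2deg(rz))
  attr(out, "gimbal") <- gimbal
  out
}

#' Migration of a reference point under a rigid transform
#'
#' The translation reported by RSA is the displacement of a chosen reference
#' point (usually the marker centroid): `d(p) = R p + t - p`. Under rotation
#' this depends on the point, which is why reference-point correction exists.
#'
#' @param transform a [rigid_transform()].
#' @param point reference point, 3-vector mm.
#' @return displacement 3-vector, mm.
#' @export
migration_of_point <- function(transform, point) {
  stopifnot(length(point) == 3L)
  as.numeric(transform$rotation %*% point + transform$translation - point)
}

#' Hurschler reference-point correction
#'
#' Re-expresses a translational migration result at a new reference point:
#' `d(new) = d(old) + (R - I)(new - old)`. Used to move the EGS pipeline's
#' virtual-marker reference point onto the tantalum-marker centroid so that
#' marker-based and model-based translations are comparable. The supplied
#' `migration_at_old` must be consistent with the transform at `old_point`
#' (checked to 1e-6 mm).
#'
#' @param transform the rigid transform the migration came from.
#' @param migration_at_old 3-vector, migration measured at `old_point`.
#' @param old_point,new_point reference points, mm.
#' @return migration 3-vector at `new_point`; identical to
#'   `migration_of_point(transform, new_point)`.
#' @export
correct_reference_point <- function(transform, migration_at_old, old_point, new_point) {
  check <- migration_of_point(transform, old_point)
  if (max(abs(check - migration_at_old)) > 1e-6) {
    stop("inconsistent inputs: migration_at_old does not match the transform at old_point")
  }
  as.numeric(migration_at_old +
               (transform$rotation - diag(3)) %*% (new_point - old_point))
}
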