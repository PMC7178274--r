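# Small 3D vector helpers shared across modules. All lengths in mm,
# all angles in degrees at the API surface (radians internally).

vnorm <- function(v) sqrt(sum(v * v))

unitize <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps^0.5) stop("cannot normalize a (near) zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

#' Rotation matrix from Euler angles (z-y-x convention)
#'
#' Builds `R = Rz %*% Ry %*% Rx`, the convention used throughout the package:
#' the x rotation is applied first, then y, then z. Angles are in degrees,
#' about the global medial-lateral (x), cranial-caudal (y) and
#' anterior-posterior (z) axes.
#'
#' @param rx,ry,rz rotation angles in degrees.
#' @return a 3x3 proper orthogonal matrix.
#' @seealso [euler_angles()] for the inverse decomposition.
#' @export
rotation_from_euler <- function(rx, ry, rz) {
  a <- deg2rad(rx); b <- deg2rad(ry); g <- deg2rad(rz)
  Rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  Rz <- rbind(c(cos(g), -sin(g), 0), c(sin(g), cos(g), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

# coerce an n x 3 (or length-3) input to a matrix with one point per row
as_points3 <- function(x, what = "points") {
  if (is.null(dim(x))) {
    if (length(x) != 3L) stop(sprintf("%s must be a 3-vector or an n x 3 matrix", what))
    x <- matrix(x, nrow = 1L)
  }
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop(sprintf("%s must have 3 columns", what))
  storage.mode(x) <- "double"
  x
}

as_points2 <- function(x, what = "points") {
  if (is.null(dim(x))) {
    if (length(x) != 2L) stop(sprintf("%s must be a 2-vector or an n x 2 matrix", what))
    x <- matrix(x, nrow = 1L)
  }
  x <- as.matrix(x)
  if (ncol(x) != 2L) stop(sprintf("%s must have 2 columns", what))
  storage.mode(x) <- "double"
  x
}

# perpendicular distance from point p to the line through o with unit direction d
point_line_distance <- function(p, o, d) {
  w <- p - o
  vnorm(w - sum(w * d) * d)
}

# least-squares point closest to a set of lines (origins o_i, unit directions d_i).
# Solves sum_i (I - d_i d_i^T) x = sum_i (I - d_i d_i^T) o_i.
least_squares_line_intersection <- function(origins, directions, rcond_min = 1e-10) {
  origins <- as_points3(origins); directions <- as_points3(directions)
  A <- matrix(0, 3, 3); b <- numeric(3)
  for (i in seq_len(nrow(origins))) {
    d <- unitize(directions[i, ])
    P <- diag(3) - tcrossprod(d)
    A <- A + P
    b <- b + P %*% origins[i, ]
  }
  if (rcond(A) < rcond_min) {
    stop("ill-conditioned line intersection: directions are (near) parallel or degenerate")
  }
  list(point = as.numeric(solve(A, b)),
       rms = NA_real_, A = A)
}
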