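# Elementary-geometrical-shape (EGS) pose recovery from silhouette
# observations: sphere centre (femoral ball head) from contour points, cone
# axis (stem taper) from silhouette lines, the virtual-marker construction
# and the taper coordinate frame.

#' Forward silhouette of a sphere
#'
#' Film-plane contour points of a sphere of known radius seen from a focus:
#' the tangency circle on the sphere is computed in closed form and projected
#' centrally onto the film `z = 0`. Used by the phantom generator and as the
#' independent forward oracle for [fit_sphere_center()].
#'
#' @param focus 3-vector focus position (mm).
#' @param center sphere centre (mm).
#' @param radius sphere radius (mm).
#' @param n number of contour points.
#' @param arc arc extent in degrees (360 = full outline; partial arcs model
#'   heads partly hidden by the cup).
#' @return n x 2 matrix of film coordinates.
#' @export
sphere_silhouette <- function(focus, center, radius, n = 64, arc = 360) {
  d <- center - focus
  D <- vnorm(d)
  if (D <= radius) stop("focus lies inside the sphere")
  dh <- d / D
  sina <- radius / D
  cosa <- sqrt(1 - sina^2)
  q <- focus + (D * cosa^2) * dh          # tangency-circle centre
  rho <- D * cosa * sina                  # tangency-circle radius
  e1 <- unitize(cross3(dh, if (abs(dh[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)))
  e2 <- cross3(dh, e1)
  phi <- seq(0, deg2rad(arc), length.out = n + 1L)[seq_len(n)]
  pts <- t(vapply(phi, function(p) q + rho * (cos(p) * e1 + sin(p) * e2), numeric(3)))
  project_from_focus(focus, pts)
}

#' Forward silhouette of a cone
#'
#' The two silhouette lines of a cone seen from a focus. Each tangent plane
#' of a cone passes through the apex; the two planes that also contain the
#' focus touch the cone along two rulings, whose central projections are the
#' silhouette lines. Returns one 2 x 2 matrix of film coordinates (segment
#' endpoints at arc lengths `s_range` from the apex) per silhouette line.
#'
#' @param focus 3-vector focus position (mm).
#' @param apex cone apex (mm).
#' @param open_direction unit vector from the apex into the cone (toward the
#'   base).
#' @param half_angle cone half-opening angle, degrees.
#' @param s_range distances from the apex (mm) bounding the projected
#'   segment.
#' @return list of two 2 x 2 matrices (rows = segment endpoints).
#' @export
cone_silhouette <- function(focus, apex, open_direction, half_angle,
                            s_range = c(18, 30)) {
  a <- unitize(open_direction)
  th <- deg2rad(half_angle)
  stopifnot(th > 0, th < pi / 2, length(s_range) == 2L)
  v <- focus - apex
  e1 <- unitize(cross3(a, if (abs(a[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)))
  e2 <- cross3(a, e1)
  A <- sum(e1 * v); B <- sum(e2 * v)
  Rm <- sqrt(A^2 + B^2); psi <- atan2(B, A)
  C <- tan(th) * sum(a * v)
  if (Rm < 1e-12 || abs(C / Rm) >= 1) {
    stop("degenerate view: focus lies inside (or on the axis of) the cone")
  }
  dphi <- acos(C / Rm)
  lapply(c(psi + dphi, psi - dphi), function(phi) {
    u <- cos(th) * a + sin(th) * (cos(phi) * e1 + sin(phi) * e2)
    project_from_focus(focus, rbind(apex + s_range[1] * u, apex + s_range[2] * u))
  })
}

# perpendicular distance from point to each back-projected film ray
ray_distances <- function(center, focus, film_pts) {
  film_pts <- as_points2(film_pts)
  vapply(seq_len(nrow(film_pts)), function(i) {
    point_line_distance(center, focus, unitize(c(film_pts[i, ], 0) - focus))
  }, numeric(1))
}

#' Fit a sphere centre from silhouette contours
#'
#' Recovers the centre of a sphere of known radius from digitized silhouette
#' contour points in one or two calibrated views. Each contour point
#' back-projects to a ray that is tangent to the sphere, so the centre is
#' found by least squares on the tangency residuals (distance from centre to
#' ray, minus the radius). With a single view the depth is fixed by the known
#' radius through the aperture of the viewing cone. Initialization places the
#' centre on the axis of the silhouette viewing cone at distance
#' `radius / sin(half-aperture)` from the focus.
#'
#' @param cals a `view_calibration` or list of 1-2 of them.
#' @param contours matching list of n x 2 film-coordinate contour matrices
#'   (views with fewer than 8 points are dropped; at least one view must
#'   survive).
#' @param radius known sphere radius, mm (14 for a 28 mm head).
#' @return list with `center` (3-vector), `rms_residual` (mm) and
#'   `n_points`.
#' @export
fit_sphere_center <- function(cals, contours, radius) {
  stopifnot(radius > 0)
  if (inherits(cals, "view_calibration")) cals <- list(cals)
  if (is.matrix(contours) || (is.numeric(contours) && is.null(dim(contours)))) {
    contours <- list(contours)
  }
  stopifnot(length(cals) == length(contours), length(cals) >= 1L)
  keep <- vapply(contours, function(ct) nrow(as_points2(ct)) >= 8L, logical(1))
  if (!any(keep)) stop("insufficient contour: need at least 8 silhouette points in some view")
  cals <- cals[keep]; contours <- contours[keep]
  foci <- lapply(cals, `[[`, "focus_position")

  init_one <- function(focus, ct) {
    ct <- as_points2(ct)
    dirs <- t(apply(ct, 1, function(m) unitize(c(m, 0) - focus)))
    dm <- unitize(colMeans(dirs))
    ca <- pmin(1, dirs %*% dm)
    alpha <- mean(acos(ca))
    if (alpha < 1e-9) stop("degenerate contour: zero angular extent")
    focus + dm * (radius / sin(alpha))
  }
  inits <- mapply(init_one, foci, contours, SIMPLIFY = FALSE)
  c0 <- Reduce(`+`, inits) / length(inits)

  obj <- function(c3) {
    s <- 0
    for (v in seq_along(cals)) {
      r <- ray_distances(c3, foci[[v]], contours[[v]]) - radius
      s <- s + sum(r^2)
    }
    s
  }
  n_pts <- sum(vapply(contours, nrow, integer(1)))
  fit <- stats::optim(c0, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  if (fit$convergence != 0) {
    # BFGS can exhaust maxit dithering at machine precision; accept when the
    # solution is at numerical zero or a restart no longer improves it
    fit2 <- stats::optim(fit$par, obj, method = "BFGS",
                         control = list(maxit = 500, reltol = 1e-12))
    at_zero <- fit2$value <= n_pts * 1e-12          # RMS residual < 1e-6 mm
    stalled <- fit$value - fit2$value <= 1e-6 * fit$value
    if (fit2$convergence != 0 && !at_zero && !stalled) {
      stop("sphere fit did not converge (code ", fit2$convergence, ", value ",
           format(fit2$value), ")")
    }
    fit <- fit2
  }
  list(center = as.numeric(fit$par),
       rms_residual = sqrt(fit$value / n_pts),
       n_points = n_pts)
}

#' Fit a cone (taper) axis from silhouette lines
#'
#' Each observed silhouette line, together with its view's focus, spans a
#' plane tangent to the cone; every tangent plane of a cone contains the
#' apex. The apex is recovered as the least-squares intersection of the
#' tangent planes, and the axis direction and half-angle minimize the squared
#' angular residuals `asin(|n_i . a|) - theta` over the (up to four) tangent
#' planes. The returned `axis_direction` points from the apex into the cone
#' (toward the base).
#'
#' @param cals list of two `view_calibration` objects.
#' @param silhouette_lines per view, a list of two 2 x 2 matrices of film
#'   coordinates (segment endpoints) — the format written by the phantom
#'   generator.
#' @return object of class `cone_model`: `axis_point` (apex, mm),
#'   `axis_direction` (unit), `half_angle` (degrees), `angular_rms`
#'   (residual, degrees).
#' @export
fit_cone_axis <- function(cals, silhouette_lines) {
  stopifnot(length(cals) == 2L, length(silhouette_lines) == 2L)
  planes <- list()
  for (v in 1:2) {
    f <- cals[[v]]$focus_position
    segs <- silhouette_lines[[v]]
    stopifnot(length(segs) == 2L)
    mids <- lapply(segs, function(s) c(colMeans(as_points2(s)), 0))
    for (k in 1:2) {
      s <- as_points2(segs[[k]])
      n <- cross3(c(s[1, ], 0) - f, c(s[2, ], 0) - f)
      if (vnorm(n) < 1e-9) stop("degenerate silhouette line (zero length)")
      n <- unitize(n)
      # orient outward: the other silhouette line of the view lies on the
      # cone-interior (negative) side
      if (sum(n * (mids[[3 - k]] - f)) > 0) n <- -n
      planes[[length(planes) + 1L]] <- list(n = n, f = f, mid = mids[[k]])
    }
  }
  N <- t(vapply(planes, `[[`, numeric(3), "n"))
  b <- vapply(planes, function(p) sum(p$n * p$f), numeric(1))
  sv <- svd(N)
  if (sv$d[3] < 1e-6 * sv$d[1]) {
    stop("degenerate view: tangent planes are near-parallel (taper seen end-on)")
  }
  apex <- as.numeric(qr.solve(N, b))

  # initial axis: it is orthogonal to the difference of each view's outward
  # normals (n1 . a = n2 . a = -sin(theta)), so a ~ (n1-n2) x (n3-n4)
  d12 <- planes[[1]]$n - planes[[2]]$n
  d34 <- planes[[3]]$n - planes[[4]]$n
  a0 <- cross3(d12, d34)
  if (vnorm(a0) < 1e-9) stop("degenerate view: cannot resolve the cone axis direction")
  a0 <- unitize(a0)
  # sign: the axis opens toward the observed silhouette segments
  towards <- unitize(Reduce(`+`, lapply(planes, `[[`, "mid")) / 4 - apex)
  if (sum(a0 * towards) < 0) a0 <- -a0

  ang <- function(a) asin(pmin(1, pmax(-1, -(N %*% a))))
  # minimize spread of per-plane half-angle estimates over the unit sphere,
  # parametrized as a perturbation of a0
  e1 <- unitize(cross3(a0, if (abs(a0[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)))
  e2 <- cross3(a0, e1)
  obj <- function(p) {
    a <- unitize(a0 + p[1] * e1 + p[2] * e2)
    th <- ang(a)
    sum((th - mean(th))^2)
  }
  fit <- stats::optim(c(0, 0), obj, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-15))
  a <- unitize(a0 + fit$par[1] * e1 + fit$par[2] * e2)
  th <- ang(a)
  if (mean(th) <= 0) stop("cone fit failed: non-positive half-angle")
  structure(list(axis_point = apex, axis_direction = a,
                 half_angle = rad2deg(mean(th)),
                 angular_rms = rad2deg(sqrt(mean((th - mean(th))^2)))),
            class = "cone_model")
}

#' Construct the EGS virtual marker set
#'
#' Three constructed points stand in for physical markers in the EGS stem
#' pipeline: `P1` the ball-head centre, `P2` the lowest point of the stem
#' tip, and `P3` the orthogonal projection of `P1` onto the stem (cylinder)
#' axis line. The reference point is their centroid. If the head centre lies
#' on the axis the set is collinear and flagged (`degenerate = TRUE`).
#'
#' @param head_center 3-vector `P1`.
#' @param axis_point,axis_direction a point on the cylinder/taper axis line
#'   and its (unit) direction.
#' @param stem_tip 3-vector `P2`.
#' @return list with `P1`, `P2`, `P3`, `reference_point`, `degenerate`.
#' @export
construct_virtual_markers <- function(head_center, axis_point, axis_direction, stem_tip) {
  d <- unitize(axis_direction)
  P1 <- as.numeric(head_center); P2 <- as.numeric(stem_tip)
  P3 <- as.numeric(axis_point) + sum((P1 - axis_point) * d) * d
  list(P1 = P1, P2 = P2, P3 = P3,
       reference_point = (P1 + P2 + P3) / 3,
       degenerate = vnorm(P1 - P3) < 1e-9)
}

#' Build the taper coordinate frame
#'
#' Orthonormal right-handed frame for reporting head-taper migration: `Y`
#' along the taper (cone) axis signed to point cranially (+global y), `X`
#' orthogonal to `Y`, parallel to the plane through the three implant
#' markers and signed to point medially (+global x for a right hip, -x for a
#' left hip), `Z = X x Y` (anterior for anatomically sensible geometry).
#'
#' @param cone a [fit_cone_axis()] result (or any list with `axis_point` and
#'   `axis_direction`).
#' @param implant_markers 3 x 3 matrix of implant tantalum marker positions.
#' @param side `"right"` or `"left"` hip.
#' @return object of class `taper_frame` with `origin`, unit vectors `X`,
#'   `Y`, `Z`, and `basis` (3 x 3 matrix with X, Y, Z as columns).
#' @export
build_taper_frame <- function(cone, implant_markers, side = c("right", "left")) {
  side <- match.arg(side)
  M <- as_points3(implant_markers, "implant_markers")
  if (nrow(M) < 3L) stop("need 3 implant markers")
  Y <- unitize(cone$axis_direction)
  if (Y[2] < 0) Y <- -Y                       # cranial
  Mc <- sweep(M, 2, colMeans(M))
  n <- svd(Mc)$v[, 3]                         # marker-plane normal
  Xr <- cross3(n, Y)
  if (vnorm(Xr) < 1e-9) stop("frame degeneracy: taper axis parallel to the marker-plane normal")
  X <- unitize(Xr)
  medial <- if (side == "right") c(1, 0, 0) else c(-1, 0, 0)
  if (sum(X * medial) < 0) X <- -X
  Z <- cross3(X, Y)
  structure(list(origin = as.numeric(cone$axis_point), X = X, Y = Y, Z = Z,
                 basis = cbind(X, Y, Z), side = side),
            class = "taper_frame")
}

#' Express a vector in a taper frame
#'
#' Components `(v . X, v . Y, v . Z)`; an isometry, so the norm is
#' preserved. The inverse operation is [vector_from_frame()].
#'
#' @param frame a [build_taper_frame()] result.
#' @param v 3-vector in global coordinates.
#' @return named components `c(x, y, z)`, mm.
#' @export
vector_in_frame <- function(frame, v) {
  out <- as.numeric(crossprod(frame$basis, v))
  names(out) <- c("x", "y", "z")
  out
}

#' Reconstruct a global vector from taper-frame components
#' @param frame a [build_taper_frame()] result.
#' @param comps components as returned by [vector_in_frame()].
#' @export
vector_from_frame <- function(frame, comps) {
  as.numeric(frame$basis %*% as.numeric(comps))
}
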