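# Sphere and cone pose recovery from silhouettes, virtual markers and the
# taper frame. The forward projectors (sphere_silhouette / cone_silhouette)
# are the closed-form oracles the fitters are checked against.

cal_pair <- noiseless_cal_pair

test_that("sphere centre is recovered from noiseless two-view silhouettes", {
  C <- c(20, -15, 180)
  ct <- lapply(1:2, function(k) sphere_silhouette(default_scene$foci[k, ], C, 14, 64))
  fit <- fit_sphere_center(cal_pair, ct, 14)
  expect_vector_equal(fit$center, C, 1e-3)
  expect_lt(fit$rms_residual, 1e-6)
})

test_that("single-view sphere fit fixes depth through the known radius", {
  C <- c(-10, 25, 210)
  ct <- sphere_silhouette(default_scene$foci[1, ], C, 14, 64)
  fit <- fit_sphere_center(cal_pair[[1]], ct, 14)
  expect_vector_equal(fit$center, C, 1e-2)
})

test_that("sphere fit under contour noise keeps sub-0.1 mm median error", {
  set.seed(31)
  C <- c(5, 10, 190)
  errs <- replicate(30, {
    ct <- lapply(1:2, function(k) {
      s <- sphere_silhouette(default_scene$foci[k, ], C, 14, 64)
      s + rnorm(length(s), 0, 0.05)
    })
    sqrt(sum((fit_sphere_center(cal_pair, ct, 14)$center - C)^2))
  })
  expect_lt(median(errs), 0.1)
})

test_that("sphere fit input validation", {
  ct <- sphere_silhouette(default_scene$foci[1, ], c(0, 0, 180), 14, 7)
  expect_error(fit_sphere_center(cal_pair[[1]], ct, 14), "insufficient contour")
})

test_that("cone axis and half-angle are recovered at zero noise", {
  apex <- c(40, 15, 185)
  open <- c(0.4, -0.9, 0.15) / sqrt(sum(c(0.4, -0.9, 0.15)^2))
  sil <- lapply(1:2, function(k) {
    cone_silhouette(default_scene$foci[k, ], apex, open, 2.8055, c(20, 32))
  })
  fit <- fit_cone_axis(cal_pair, sil)
  expect_vector_equal(fit$axis_point, apex, 1e-6)
  dir_err <- acos(min(1, abs(sum(fit$axis_direction * open)))) * 180 / pi
  expect_lt(dir_err, 0.01)
  expect_equal(fit$half_angle, 2.8055, tolerance = 0.005)
})

test_that("axis-aligned cone recovers a y-axis direction", {
  apex <- c(0, 40, 170)
  sil <- lapply(1:2, function(k) {
    cone_silhouette(default_scene$foci[k, ], apex, c(0, -1, 0), 2.8055, c(20, 32))
  })
  fit <- fit_cone_axis(cal_pair, sil)
  expect_vector_equal(abs(fit$axis_direction), c(0, 1, 0), 1e-6)
})

test_that("cone direction error stays below 0.5 degrees at 0.05 mm noise", {
  set.seed(41)
  apex <- c(30, 20, 180)
  open <- c(0.5, -0.85, 0.1) / sqrt(sum(c(0.5, -0.85, 0.1)^2))
  errs <- replicate(30, {
    sil <- lapply(1:2, function(k) {
      lapply(cone_silhouette(default_scene$foci[k, ], apex, open, 2.8055, c(20, 32)),
             function(s) s + rnorm(4, 0, 0.05))
    })
    fit <- fit_cone_axis(cal_pair, sil)
    acos(min(1, abs(sum(fit$axis_direction * open)))) * 180 / pi
  })
  expect_lt(median(errs), 0.5)
})

test_that("virtual marker construction follows the projection arithmetic", {
  # P1=(10,100,0), axis x=z=0, P2=(0,-30,0) -> P3=(0,100,0)
  vm <- construct_virtual_markers(c(10, 100, 0), c(0, 0, 0), c(0, 1, 0), c(0, -30, 0))
  expect_vector_equal(vm$P3, c(0, 100, 0), 1e-12)
  expect_vector_equal(vm$reference_point, c(10 / 3, 170 / 3, 0), 1e-12)
  expect_false(vm$degenerate)
  # P1 on the axis degenerates (flagged, not an error)
  vm2 <- construct_virtual_markers(c(0, 50, 0), c(0, 0, 0), c(0, 1, 0), c(0, -30, 0))
  expect_true(vm2$degenerate)
  # defining property (P1 - P3) . axis = 0 on random inputs
  set.seed(8)
  for (i in 1:10) {
    d <- c(rnorm(3)); d <- d / sqrt(sum(d^2))
    ap <- rnorm(3, 0, 10)
    vm3 <- construct_virtual_markers(rnorm(3, 0, 50), ap, d, rnorm(3, 0, 50))
    expect_lt(abs(sum((vm3$P1 - vm3$P3) * d)), 1e-9)
    expect_lt(rsataper:::point_line_distance(vm3$P3, ap, d), 1e-9)
  }
  expect_error(construct_virtual_markers(c(1, 1, 1), c(0, 0, 0), c(0, 0, 0), c(0, -1, 0)),
               "zero-length")
})

test_that("taper frame is right-handed orthonormal with the stated signs", {
  cone <- list(axis_point = c(0, 0, 0), axis_direction = c(0, 1, 0))
  markers <- rbind(c(10, 0, 0), c(0, 10, 0), c(-10, -10, 0))
  fr <- build_taper_frame(cone, markers, "right")
  expect_vector_equal(fr$Y, c(0, 1, 0), 1e-12)
  expect_vector_equal(abs(fr$X), c(1, 0, 0), 1e-12)
  expect_gt(fr$X[1], 0)            # medial for a right hip
  expect_vector_equal(abs(fr$Z), c(0, 0, 1), 1e-12)
  # left hip mirrors the medial direction
  fl <- build_taper_frame(cone, markers, "left")
  expect_lt(fl$X[1], 0)
  # frame properties on random valid inputs
  set.seed(19)
  for (i in 1:10) {
    d <- rnorm(3); d <- d / sqrt(sum(d^2))
    M <- matrix(rnorm(9, 0, 30), 3, 3)
    fr2 <- tryCatch(build_taper_frame(list(axis_point = rnorm(3), axis_direction = d),
                                      M, "right"),
                    error = function(e) NULL)
    if (is.null(fr2)) next
    B <- fr2$basis
    expect_vector_equal(crossprod(B), diag(3), 1e-12)
    expect_equal(det(B), 1, tolerance = 1e-12)
  }
})

test_that("taper frame construction is equivariant under global rotation", {
  cone <- list(axis_point = c(5, 10, 2), axis_direction = c(0.3, 0.9, 0.2))
  markers <- rbind(c(12, 3, 1), c(-6, 9, -2), c(2, -11, 4))
  Q <- rotation_from_euler(4, -3, 6)
  f1 <- build_taper_frame(cone, markers, "right")
  f2 <- build_taper_frame(list(axis_point = as.numeric(Q %*% cone$axis_point),
                               axis_direction = as.numeric(Q %*% cone$axis_direction)),
                          markers %*% t(Q), "right")
  # small global rotations do not flip the sign conventions here
  expect_vector_equal(f2$basis, Q %*% f1$basis, 1e-9)
})

test_that("vector_in_frame is an isometry with an exact inverse", {
  cone <- list(axis_point = c(0, 0, 0), axis_direction = c(0.2, 1, -0.1))
  fr <- build_taper_frame(cone, rbind(c(10, 0, 1), c(0, 12, 0), c(-9, -7, 2)), "right")
  v <- c(0.3, -1.2, 0.8)
  comps <- vector_in_frame(fr, v)
  expect_equal(sqrt(sum(comps^2)), sqrt(sum(v^2)), tolerance = 1e-12)
  expect_vector_equal(vector_from_frame(fr, comps), v, 1e-12)
  expect_vector_equal(vector_in_frame(fr, fr$Y), c(0, 1, 0), 1e-12)
})
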