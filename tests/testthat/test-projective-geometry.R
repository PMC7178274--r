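# Scene geometry, central projection, calibration-box calibration and
# stereo reconstruction.

test_that("scene geometry places foci so central rays meet at the set angle", {
  sc <- scene_geometry(1400, 40)
  expect_equal(sc$foci[, 3], c(1400, 1400))
  expect_equal(sc$foci[1, 1], 1400 * tan(pi * 20 / 180))
  r1 <- -sc$foci[1, ] / sqrt(sum(sc$foci[1, ]^2))
  r2 <- -sc$foci[2, ] / sqrt(sum(sc$foci[2, ]^2))
  expect_equal(180 / pi * acos(sum(r1 * r2)), 40, tolerance = 1e-12)
})

test_that("central projection matches the similar-triangles oracle", {
  sc <- scene_geometry()
  # a film-plane point projects to itself
  expect_vector_equal(project_point(sc, 1, c(0, 0, 0)), c(0, 0), 1e-12)
  # focus (0,0,1400), point (10,20,700): scale 1400/700 = 2 -> (20,40)
  expect_vector_equal(rsataper:::project_from_focus(c(0, 0, 1400), c(10, 20, 700)),
                      c(20, 40), 1e-12)
  # collinearity of (focus, point, image) for random inputs
  set.seed(42)
  for (i in 1:20) {
    p <- c(runif(2, -150, 150), runif(1, 20, 1000))
    k <- sample(1:2, 1)
    img <- c(project_point(sc, k, p), 0)
    f <- sc$foci[k, ]
    resid <- rsataper:::point_line_distance(img, f, (p - f) / sqrt(sum((p - f)^2)))
    expect_lt(resid, 1e-9)
  }
  expect_error(project_point(sc, 1, c(0, 0, 1500)), "degenerate")
})

test_that("noiseless calibration recovers the focus exactly", {
  for (k in 1:2) {
    f <- default_scene$foci[k, ]
    cal <- noiseless_cal_pair[[k]]
    expect_vector_equal(cal$focus_position, f, 1e-6)
    expect_lt(cal$calibration_error, 1e-9)
    expect_lt(cal$focus_error, 1e-9)
  }
})

test_that("calibration quality under sigma = 0.01 mm noise meets RSA gates", {
  # Monte-Carlo against the standard thresholds (0.05 mm / 0.5 mm)
  set.seed(7)
  f <- default_scene$foci[1, ]
  ctrl_img <- rsataper:::project_from_focus(f, default_box$controls)
  for (i in 1:25) {
    cal <- calibrate_view(default_box,
                          default_box$fiducials[, 1:2] + rnorm(18, 0, 0.01),
                          ctrl_img + rnorm(18, 0, 0.01))
    expect_lt(cal$calibration_error, 0.05)
    expect_lt(cal$focus_error, 0.5)
  }
})

test_that("calibration is invariant to rigid in-plane re-digitization", {
  f <- default_scene$foci[1, ]
  ctrl_img <- rsataper:::project_from_focus(f, default_box$controls)
  th <- pi / 7
  Q <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  redig <- function(p) sweep(p %*% t(Q), 2, c(13.5, -4.2), `+`)
  cal <- calibrate_view(default_box, redig(default_box$fiducials[, 1:2]),
                        redig(ctrl_img))
  expect_vector_equal(cal$focus_position, f, 1e-6)
  expect_lt(cal$calibration_error, 1e-9)
})

test_that("degenerate calibrations error out", {
  f <- default_scene$foci[1, ]
  # coincident control markers -> ill-conditioned
  ctrl_img <- matrix(rep(c(5, 5), 9), ncol = 2, byrow = TRUE)
  expect_error(calibrate_view(default_box, default_box$fiducials[, 1:2], ctrl_img),
               "ill-conditioned")
  expect_error(calibrate_view(default_box, default_box$fiducials[1:4, 1:2],
                              rsataper:::project_from_focus(f, default_box$controls)),
               "counts")
  small <- list(fiducials = default_box$fiducials[1:3, ],
                controls = default_box$controls, control_height = 80)
  expect_error(calibrate_view(structure(small, class = "calibration_box"),
                              default_box$fiducials[1:3, 1:2],
                              rsataper:::project_from_focus(f, default_box$controls)),
               "at least 4")
})

test_that("projection / reconstruction round trip is the identity", {
  cal <- noiseless_cal_pair
  P <- c(12, -7, 150)
  m <- lapply(1:2, function(k) as.numeric(project_point(default_scene, k, P)))
  r <- reconstruct_point(cal[[1]], cal[[2]], m[[1]], m[[2]])
  expect_vector_equal(r$position, P, 1e-9)
  expect_lt(r$crossing_distance, 1e-12)

  # perturbing one image off the epipolar direction makes the crossing
  # distance strictly positive (the foci baseline is along x, so a pure-x
  # shift keeps the rays coplanar)
  r2 <- reconstruct_point(cal[[1]], cal[[2]], m[[1]], m[[2]] + c(0, 0.1))
  expect_gt(r2$crossing_distance, 1e-4)

  # batch round trip over 100 random points
  set.seed(11)
  pts <- cbind(runif(100, -120, 120), runif(100, -120, 120), runif(100, 30, 900))
  m1 <- project_point(default_scene, 1, pts)
  m2 <- project_point(default_scene, 2, pts)
  rb <- reconstruct_point(cal[[1]], cal[[2]], m1, m2)
  expect_lt(max(abs(rb$positions - pts)), 1e-6)
  expect_lt(max(rb$crossing_distances), 1e-9)
})

test_that("reconstruction error grows continuously with 2D noise", {
  cal <- noiseless_cal_pair
  P <- c(30, 40, 200)
  m1 <- as.numeric(project_point(default_scene, 1, P))
  m2 <- as.numeric(project_point(default_scene, 2, P))
  set.seed(3)
  err <- sapply(c(0, 0.01, 0.05), function(s) {
    mean(replicate(20, {
      r <- reconstruct_point(cal[[1]], cal[[2]], m1 + rnorm(2, 0, s), m2 + rnorm(2, 0, s))
      sqrt(sum((r$position - P)^2))
    }))
  })
  expect_equal(err[1], 0, tolerance = 1e-9)
  expect_true(all(diff(err) > 0))
})

test_that("parallel rays are rejected", {
  cal <- noiseless_cal_pair[[1]]
  expect_error(reconstruct_point(cal, cal, c(10, 10), c(10, 10)), "parallel")
})
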