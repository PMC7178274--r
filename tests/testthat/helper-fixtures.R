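# Shared fixtures: a noiseless calibrated stereo pair and small phantom
# configs. Everything is built in code at test time.

default_scene <- scene_geometry()
default_box <- calibration_box()

# noiseless calibration of both views of the default scene
noiseless_cal_pair <- local({
  lapply(1:2, function(k) {
    f <- default_scene$foci[k, ]
    calibrate_view(default_box,
                   default_box$fiducials[, 1:2],
                   rsataper:::project_from_focus(f, default_box$controls))
  })
})

# a fast phantom config: few patients, exact world unless noise requested
quick_config <- function(n_patients = 1, noise = 0, seed = 1, ...) {
  args <- utils::modifyList(list(n_patients = n_patients, noise_sigma_2d = noise,
                                 marker_jitter_sd = 0, amplitude_sdlog = 0,
                                 seed = seed),
                            list(...))
  do.call(phantom_config, args)
}

expect_vector_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(as.numeric(actual) - as.numeric(expected))), tol)
}
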