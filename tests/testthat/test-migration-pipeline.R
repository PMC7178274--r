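# End-to-end migration pipeline on phantoms with known ground truth, the
# quality gates and the descriptive statistics.

noiseless_series <- local({
  # one patient, zero noise, default trajectories
  analyze_series(generate_study(quick_config(seed = 101))$patients[[1]])
})

test_that("no-motion phantom recovers all-zero migration", {
  cfg <- quick_config(seed = 5,
                      total_migration = list(translation = c(0, 0, 0),
                                             rotation_deg = c(0, 0, 0)),
                      total_slip = c(0, 0, 0))
  ser <- analyze_series(generate_study(cfg)$patients[[1]])
  for (m in c(3, 120)) {
    r <- implant_to_bone_migration(ser, m, "marker")
    expect_vector_equal(c(r$Tx, r$Ty, r$Tz, r$Rx, r$Ry, r$Rz), rep(0, 6), 1e-6)
  }
})

test_that("marker migration matches ground truth at zero noise", {
  ser <- noiseless_series
  for (m in c(6, 24, 120)) {
    gt <- ser$ground_truth[[format(m)]]
    r <- implant_to_bone_migration(ser, m, "marker")
    expect_vector_equal(c(r$Tx, r$Ty, r$Tz), gt$migration[1:3], 1e-6)
    expect_vector_equal(c(r$Rx, r$Ry, r$Rz), gt$migration[4:6], 1e-6)
    expect_false(r$gated_out)
  }
})

test_that("marker and egs_corrected agree on a no-slip phantom; slip splits them", {
  cfg <- quick_config(seed = 6, total_slip = c(0, 0, 0))
  ser0 <- analyze_series(generate_study(cfg)$patients[[1]])
  a <- implant_to_bone_migration(ser0, 24, "marker")
  b <- implant_to_bone_migration(ser0, 24, "egs_corrected")
  expect_vector_equal(c(a$Tx, a$Ty, a$Tz, a$Rx, a$Ry, a$Rz),
                      c(b$Tx, b$Ty, b$Tz, b$Rx, b$Ry, b$Rz), 1e-6)
  # with slip: marker result unchanged, egs deviates (virtual-marker bias)
  cfg1 <- quick_config(seed = 6, total_slip = c(0, -0.25, 0))
  ser1 <- analyze_series(generate_study(cfg1)$patients[[1]])
  a1 <- implant_to_bone_migration(ser1, 24, "marker")
  e1 <- implant_to_bone_migration(ser1, 24, "egs")
  expect_vector_equal(c(a1$Tx, a1$Ty, a1$Tz), c(a$Tx, a$Ty, a$Tz), 1e-6)
  expect_gt(max(abs(c(e1$Tx - a1$Tx, e1$Ty - a1$Ty, e1$Tz - a1$Tz))), 0.02)
})

test_that("head-taper slip is recovered exactly at zero noise", {
  # the component values exercise all three taper-frame axes
  cfg <- quick_config(seed = 7, total_slip = c(0.044, 0.115, -0.279))
  ser <- analyze_series(generate_study(cfg)$patients[[1]])
  gt24 <- ser$ground_truth[["24"]]
  ht <- head_taper_migration(ser, 24)
  expect_vector_equal(c(ht$dx, ht$dy, ht$dz), gt24$slip, 1e-3)
  # visit 0 is exactly zero
  ht0 <- head_taper_migration(ser, 0)
  expect_identical(c(ht0$dx, ht0$dy, ht0$dz), c(0, 0, 0))
})

test_that("slip recovery under noise: null stays below the noise floor,
           injected slip is recovered within tolerance", {
  set.seed(55)
  # null phantoms, sigma = 0.05 mm
  cfg0 <- quick_config(n_patients = 6, noise = 0.05, seed = 77,
                       total_slip = c(0, 0, 0))
  st0 <- generate_study(cfg0)
  dy0 <- vapply(st0$patients, function(s) {
    head_taper_migration(analyze_series(s), 120)$dy
  }, numeric(1))
  expect_lt(median(abs(dy0)), 0.05)
  # injected taper-axis slip 0.10 mm
  cfg1 <- quick_config(n_patients = 6, noise = 0.05, seed = 78,
                       total_slip = c(0, 0.10, 0))
  st1 <- generate_study(cfg1)
  dy1 <- vapply(st1$patients, function(s) {
    head_taper_migration(analyze_series(s), 120)$dy
  }, numeric(1))
  expect_lt(abs(mean(dy1) - 0.10), 0.03)
})

test_that("quality gates compare inclusively and report per criterion", {
  th <- quality_thresholds()
  g <- quality_gate(list(calibration_error = 0, focus_error = 0,
                         condition_number = 0, rigid_body_error = 0), th)
  expect_true(attr(g, "pass"))
  g2 <- quality_gate(list(calibration_error = 0.01, focus_error = 0.1,
                          condition_number = 101, rigid_body_error = 0.1), th)
  expect_false(attr(g2, "pass"))
  expect_false(g2[["condition_number"]])
  expect_true(all(g2[c("calibration_error", "focus_error", "rigid_body_error")]))
  # boundary: exactly at the threshold passes
  g3 <- quality_gate(list(calibration_error = 0.05, focus_error = 0.5,
                          condition_number = 100, rigid_body_error = 0.35), th)
  expect_true(attr(g3, "pass"))
})

test_that("gating flags collinear-marker exams through the condition number", {
  ser <- noiseless_series
  # sabotage: replace bone markers by a collinear set in the analysis
  ser2 <- ser
  for (k in names(ser2$analysis)) {
    ser2$analysis[[k]]$bone <- cbind(1:4, 2 * (1:4) + 10, 150 + 3 * (1:4))
  }
  expect_error(implant_to_bone_migration(ser2, 12, "marker"), "collinear")
})

test_that("descriptive stats reproduce both SD conventions", {
  d <- descriptive_stats(c(160, 155, 160, 173, 160))
  expect_equal(round(d$mean), 162)
  expect_equal(round(d$sd_population), 6)
  expect_equal(d$sd_sample, sd(c(160, 155, 160, 173, 160)))
  expect_equal(d$n, 5L)
  d2 <- descriptive_stats(c(5, 5, 5))
  expect_equal(d2$mean, 5)
  expect_equal(d2$sd_population, 0)
  expect_error(descriptive_stats(numeric(0)), "at least one")
})

test_that("cohort summary recovers the programmed migration rate", {
  # plateau at ~0.26 mm by 120 months -> ~0.026 mm/year; zero noise keeps
  # the check tight at small n
  cfg <- quick_config(n_patients = 4, seed = 30)
  st <- generate_study(cfg)
  ht <- headtaper_table(st)
  cs <- cohort_summary(ht)
  total <- sqrt(sum(cfg$total_slip^2))
  expect_equal(cs$rate_mm_per_year, total / 10, tolerance = 1e-3)
  expect_equal(unname(cs$rate_per_axis[["y"]]), cfg$total_slip[2] / 10, tolerance = 1e-3)
  # all-zero cohort
  cfg0 <- quick_config(n_patients = 2, seed = 31, total_slip = c(0, 0, 0))
  cs0 <- cohort_summary(headtaper_table(generate_study(cfg0)))
  expect_equal(cs0$rate_mm_per_year, 0, tolerance = 1e-6)
  expect_true(all(abs(cs0$summary$dy_mean) < 1e-6))
  # grouping bookkeeping
  cfgG <- phantom_config(n_patients = 6, seed = 32, noise_sigma_2d = 0,
                         marker_jitter_sd = 0, amplitude_sdlog = 0)
  csG <- cohort_summary(headtaper_table(generate_study(cfgG)), "head_neck_length")
  expect_equal(sum(csG$group_counts), 6)
})

test_that("migration table has the declared schema and passes gates", {
  cfg <- quick_config(n_patients = 1, seed = 44)
  mig <- migration_table(generate_study(cfg), methods = c("marker", "egs_corrected"))
  expect_setequal(names(mig), c("patient_id", "visit_months", "method",
                                "Tx", "Ty", "Tz", "Rx", "Ry", "Rz",
                                "CN", "RBE", "pass"))
  expect_equal(nrow(mig), 7 * 2)
  expect_true(all(mig$pass))
  expect_true(all(mig$CN <= 100))
})
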