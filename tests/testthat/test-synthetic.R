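test_that("equal seeds give bit-identical records for every generator", {
  p <- loading_protocol(n_cycles = 2, samples_per_cycle = 120)
  tr <- curve_truth()
  expect_identical(generate_axial_cycles(p, tr, seed = 11),
                   generate_axial_cycles(p, tr, seed = 11))
  expect_identical(generate_torsion_cycles(p, torsion_truth(), seed = 11),
                   generate_torsion_cycles(p, torsion_truth(), seed = 11))
  expect_identical(generate_failure_ramp(failure_truth("herniation"), 300, seed = 11),
                   generate_failure_ramp(failure_truth("herniation"), 300, seed = 11))
  expect_identical(generate_endplate_profiles(8, seed = 11),
                   generate_endplate_profiles(8, seed = 11))
  base <- c(a = 1, b = 2)
  expect_identical(generate_cohort(cohort_spec("g", 5, 3, 2, seed = 11), base),
                   generate_cohort(cohort_spec("g", 5, 3, 2, seed = 11), base))
  expect_false(identical(generate_axial_cycles(p, tr, seed = 11),
                         generate_axial_cycles(p, tr, seed = 12)))
})

test_that("degenerate single-slope truth yields an exactly linear limb", {
  k <- 120
  tr <- curve_truth(nz_stiffness = k, compressive_stiffness = k,
                    tensile_stiffness = k, hysteresis_offset = 0, noise_sd = 0)
  rec <- generate_axial_cycles(loading_protocol(n_cycles = 2), tr, seed = 1)
  seg <- extract_last_cycle(rec)
  limb <- seg$data[seg$data$sweep == "first", ]
  fit <- stats::lm(response ~ primary, data = limb)
  expect_lt(max(abs(stats::resid(fit))), 1e-9 * diff(range(rec$force_N)))
  expect_equal(unname(stats::coef(fit)[2]), k, tolerance = 1e-6)
})

test_that("axial force extremes honour the protocol stress limits times area", {
  p <- loading_protocol(n_cycles = 2)
  area <- cross_sectional_area(20)
  rec <- generate_axial_cycles(p, curve_truth(noise_sd = 0), seed = 1, area = area)
  expect_equal(max(rec$force_N), p$tension_limit * area, tolerance = 1e-6)
  expect_equal(min(rec$force_N), p$compression_limit * area, tolerance = 1e-6)
})

test_that("torsion rotation sweeps exactly twice the protocol amplitude", {
  p <- loading_protocol(n_cycles = 2, rotation_amplitude = 4)
  rec <- generate_torsion_cycles(p, torsion_truth(), seed = 1)
  expect_equal(diff(range(rec$rotation_deg)), 8)
})

test_that("generator rejects invalid protocols and truths", {
  expect_error(loading_protocol(samples_per_cycle = 20), "samples_per_cycle")
  expect_error(curve_truth(transition_sharpness = 0), "transition_sharpness")
  expect_error(curve_truth(compressive_stiffness = 5, nz_stiffness = 10),
               "compressive_stiffness")
  expect_error(generate_failure_ramp(failure_truth("herniation"), area = -1, seed = 1))
  expect_error(failure_truth("herniation", post_peak_drop_fraction = 0))
})

test_that("failure ramp boundary shapes behave as constructed", {
  area <- 300
  # full drop: force reaches zero after the peak
  r <- generate_failure_ramp(failure_truth("endplate", post_peak_drop_fraction = 1,
                                           rebound = FALSE),
                             area, seed = 1, noise_sd = 0)
  expect_equal(min(r$force_N[which.max(r$force_N):nrow(r)]), 0)
  # no rebound: the single global maximum equals peak stress x area
  tr <- failure_truth("endplate", peak_stress = 3, rebound = FALSE)
  r2 <- generate_failure_ramp(tr, area, seed = 1, noise_sd = 0)
  expect_equal(max(r2$force_N), 3 * area, tolerance = 1e-6)
  expect_true(all(diff(r2$displacement_mm) > 0))
})

test_that("endplate profiles encode the requested mean height", {
  flat <- generate_endplate_profiles(8, curvature_depth = 0, seed = 3)
  expect_equal(average_disc_height(flat), 8)
  curved <- generate_endplate_profiles(8, curvature_depth = 1, seed = 3)
  expect_equal(average_disc_height(curved), 8, tolerance = 0.005)
  # halving the scale with doubled pixel coordinates leaves mm height fixed
  doubled <- curved
  doubled$superior$x_px <- 2 * curved$superior$x_px
  doubled$superior$y_px <- 2 * curved$superior$y_px
  doubled$inferior$x_px <- 2 * curved$inferior$x_px
  doubled$inferior$y_px <- 2 * curved$inferior$y_px
  doubled$scale_mm_per_px <- curved$scale_mm_per_px / 2
  expect_equal(average_disc_height(doubled), average_disc_height(curved))
})

test_that("cohort generator reproduces its percent-change distribution", {
  base <- c(compressive_stiffness = 300)
  big <- generate_cohort(cohort_spec("defect", 10000, 6.96, 5.93, seed = 5), base)
  expect_lt(abs(mean(big$pct_change) - 6.96), 0.2)
  # degenerate SD: every specimen shares the exact change
  fixed <- generate_cohort(cohort_spec("g", 20, -10, 0, seed = 5), base)
  expect_true(all(fixed$pct_change == -10))
  # null treatment: normalized ratio exactly 1
  null <- generate_cohort(cohort_spec("g", 20, 0, 0, seed = 5), base)
  expect_true(all(null$ratio == 1))
})
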