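# Cycle segmentation --------------------------------------------------------

test_that("the last complete cycle of a 20-cycle record spans the final period", {
  p <- loading_protocol(n_cycles = 20, samples_per_cycle = 200)
  rec <- generate_axial_cycles(p, curve_truth(noise_sd = 0), seed = 1)
  seg <- extract_last_cycle(rec)
  dt <- 1 / (p$frequency * p$samples_per_cycle)
  # final 1/0.1 Hz = 10 s window, within one sample
  expect_equal(min(seg$data$time), 190, tolerance = dt * 1.5)
  expect_equal(max(seg$data$time), 200, tolerance = dt * 1.5)
  expect_equal(seg$n_cycles_found, 20)
})

test_that("a single cosine cycle is returned whole", {
  t <- seq(0, 10, length.out = 201)
  rec <- tibble::tibble(time_s = t, displacement_mm = cos(2 * pi * 0.1 * t),
                        force_N = 50 * cos(2 * pi * 0.1 * t))
  seg <- extract_last_cycle(rec)
  expect_equal(nrow(seg$data), 201)
})

test_that("a record truncated mid-cycle falls back to the previous complete cycle", {
  p <- loading_protocol(n_cycles = 20, samples_per_cycle = 200)
  rec <- generate_axial_cycles(p, curve_truth(noise_sd = 0), seed = 1)
  truncated <- rec[rec$time_s < 195.5, ]   # stops inside cycle 20
  seg <- extract_last_cycle(truncated)
  expect_equal(min(seg$data$time), 180, tolerance = 0.1)
  expect_equal(max(seg$data$time), 190, tolerance = 0.1)
})

test_that("records without a complete cycle raise an informative error", {
  t <- seq(0, 3, length.out = 100)
  rec <- tibble::tibble(time_s = t, displacement_mm = t, force_N = t)
  expect_error(extract_last_cycle(rec), "complete loading cycle")
})

# Limb stiffness -------------------------------------------------------------

test_that("limb stiffness recovers straight, bilinear and constant responses", {
  x <- seq(0, 1, length.out = 101)
  expect_equal(limb_stiffness(data.frame(primary = x, response = 100 * x)), 100)
  # bilinear: slope 50 below 0.5, slope 200 above; top 20% all lie above 0.5
  y <- ifelse(x < 0.5, 50 * x, 25 + 200 * (x - 0.5))
  expect_equal(limb_stiffness(data.frame(primary = x, response = y)), 200,
               tolerance = 1e-9)
  expect_equal(limb_stiffness(data.frame(primary = x, response = rep(2, 101))), 0)
})

test_that("limb stiffness errors when the selected fraction is too small", {
  x <- seq(0, 1, length.out = 10)
  expect_error(limb_stiffness(data.frame(primary = x, response = x), fraction = 0.2),
               ">= 3")
})

# Range of motion ------------------------------------------------------------

test_that("range of motion is the primary excursion, warning when degenerate", {
  expect_equal(range_of_motion(data.frame(primary = c(-1, 0.3, 1.5),
                                          response = c(-1, 0, 1))), 2.5)
  t <- seq(0, 10, length.out = 101)
  tor <- tibble::tibble(time_s = t, rotation_deg = 4 * cos(2 * pi * 0.1 * t),
                        torque_Nmm = 20 * cos(2 * pi * 0.1 * t))
  expect_equal(range_of_motion(extract_last_cycle(tor)), 8)
  expect_warning(rom <- range_of_motion(data.frame(primary = c(0, 0, 0),
                                                   response = c(0, 1, 0))),
                 "zero-amplitude")
  expect_equal(rom, 0)
})

# Neutral zone ---------------------------------------------------------------

test_that("a perfect straight line expands to the full curve", {
  x <- seq(-1, 1, length.out = 120)
  nz <- find_neutral_zone(data.frame(primary = x, response = 7.5 * x))
  expect_equal(nz$start, 1)
  expect_equal(nz$end, 120)
  expect_equal(nz$nz_stiffness, 7.5, tolerance = 1e-9)
  expect_equal(nz$nz_length, 2)
})

test_that("the neutral zone of a noiseless trilinear curve sits in the plateau", {
  # plateau slope 5 on [-0.2, 0.2], flanks 100
  tr <- curve_truth(nz_half_width = 0.2, nz_stiffness = 5,
                    compressive_stiffness = 100, tensile_stiffness = 100,
                    hysteresis_offset = 0, noise_sd = 0)
  x <- seq(-1, 1, length.out = 241)
  curve <- data.frame(primary = x, response = trilinear_response_ref(x, tr))
  nz <- find_neutral_zone(curve)
  blend <- 2 * log(99) * tr$nz_half_width / tr$transition_sharpness
  expect_gte(min(x[nz$start:nz$end]), -0.2 - blend)
  expect_lte(max(x[nz$start:nz$end]), 0.2 + blend)
  expect_equal(nz$nz_stiffness, 5, tolerance = 0.10 * 5)
})

test_that("the detected slope of a noisy line is close to truth", {
  slopes <- vapply(1:100, function(s) {
    withr::with_seed(s, {
      x <- seq(0, 1, length.out = 150)
      y <- 10 * x + rnorm(150, sd = 0.01 * 10) # noise 1% of range
    })
    find_neutral_zone(data.frame(primary = x, response = y))$nz_stiffness
  }, numeric(1))
  expect_lt(abs(median(slopes) - 10) / 10, 0.05)
})

test_that("curves shorter than the window are rejected", {
  x <- seq(0, 1, length.out = 10)
  expect_error(find_neutral_zone(data.frame(primary = x, response = x)),
               "moving window")
})

test_that("the incremental seed window matches exhaustive lm() enumeration", {
  for (s in 1:30) {
    curve <- random_curve(s)
    nz <- find_neutral_zone(curve)
    expect_identical(nz$seed_start,
                     oracle_min_slope_start(curve$primary, curve$response))
  }
})

# Parameter assembly ---------------------------------------------------------

test_that("zero-noise trilinear parameters are recovered", {
  p <- loading_protocol(n_cycles = 2)
  tr <- curve_truth(noise_sd = 0)
  fit <- analyze_axial(generate_axial_cycles(p, tr, seed = 4))
  expect_equal(param_value(fit, "compressive_stiffness"), 300, tolerance = 0.02)
  expect_equal(param_value(fit, "tensile_stiffness"), 150, tolerance = 0.02)
  expect_equal(param_value(fit, "nz_stiffness"), 20, tolerance = 0.10)
  rec <- generate_axial_cycles(p, tr, seed = 4)
  tol <- nz_length_tol(tr, p, diff(range(rec$displacement_mm)))
  expect_lt(abs(param_value(fit, "nz_length") - 2 * tr$nz_half_width), tol)
  expect_equal(param_value(fit, "range_of_motion"),
               diff(range(rec$displacement_mm)))
})

test_that("a purely linear loop gives equal stiffnesses and nz_length = ROM", {
  k <- 80
  tr <- curve_truth(nz_stiffness = k, compressive_stiffness = k,
                    tensile_stiffness = k, hysteresis_offset = 0, noise_sd = 0)
  fit <- analyze_axial(generate_axial_cycles(loading_protocol(n_cycles = 2), tr, seed = 1))
  expect_equal(param_value(fit, "compressive_stiffness"), k, tolerance = 1e-6)
  expect_equal(param_value(fit, "tensile_stiffness"), k, tolerance = 1e-6)
  expect_equal(param_value(fit, "nz_stiffness"), k, tolerance = 1e-6)
  expect_equal(param_value(fit, "nz_length"), param_value(fit, "range_of_motion"),
               tolerance = 1e-9)
})

test_that("scaling the response scales stiffnesses and leaves lengths fixed", {
  p <- loading_protocol(n_cycles = 2, samples_per_cycle = 200)
  rec <- generate_axial_cycles(p, curve_truth(), seed = 9)
  fit1 <- analyze_axial(rec)
  rec2 <- dplyr::mutate(rec, force_N = 3 * force_N)
  fit2 <- analyze_axial(rec2)
  for (nm in c("compressive_stiffness", "tensile_stiffness", "nz_stiffness")) {
    expect_equal(param_value(fit2, nm), 3 * param_value(fit1, nm), tolerance = 1e-9)
  }
  expect_equal(param_value(fit2, "range_of_motion"), param_value(fit1, "range_of_motion"))
  expect_equal(param_value(fit2, "nz_length"), param_value(fit1, "nz_length"))
  # scaling the primary axis divides stiffnesses and scales lengths
  rec3 <- dplyr::mutate(rec, displacement_mm = 2 * displacement_mm)
  fit3 <- analyze_axial(rec3)
  expect_equal(param_value(fit3, "compressive_stiffness"),
               param_value(fit1, "compressive_stiffness") / 2, tolerance = 1e-9)
  expect_equal(param_value(fit3, "range_of_motion"),
               2 * param_value(fit1, "range_of_motion"))
  expect_equal(param_value(fit3, "nz_length"), 2 * param_value(fit1, "nz_length"),
               tolerance = 1e-9)
})

test_that("mirroring a record leaves reported magnitudes unchanged (roles swap)", {
  p <- loading_protocol(n_cycles = 2, samples_per_cycle = 200)
  rec <- generate_axial_cycles(p, curve_truth(), seed = 10)
  fit1 <- analyze_axial(rec)
  mir <- dplyr::mutate(rec, displacement_mm = -displacement_mm, force_N = -force_N)
  fit2 <- analyze_axial(mir)
  expect_equal(param_value(fit2, "range_of_motion"),
               param_value(fit1, "range_of_motion"))
  expect_equal(param_value(fit2, "nz_length"), param_value(fit1, "nz_length"),
               tolerance = 1e-9)
  expect_equal(param_value(fit2, "nz_stiffness"), param_value(fit1, "nz_stiffness"),
               tolerance = 1e-9)
  expect_equal(sort(c(param_value(fit2, "compressive_stiffness"),
                      param_value(fit2, "tensile_stiffness"))),
               sort(c(param_value(fit1, "compressive_stiffness"),
                      param_value(fit1, "tensile_stiffness"))), tolerance = 1e-9)
})

test_that("nz_length never exceeds range of motion", {
  p <- loading_protocol(n_cycles = 2, samples_per_cycle = 150)
  for (s in 1:10) {
    tr <- withr::with_seed(s, curve_truth(
      nz_half_width = runif(1, 0.1, 0.4),
      nz_stiffness = runif(1, 5, 50),
      compressive_stiffness = runif(1, 100, 400),
      tensile_stiffness = runif(1, 80, 300),
      hysteresis_offset = runif(1, 0, 20),
      noise_sd = runif(1, 0, 3)))
    fit <- analyze_axial(generate_axial_cycles(p, tr, seed = s))
    expect_lte(param_value(fit, "nz_length"), param_value(fit, "range_of_motion"))
  }
})

# Torsion --------------------------------------------------------------------

test_that("torsional parameters: averages, ranges and asymmetric recovery", {
  p <- loading_protocol(n_cycles = 2)
  # exact linear torque = 5 * rotation: range over +/-4 deg is 40 N mm
  lin <- torsion_truth(nz_stiffness = 5, cw_stiffness = 5, ccw_stiffness = 5,
                       hysteresis_offset = 0, noise_sd = 0)
  fit_lin <- analyze_torsion(generate_torsion_cycles(p, lin, seed = 1))
  expect_equal(param_value(fit_lin, "torque_range"), 40, tolerance = 1e-6)
  # asymmetric limbs: cw 2.0, ccw 3.0 averages to 2.5
  asym <- torsion_truth(nz_stiffness = 0.5, cw_stiffness = 2, ccw_stiffness = 3,
                        hysteresis_offset = 1, noise_sd = 0)
  fit <- analyze_torsion(generate_torsion_cycles(p, asym, seed = 2))
  expect_equal(param_value(fit, "cw_stiffness"), 2, tolerance = 0.02)
  expect_equal(param_value(fit, "ccw_stiffness"), 3, tolerance = 0.02)
  expect_equal(param_value(fit, "torsional_stiffness"), 2.5, tolerance = 0.02)
  expect_identical(param_value(fit, "torsional_stiffness"),
                   (param_value(fit, "cw_stiffness") +
                      param_value(fit, "ccw_stiffness")) / 2)
  # symmetric truth, zero noise: both limbs agree to 1e-6 relative
  sym <- torsion_truth(noise_sd = 0)
  fit_sym <- analyze_torsion(generate_torsion_cycles(p, sym, seed = 3))
  expect_equal(param_value(fit_sym, "cw_stiffness"),
               param_value(fit_sym, "ccw_stiffness"), tolerance = 1e-6)
})
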