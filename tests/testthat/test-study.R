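test_that("normalization returns ratios, percent changes and undefined flags", {
  out <- normalize_to_intact(c(k = 10), c(k = 9))
  expect_equal(out$ratio, 0.9)
  expect_equal(out$pct_change, -10)
  # identity
  same <- normalize_to_intact(c(a = 3, b = 5), c(a = 3, b = 5))
  expect_true(all(same$ratio == 1))
  # zero intact value: flagged, not fatal
  z <- normalize_to_intact(c(a = 0, b = 2), c(a = 1, b = 4))
  expect_true(is.na(z$ratio[z$parameter == "a"]))
  expect_false(z$defined[z$parameter == "a"])
  expect_equal(z$ratio[z$parameter == "b"], 2)
  expect_error(normalize_to_intact(c(a = 1), c(b = 1)), "same keys")
})

test_that("the null pipeline returns unit ratios at zero noise", {
  des <- study_design(c(sham = 3))
  coh <- run_study(des, loading_protocol(n_cycles = 2, samples_per_cycle = 200),
                   seed = 2, axial_truth = curve_truth(noise_sd = 0),
                   torsional_truth = torsion_truth(noise_sd = 0))
  expect_true(all(is.na(coh$specimens$error)))
  expect_true(all(abs(coh$parameters$ratio - 1) < 1e-6))
})

test_that("an injected tensile-stiffness drop is recovered in the group mean", {
  des <- study_design(
    c(defect = 4),
    perturbations = tibble::tibble(group = "defect", channel = "axial",
                                   parameter = "tensile_stiffness",
                                   pct_mean = -30, pct_sd = 0)
  )
  coh <- run_study(des, loading_protocol(n_cycles = 2, samples_per_cycle = 200),
                   seed = 3, axial_truth = curve_truth(noise_sd = 0),
                   torsional_truth = torsion_truth(noise_sd = 0))
  tens <- dplyr::filter(coh$parameters, channel == "axial",
                        parameter == "tensile_stiffness")
  expect_equal(mean(tens$ratio), 0.70, tolerance = 0.02)
  # untouched parameters stay at unity
  comp <- dplyr::filter(coh$parameters, channel == "axial",
                        parameter == "compressive_stiffness")
  expect_true(all(abs(comp$ratio - 1) < 1e-6))
})

test_that("the cohort table is a pure function of design, protocol and seed", {
  des <- study_design(c(g = 2))
  p <- loading_protocol(n_cycles = 2, samples_per_cycle = 150)
  a <- run_study(des, p, seed = 7)
  b <- run_study(des, p, seed = 7)
  expect_identical(a$parameters, b$parameters)
  expect_identical(a$specimens, b$specimens)
  c2 <- run_study(des, p, seed = 8)
  expect_false(identical(a$parameters, c2$parameters))
})

test_that("group summaries report mean and sample SD, NA for singletons", {
  df <- data.frame(group = "g", parameter = "k", ratio = c(0.9, 1.0, 1.1))
  out <- summarize_groups(df)
  expect_equal(out$ratio_mean, 1.0)
  expect_equal(out$ratio_sd, 0.1)
  single <- summarize_groups(data.frame(group = "g", parameter = "k", ratio = 1.2))
  expect_equal(single$ratio_mean, 1.2)
  expect_true(is.na(single$ratio_sd))
})

test_that("cohort-level percent change converges to its target distribution", {
  base <- c(compressive_stiffness = 300)
  coh <- generate_cohort(cohort_spec("defect", 10000, 6.96, 5.93, seed = 21), base)
  out <- summarize_groups(coh)
  expect_lt(abs(out$pct_change_mean - 6.96), 0.2)
  expect_lt(abs(out$pct_change_sd - 5.93), 0.2)
})

test_that("stage errors are recorded per specimen without aborting the cohort", {
  des <- study_design(c(bad = 1, good = 1),
                      failure = tibble::tibble(group = "bad",
                                               mode = "herniation",
                                               peak_stress = -2))
  coh <- run_study(des, loading_protocol(n_cycles = 2, samples_per_cycle = 150),
                   seed = 4, axial_truth = curve_truth(noise_sd = 0),
                   torsional_truth = torsion_truth(noise_sd = 0))
  expect_equal(nrow(coh$specimens), 2)
  expect_true(any(!is.na(coh$specimens$error)))
  expect_true(any(is.na(coh$specimens$error)))
})
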