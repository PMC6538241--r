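# Independent oracles used by the unit and acceptance tests. These are kept
# deliberately naive (lm() per window, dense numeric integration) so they
# exercise none of the package's own fitting code.

# Exhaustive minimal-|slope| window search via lm(), with the same tie-break
# convention as the incremental implementation (proximity to the response
# zero-crossing, then lowest start index).
oracle_min_slope_start <- function(x, y, window = 15) {
  starts <- seq_len(length(x) - window + 1)
  slopes <- vapply(starts, function(s) {
    unname(stats::coef(stats::lm(y[s:(s + window - 1)] ~ x[s:(s + window - 1)]))[2])
  }, numeric(1))
  m <- min(abs(slopes))
  cand <- which(abs(slopes) == m)
  if (length(cand) > 1) {
    zc <- which.min(abs(y))
    centres <- cand + (window - 1) / 2
    cand <- cand[order(abs(centres - zc), cand)]
  }
  cand[1]
}

# Random smooth-ish test curves for the oracle-equivalence property:
# a cubic trend plus sinusoids plus noise over a random span.
random_curve <- function(seed, max_points = 300) {
  withr::with_seed(seed, {
    n <- sample(40:max_points, 1)
    x <- sort(stats::runif(n, -1, 1)) * stats::runif(1, 0.5, 5)
    b <- stats::rnorm(4)
    y <- b[1] + b[2] * x + b[3] * x^2 + b[4] * x^3 +
      stats::rnorm(1, sd = 2) * sin(stats::runif(1, 1, 5) * x) +
      stats::rnorm(n, sd = 0.1)
    tibble::tibble(primary = x, response = y)
  })
}

# Tolerance for recovered neutral-zone length on a sampled record: the blend
# corners (1%-99% logistic span) plus the local sample spacing at the curve
# centre on each side - an edge cannot be localized more finely than the grid.
nz_length_tol <- function(truth, protocol, primary_range) {
  blend <- 2 * log(99) * truth$nz_half_width / truth$transition_sharpness
  spacing <- primary_range * pi / protocol$samples_per_cycle
  blend + 2 * spacing
}

# Zero-noise, zero-hysteresis variants for exact-recovery comparisons.
quiet_truth <- function(...) {
  curve_truth(noise_sd = 0, ...)
}

param_value <- function(fit, name) {
  fit$parameters$value[fit$parameters$parameter == name]
}

# Reference implementation of the blended-trilinear law, written directly
# from its closed form (logistic integral = softplus), independent of the
# package's internal evaluator.
trilinear_response_ref <- function(d, truth) {
  s <- truth$nz_half_width / truth$transition_sharpness
  sp <- function(x) ifelse(x > 30, x, log1p(exp(x)))
  f <- function(x) {
    truth$nz_stiffness * (x - truth$nz_center) +
      (truth$tensile_stiffness - truth$nz_stiffness) * s *
        sp((x - truth$nz_center - truth$nz_half_width) / s) -
      (truth$compressive_stiffness - truth$nz_stiffness) * s *
        sp(-(x - truth$nz_center + truth$nz_half_width) / s)
  }
  f(d) - f(truth$nz_center)
}
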