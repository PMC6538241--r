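# Logistic-blended trilinear constitutive law shared by the cyclic simulators.
#
# Local stiffness k(d) = k_nz
#                      + (k_tens - k_nz) * sigmoid((d - (c + w)) / s)
#                      + (k_comp - k_nz) * sigmoid(-(d - (c - w)) / s)
# with blend scale s = w / transition_sharpness. Integrating in closed form
# (the integral of the logistic is the softplus) gives a smooth load curve
# whose neutral zone [c - w, c + w], flank slopes and transition width are
# all analytically known -- the property the parameter-recovery tests rely on.

softplus <- function(x) {
  ifelse(x > 0, x + log1p(exp(-x)), log1p(exp(x)))
}

# Force (or torque) at primary position d under a curve_truth, before any
# hysteresis offset or noise. Anchored so the response is 0 at nz_center.
trilinear_response <- function(d, truth) {
  c0 <- truth$nz_center
  w <- truth$nz_half_width
  s <- w / truth$transition_sharpness
  dk_t <- truth$tensile_stiffness - truth$nz_stiffness
  dk_c <- truth$compressive_stiffness - truth$nz_stiffness
  raw <- function(x) {
    truth$nz_stiffness * (x - c0) +
      dk_t * s * softplus((x - (c0 + w)) / s) -
      dk_c * s * softplus(-(x - (c0 - w)) / s)
  }
  raw(d) - raw(c0)
}

# Invert trilinear_response: the primary position where the response equals
# `target`. The law is nondecreasing, strictly so outside the plateau, which
# is where the protocol stress limits live.
trilinear_invert <- function(target, truth) {
  f <- function(x) trilinear_response(x, truth) - target
  lo <- truth$nz_center - truth$nz_half_width
  hi <- truth$nz_center + truth$nz_half_width
  span <- max(hi - lo, 1e-6)
  while (f(lo) > 0) lo <- lo - span
  while (f(hi) < 0) hi <- hi + span
  stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
}
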