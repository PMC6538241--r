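#' Loading protocol for cyclic and failure testing
#'
#' Describes the servohydraulic loading protocol applied to a motion segment:
#' a static preload, cyclic axial loading between a tensile and a compressive
#' effective-stress limit, cyclic torsion of fixed amplitude, and a
#' displacement-controlled ramp to failure. Defaults reproduce a widely used
#' ex vivo protocol for bovine caudal discs: 0.1 MPa preload for 5 min, then
#' 20 cycles at 0.1 Hz between +0.25 MPa tension and -0.50 MPa compression,
#' torsion at +/-4 degrees for 20 cycles at 0.1 Hz, and a 2 mm/min
#' compression ramp to failure.
#'
#' @param preload_stress Preload effective stress in MPa.
#' @param preload_duration Preload hold in seconds.
#' @param n_cycles Number of loading cycles (>= 1).
#' @param frequency Cycle frequency in Hz.
#' @param tension_limit Tensile effective-stress limit in MPa (positive).
#' @param compression_limit Compressive effective-stress limit in MPa (negative).
#' @param rotation_amplitude Torsion amplitude in degrees (rotation sweeps
#'   +/- this value).
#' @param failure_rate Failure-ramp displacement rate in mm/min.
#' @param samples_per_cycle Samples recorded per cycle (>= 50, so that each
#'   limb comfortably holds the 15-point neutral-zone window).
#'
#' @return An object of class `loading_protocol` (a named list).
#' @examples
#' loading_protocol()
#' loading_protocol(n_cycles = 5, samples_per_cycle = 200)
#' @export
loading_protocol <- function(preload_stress = 0.1,
                             preload_duration = 300,
                             n_cycles = 20,
                             frequency = 0.1,
                             tension_limit = 0.25,
                             compression_limit = -0.50,
                             rotation_amplitude = 4,
                             failure_rate = 2,
                             samples_per_cycle = 400) {
  stopifnot(
    "tension_limit must be positive" = tension_limit > 0,
    "compression_limit must be negative" = compression_limit < 0,
    "n_cycles must be >= 1" = n_cycles >= 1,
    "frequency must be positive" = frequency > 0,
    "rotation_amplitude must be positive" = rotation_amplitude > 0,
    "failure_rate must be positive" = failure_rate > 0
  )
  if (samples_per_cycle < 50) {
    stop("samples_per_cycle must be >= 50 so each limb supports the moving-window fit",
         call. = FALSE)
  }
  structure(
    list(
      preload_stress = preload_stress,
      preload_duration = preload_duration,
      n_cycles = as.integer(n_cycles),
      frequency = frequency,
      tension_limit = tension_limit,
      compression_limit = compression_limit,
      rotation_amplitude = rotation_amplitude,
      failure_rate = failure_rate,
      samples_per_cycle = as.integer(samples_per_cycle)
    ),
    class = "loading_protocol"
  )
}

#' @export
print.loading_protocol <- function(x, ...) {
  cat("<loading_protocol>\n")
  cat(sprintf("  preload: %.2f MPa for %.0f s\n", x$preload_stress, x$preload_duration))
  cat(sprintf("  axial:   %d cycles @ %.2g Hz, %+.2f / %+.2f MPa\n",
              x$n_cycles, x$frequency, x$tension_limit, x$compression_limit))
  cat(sprintf("  torsion: +/-%.1f deg, %d cycles @ %.2g Hz\n",
              x$rotation_amplitude, x$n_cycles, x$frequency))
  cat(sprintf("  failure: %.1f mm/min ramp; %d samples/cycle\n",
              x$failure_rate, x$samples_per_cycle))
  invisible(x)
}

#' Ground-truth curve shape for a synthetic cyclic test
#'
#' Parameterizes the logistic-blended trilinear load-displacement law used by
#' the simulators: a low-stiffness neutral zone of half-width `nz_half_width`
#' centred at `nz_center`, blending smoothly into stiffer compressive and
#' tensile flanks. The blend scale is `nz_half_width / transition_sharpness`,
#' so larger `transition_sharpness` gives a crisper trilinear shape. Loading
#' and unloading limbs are separated by a constant force gap
#' `hysteresis_offset`, and i.i.d. Gaussian noise of `noise_sd` is added to
#' the response channel only (displacement/rotation is actuator-controlled).
#'
#' For torsional curves the same law applies with rotation in degrees and
#' torque in N mm; `compressive_stiffness` is the clockwise (negative
#' rotation) flank and `tensile_stiffness` the counterclockwise flank. The
#' [torsion_truth()] wrapper exposes those names directly.
#'
#' Defaults are representative of an intact bovine caudal motion segment:
#' flank stiffnesses of a few hundred N/mm, a neutral zone of ~0.5 mm total
#' length at an order of magnitude lower stiffness, and a visible hysteresis
#' gap. The default `transition_sharpness` of 100 keeps the blend corners
#' narrow (about two sample spacings under the default protocol), so the
#' neutral zone the law encodes is exact at working precision - the property
#' the parameter-recovery tests compare against; lower values give softer,
#' more sigmoid-looking loops whose true neutral zone is correspondingly
#' fuzzier.
#'
#' @param nz_center Neutral-zone centre, mm (axial) or degrees (torsion).
#' @param nz_half_width Neutral-zone half width, same units as `nz_center`.
#' @param nz_stiffness Neutral-zone slope, N/mm (or N mm/deg); >= 0.
#' @param compressive_stiffness Compressive (or clockwise) flank slope; at
#'   least `nz_stiffness` (equality degenerates to a single straight limb).
#' @param tensile_stiffness Tensile (or counterclockwise) flank slope; at
#'   least `nz_stiffness`.
#' @param hysteresis_offset Force (torque) gap between loading and unloading
#'   limbs at the neutral-zone centre, N (or N mm).
#' @param noise_sd Standard deviation of additive Gaussian response noise,
#'   N (or N mm); >= 0.
#' @param transition_sharpness Dimensionless > 0; ratio of the neutral-zone
#'   half width to the logistic blending scale.
#'
#' @return An object of class `curve_truth` (a named list).
#' @examples
#' curve_truth()
#' torsion_truth(cw_stiffness = 2, ccw_stiffness = 3, noise_sd = 0)
#' @export
curve_truth <- function(nz_center = 0,
                        nz_half_width = 0.25,
                        nz_stiffness = 20,
                        compressive_stiffness = 300,
                        tensile_stiffness = 150,
                        hysteresis_offset = 10,
                        noise_sd = 0.5,
                        transition_sharpness = 100) {
  stopifnot(
    "nz_half_width must be positive" = nz_half_width > 0,
    "nz_stiffness must be >= 0" = nz_stiffness >= 0,
    "compressive_stiffness must be >= nz_stiffness" =
      compressive_stiffness >= nz_stiffness,
    "tensile_stiffness must be >= nz_stiffness" =
      tensile_stiffness >= nz_stiffness,
    "noise_sd must be >= 0" = noise_sd >= 0
  )
  if (transition_sharpness <= 0) {
    stop("transition_sharpness must be positive", call. = FALSE)
  }
  structure(
    list(
      nz_center = nz_center,
      nz_half_width = nz_half_width,
      nz_stiffness = nz_stiffness,
      compressive_stiffness = compressive_stiffness,
      tensile_stiffness = tensile_stiffness,
      hysteresis_offset = hysteresis_offset,
      noise_sd = noise_sd,
      transition_sharpness = transition_sharpness
    ),
    class = "curve_truth"
  )
}

#' @rdname curve_truth
#' @param cw_stiffness Clockwise (negative rotation) flank slope, N mm/deg.
#' @param ccw_stiffness Counterclockwise flank slope, N mm/deg.
#' @param ... Passed on to [curve_truth()].
#' @export
torsion_truth <- function(nz_center = 0,
                          nz_half_width = 1,
                          nz_stiffness = 20,
                          cw_stiffness = 100,
                          ccw_stiffness = 100,
                          hysteresis_offset = 40,
                          noise_sd = 5,
                          transition_sharpness = 100,
                          ...) {
  curve_truth(
    nz_center = nz_center,
    nz_half_width = nz_half_width,
    nz_stiffness = nz_stiffness,
    compressive_stiffness = cw_stiffness,
    tensile_stiffness = ccw_stiffness,
    hysteresis_offset = hysteresis_offset,
    noise_sd = noise_sd,
    transition_sharpness = transition_sharpness,
    ...
  )
}

#' Ground truth for a synthetic compression-to-failure ramp
#'
#' @param mode Failure mode the curve emulates: `"herniation"` (nucleus
#'   extrusion through an annulus defect; the stress re-rises after the drop
#'   as the endplates approach) or `"endplate"` (brittle endplate fracture).
#' @param peak_stress Effective stress at failure, MPa (> 0).
#' @param peak_displacement Displacement at the failure peak, mm.
#' @param post_peak_drop_fraction Relative stress drop after the peak, in
#'   (0, 1]; 1 means the load falls to zero.
#' @param rebound Logical; does stress re-rise after the drop? Defaults to
#'   `TRUE` for herniation and `FALSE` for endplate failure.
#'
#' @return An object of class `failure_truth`.
#' @examples
#' failure_truth("herniation", peak_stress = 2.2)
#' failure_truth("endplate", peak_stress = 4.5)
#' @export
failure_truth <- function(mode = c("herniation", "endplate"),
                          peak_stress = if (mode == "herniation") 2.2 else 4.5,
                          peak_displacement = if (mode == "herniation") 3 else 4,
                          post_peak_drop_fraction = if (mode == "herniation") 0.5 else 0.8,
                          rebound = mode == "herniation") {
  mode <- match.arg(mode)
  stopifnot(
    "peak_stress must be positive" = peak_stress > 0,
    "peak_displacement must be positive" = peak_displacement > 0,
    "post_peak_drop_fraction must lie in (0, 1]" =
      post_peak_drop_fraction > 0 && post_peak_drop_fraction <= 1
  )
  structure(
    list(
      mode = mode,
      peak_stress = peak_stress,
      peak_displacement = peak_displacement,
      post_peak_drop_fraction = post_peak_drop_fraction,
      rebound = isTRUE(rebound)
    ),
    class = "failure_truth"
  )
}
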