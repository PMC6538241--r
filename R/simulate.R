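#' Simulate a cyclic axial tension-compression test
#'
#' Generates the actuator log of a displacement-controlled cyclic axial test
#' on a motion segment. The displacement follows a cosine trajectory (the
#' record starts and ends at peak tension) whose amplitude is chosen so the
#' force extremes equal the protocol's effective-stress limits times the disc
#' cross-sectional area. The force follows the logistic-blended trilinear law
#' of the supplied [curve_truth()]; the sweep toward compression and the
#' sweep toward tension are offset by minus/plus half the hysteresis gap, and
#' Gaussian noise of `truth$noise_sd` is added to the force channel.
#'
#' @param protocol A [loading_protocol()].
#' @param truth A [curve_truth()] (axial units: mm, N, N/mm).
#' @param seed Integer seed; identical seeds give bit-identical records.
#' @param area Disc cross-sectional area in mm^2, used to convert the
#'   protocol's stress limits to force limits.
#'
#' @return A tibble of class `mech_series` with columns `time_s`,
#'   `displacement_mm`, `force_N`; the protocol, truth and area are attached
#'   as attributes.
#' @seealso [generate_torsion_cycles()], [generate_failure_ramp()],
#'   [axial_parameters()]
#' @examples
#' rec <- generate_axial_cycles(loading_protocol(n_cycles = 2), curve_truth(), seed = 1)
#' head(rec)
#' @export
generate_axial_cycles <- function(protocol = loading_protocol(),
                                  truth = curve_truth(),
                                  seed = 1L,
                                  area = cross_sectional_area(20)) {
  stopifnot(inherits(protocol, "loading_protocol"), inherits(truth, "curve_truth"))
  h <- truth$hysteresis_offset
  # Force targets at the trajectory extremes; the tensile extreme is reached
  # on the loading-toward-tension sweep (+h/2), the compressive extreme on
  # the loading-toward-compression sweep (-h/2), so the recorded extremes hit
  # the stress limits exactly.
  d_max <- trilinear_invert(protocol$tension_limit * area - h / 2, truth)
  d_min <- trilinear_invert(protocol$compression_limit * area + h / 2, truth)
  sim_cycles(protocol, truth, seed, d_min, d_max,
             cols = c("time_s", "displacement_mm", "force_N"), kind = "axial",
             area = area)
}

#' Simulate a cyclic torsion test
#'
#' As [generate_axial_cycles()], with rotation sweeping +/- the protocol's
#' `rotation_amplitude` (degrees) and torque in N mm. Clockwise rotation is
#' negative, counterclockwise positive; the clockwise and counterclockwise
#' flank stiffnesses are set independently through [torsion_truth()].
#'
#' @inheritParams generate_axial_cycles
#' @param truth A [torsion_truth()] (degrees, N mm, N mm/deg).
#' @return A tibble of class `mech_series` with columns `time_s`,
#'   `rotation_deg`, `torque_Nmm`.
#' @examples
#' rec <- generate_torsion_cycles(loading_protocol(n_cycles = 2), torsion_truth(), seed = 1)
#' range(rec$rotation_deg)
#' @export
generate_torsion_cycles <- function(protocol = loading_protocol(),
                                    truth = torsion_truth(),
                                    seed = 1L) {
  stopifnot(inherits(protocol, "loading_protocol"), inherits(truth, "curve_truth"))
  a <- protocol$rotation_amplitude
  sim_cycles(protocol, truth, seed, -a, a,
             cols = c("time_s", "rotation_deg", "torque_Nmm"), kind = "torsion",
             area = NA_real_)
}

# Shared cyclic simulator: cosine primary trajectory between d_min and d_max,
# blended-trilinear response, per-sweep hysteresis offset, seeded noise.
sim_cycles <- function(protocol, truth, seed, d_min, d_max, cols, kind, area) {
  n <- protocol$n_cycles * protocol$samples_per_cycle
  tt <- seq(0, protocol$n_cycles / protocol$frequency, length.out = n + 1)
  theta <- 2 * pi * protocol$frequency * tt
  mid <- (d_max + d_min) / 2
  amp <- (d_max - d_min) / 2
  d <- mid + amp * cos(theta)
  # +1 on the loading-toward-tension (primary increasing) sweep, -1 on the
  # loading-toward-compression sweep; extrema take the sign of their side so
  # the recorded force extremes sit on the loading limbs.
  s_dir <- dplyr::case_when(
    sin(theta) < -1e-9 ~ 1,
    sin(theta) > 1e-9 ~ -1,
    .default = sign(cos(theta))
  )
  base <- trilinear_response(d, truth) + s_dir * truth$hysteresis_offset / 2
  noise <- withr::with_seed(seed, stats::rnorm(n + 1, 0, truth$noise_sd))
  out <- tibble::tibble(!!cols[1] := tt, !!cols[2] := d, !!cols[3] := base + noise)
  new_mech_series(out, kind = kind, protocol = protocol, truth = truth, area = area)
}

new_mech_series <- function(x, kind, ...) {
  attr(x, "kind") <- kind
  extras <- list(...)
  for (nm in names(extras)) attr(x, nm) <- extras[[nm]]
  class(x) <- c("mech_series", class(x))
  x
}

#' Simulate a compression-to-failure ramp
#'
#' Produces the force-displacement record of a displacement-controlled ramp
#' to failure. The stress rises smoothly to `truth$peak_stress` at
#' `truth$peak_displacement` (a rounded characteristic peak), drops by
#' `truth$post_peak_drop_fraction` over a short displacement interval, and
#' then either re-rises (`rebound = TRUE`, the soft-tissue extrusion
#' signature of nucleus herniation, capped below the peak) or continues a
#' gentle decline (brittle endplate fracture). Force = stress x area.
#'
#' @inheritParams generate_axial_cycles
#' @param truth A [failure_truth()].
#' @param rate Ramp rate in mm/min.
#' @param sampling_hz Sampling frequency in Hz.
#' @param noise_sd Force noise SD in N; default 0.5% of the peak force.
#' @return A tibble of class `mech_series` (`kind = "failure"`) with columns
#'   `time_s`, `displacement_mm`, `force_N`.
#' @examples
#' ramp <- generate_failure_ramp(failure_truth("herniation"), area = 300, seed = 1)
#' detect_failure(ramp, area = 300)
#' @export
generate_failure_ramp <- function(truth = failure_truth("herniation"),
                                  area = cross_sectional_area(20),
                                  seed = 1L,
                                  rate = 2,
                                  sampling_hz = 5,
                                  noise_sd = NULL) {
  stopifnot(inherits(truth, "failure_truth"), area > 0)
  if (is.null(noise_sd)) noise_sd <- 0.005 * truth$peak_stress * area
  dp <- truth$peak_displacement
  drop_width <- if (truth$mode == "herniation") 0.10 * dp else 0.05 * dp
  tail_span <- 1.5
  d_end <- dp + drop_width + tail_span
  speed <- rate / 60 # mm/s
  tt <- seq(0, d_end / speed, by = 1 / sampling_hz)
  d <- speed * tt
  stress <- failure_stress_curve(d, truth, drop_width)
  noise <- withr::with_seed(seed, stats::rnorm(length(d), 0, noise_sd))
  out <- tibble::tibble(time_s = tt, displacement_mm = d,
                        force_N = stress * area + noise)
  new_mech_series(out, kind = "failure", truth = truth, area = area)
}

failure_stress_curve <- function(d, truth, drop_width) {
  peak <- truth$peak_stress
  dp <- truth$peak_displacement
  drop <- truth$post_peak_drop_fraction
  floor_stress <- peak * (1 - drop)
  smoothstep <- function(u) {
    u <- pmin(pmax(u, 0), 1)
    u^2 * (3 - 2 * u)
  }
  x <- d / dp
  rise <- peak * (2 * pmin(x, 1) - pmin(x, 1)^2) # zero slope at the peak
  s <- rise
  after <- d > dp
  s[after] <- peak - peak * drop * smoothstep((d[after] - dp) / drop_width)
  tail <- d > dp + drop_width
  if (any(tail)) {
    dt <- d[tail] - (dp + drop_width)
    if (truth$rebound) {
      target <- min(0.95 * peak, floor_stress + 0.3 * peak)
      span <- max(d) - (dp + drop_width)
      s[tail] <- floor_stress + (target - floor_stress) * dt / max(span, 1e-9)
    } else {
      s[tail] <- pmax(floor_stress - 0.05 * peak * dt, 0)
    }
  }
  s
}

#' Simulate digitized sagittal endplate profiles
#'
#' Emulates the point lists produced by manually tracing the superior and
#' inferior endplates of a disc on a sagittal radiograph. Both endplates are
#' parabolic arcs over a common lateral span, placed so that the exact mean
#' vertical separation of the continuous curves equals `mean_height`;
#' `curvature_depth` is the total centre-to-edge variation of the separation
#' (0 gives flat parallel plates). Coordinates are reported in pixels with a
#' `scale` mm/pixel sidecar, matching hand-digitized exports. The lateral
#' sample positions are jittered (seeded) and optional Gaussian digitization
#' noise can be added to the vertical coordinates.
#'
#' @param mean_height True mean disc height in mm (> 0).
#' @param curvature_depth Edge-minus-centre separation variation in mm (>= 0).
#' @param scale Image scale in mm per pixel.
#' @param n_points Points per polyline.
#' @param seed Integer seed.
#' @param span Lateral extent of the traced region in mm.
#' @param noise_sd_px SD of vertical digitization noise in pixels.
#' @return An object of class `endplate_profile`: a list with tibbles
#'   `superior` and `inferior` (columns `x_px`, `y_px`) and
#'   `scale_mm_per_px`.
#' @examples
#' prof <- generate_endplate_profiles(8, curvature_depth = 1, seed = 1)
#' average_disc_height(prof)
#' @export
generate_endplate_profiles <- function(mean_height,
                                       curvature_depth = 1,
                                       scale = 0.1,
                                       n_points = 40,
                                       seed = 1L,
                                       span = 20,
                                       noise_sd_px = 0) {
  stopifnot(
    "mean_height must be positive" = mean_height > 0,
    "curvature_depth must be >= 0" = curvature_depth >= 0,
    "scale must be positive" = scale > 0,
    n_points >= 2
  )
  h_px <- mean_height / scale
  depth_px <- curvature_depth / scale
  span_px <- span / scale
  centre <- 5 * h_px # arbitrary vertical placement on the "image"
  # separation(u) = h + depth * ((2u-1)^2 - 1/3); the (2u-1)^2 term has mean
  # 1/3 on [0,1], so the continuous mean separation is exactly h.
  sep_px <- function(u) h_px + depth_px * ((2 * u - 1)^2 - 1 / 3)
  withr::with_seed(seed, {
    sample_u <- function() {
      u <- seq(0, 1, length.out = n_points)
      jit <- stats::runif(n_points, -0.2, 0.2) / (n_points - 1)
      jit[c(1, n_points)] <- 0
      sort(u + jit)
    }
    u_s <- sample_u()
    u_i <- sample_u()
    superior <- tibble::tibble(
      x_px = u_s * span_px,
      y_px = centre + sep_px(u_s) / 2 + stats::rnorm(n_points, 0, noise_sd_px)
    )
    inferior <- tibble::tibble(
      x_px = u_i * span_px,
      y_px = centre - sep_px(u_i) / 2 + stats::rnorm(n_points, 0, noise_sd_px)
    )
  })
  structure(
    list(superior = superior, inferior = inferior, scale_mm_per_px = scale),
    class = "endplate_profile"
  )
}

#' Cohort specification for parameter-level simulation
#'
#' Describes one experimental group for [generate_cohort()]: `n` specimens
#' whose intact parameter values are jittered around a baseline
#' (log-normal-free multiplicative jitter with coefficient of variation
#' `intact_cv`) and whose treated values apply a percent change drawn from
#' Normal(`pct_mean`, `pct_sd`) per specimen and parameter.
#'
#' @param group Group label.
#' @param n Specimens in the group (>= 1).
#' @param pct_mean Mean percent change, scalar or named per parameter.
#' @param pct_sd SD of the percent change (>= 0), scalar or named.
#' @param intact_cv Coefficient of variation of the intact jitter.
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @examples
#' cohort_spec("defect", n = 10, pct_mean = 6.96, pct_sd = 5.93)
#' @export
cohort_spec <- function(group, n, pct_mean, pct_sd, intact_cv = 0.10, seed = 1L) {
  stopifnot(
    "n must be >= 1" = n >= 1,
    "pct_sd must be >= 0" = all(pct_sd >= 0),
    "intact_cv must be >= 0" = intact_cv >= 0
  )
  structure(
    list(group = group, n = as.integer(n), pct_mean = pct_mean,
         pct_sd = pct_sd, intact_cv = intact_cv, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Simulate paired intact/treated parameter sets for a cohort
#'
#' Draws, for each specimen, intact parameter values jittered around
#' `baseline` and treated values `intact * (1 + pct/100)` with
#' `pct ~ Normal(pct_mean, pct_sd)`, the design used to emulate a reported
#' group-level percent change (e.g. a 6.96 +/- 5.93% change in compressive
#' stiffness after a 4-mm annulus defect).
#'
#' @param spec A [cohort_spec()].
#' @param baseline Named numeric vector of intact parameter values.
#' @return A tibble with one row per specimen x parameter: `specimen`,
#'   `group`, `parameter`, `intact`, `treated`, `ratio`, `pct_change`.
#' @examples
#' base <- c(compressive_stiffness = 300, tensile_stiffness = 150)
#' generate_cohort(cohort_spec("defect", 5, 6.96, 5.93), base)
#' @export
generate_cohort <- function(spec, baseline) {
  stopifnot(inherits(spec, "cohort_spec"), is.numeric(baseline),
            !is.null(names(baseline)))
  pars <- names(baseline)
  mean_vec <- expand_by_parameter(spec$pct_mean, pars, "pct_mean")
  sd_vec <- expand_by_parameter(spec$pct_sd, pars, "pct_sd")
  withr::with_seed(spec$seed, {
    grid <- tidyr::expand_grid(specimen = seq_len(spec$n), parameter = pars)
    intact <- baseline[grid$parameter] *
      (1 + stats::rnorm(nrow(grid), 0, spec$intact_cv))
    pct <- stats::rnorm(nrow(grid), mean_vec[grid$parameter], sd_vec[grid$parameter])
  })
  tibble::tibble(
    specimen = paste0(spec$group, "_", sprintf("%02d", grid$specimen)),
    group = spec$group,
    parameter = grid$parameter,
    intact = unname(intact),
    treated = unname(intact * (1 + pct / 100)),
    ratio = unname(1 + pct / 100),
    pct_change = unname(pct)
  )
}

expand_by_parameter <- function(x, pars, what) {
  if (length(x) == 1 && is.null(names(x))) {
    stats::setNames(rep(x, length(pars)), pars)
  } else {
    if (!all(pars %in% names(x))) {
      stop(sprintf("%s must be a scalar or named for every parameter", what),
           call. = FALSE)
    }
    x[pars]
  }
}
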