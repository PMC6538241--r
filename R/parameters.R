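#' Axial biomechanical parameters of the last loading cycle
#'
#' Assembles the five axial outcome parameters from a cyclic
#' force-displacement record: range of motion, compressive and tensile
#' stiffness (top-fraction limb regressions, see [limb_stiffness()]), and the
#' neutral-zone length and stiffness from the adaptive moving-window fit
#' ([find_neutral_zone()]).
#'
#' The neutral-zone search domain is configurable. The default, `"sweep"`,
#' runs the fit along the cycle's first full sweep - a single continuous
#' traversal from one displacement extreme to the other that contains the
#' entire low-stiffness region. The alternative, `"loading"`, concatenates
#' the tension-side loading portion with the compression-side loading
#' portion; because the two portions come from different halves of the
#' hysteresis loop, that domain carries a force discontinuity equal to the
#' hysteresis gap at the splice, and is provided for comparison only (see
#' the methods vignette).
#'
#' @param segment A [cycle_segment][extract_last_cycle()] from an axial test.
#' @param window,se_growth,se_type Passed to [find_neutral_zone()].
#' @param fraction Passed to [limb_stiffness()].
#' @param nz_domain `"sweep"` (default) or `"loading"`; see Details.
#' @return An object of class `disc_params` with a `parameters` tibble
#'   (`range_of_motion` mm, `compressive_stiffness` N/mm,
#'   `tensile_stiffness` N/mm, `nz_length` mm, `nz_stiffness` N/mm), the
#'   underlying `nz_fit` and the segment.
#' @examples
#' rec <- generate_axial_cycles(loading_protocol(n_cycles = 2),
#'                              curve_truth(noise_sd = 0), seed = 1)
#' fit <- axial_parameters(extract_last_cycle(rec))
#' tidy(fit)
#' @export
axial_parameters <- function(segment, window = 15, se_growth = 0.10,
                             fraction = 0.20, se_type = "residual",
                             nz_domain = c("sweep", "loading")) {
  stopifnot(inherits(segment, "cycle_segment"))
  nz_domain <- match.arg(nz_domain)
  rom <- range_of_motion(segment)
  comp <- limb_stiffness(segment, "compressive", fraction)
  tens <- limb_stiffness(segment, "tensile", fraction)
  nz <- find_neutral_zone(nz_curve(segment, nz_domain), window, se_growth, se_type)
  params <- tibble::tibble(
    parameter = c("range_of_motion", "compressive_stiffness",
                  "tensile_stiffness", "nz_length", "nz_stiffness"),
    value = c(rom, comp, tens, nz$nz_length, nz$nz_stiffness),
    unit = c("mm", "N/mm", "N/mm", "mm", "N/mm")
  )
  new_disc_params("axial", params, nz, segment,
                  list(window = window, se_growth = se_growth,
                       fraction = fraction, se_type = se_type,
                       nz_domain = nz_domain))
}

#' Torsional biomechanical parameters of the last loading cycle
#'
#' Assembles the torsional outcomes from a cyclic torque-rotation record:
#' clockwise and counterclockwise stiffness (top-fraction limb regressions),
#' their average as the torsional stiffness, the torque range (total torque
#' developed between the positive and negative rotation endpoints of the
#' last cycle, taken on the loading limbs by default), and the torsional
#' neutral-zone length and stiffness.
#'
#' @inheritParams axial_parameters
#' @param segment A [cycle_segment][extract_last_cycle()] from a torsion test.
#' @param torque_range_limb `"loading"` (default) or `"unloading"`: which limb
#'   supplies the torque at each rotation endpoint.
#' @return An object of class `disc_params` with parameters
#'   `torsional_stiffness`, `cw_stiffness`, `ccw_stiffness` (N mm/deg),
#'   `torque_range` (N mm), `nz_length` (deg), `nz_stiffness` (N mm/deg).
#' @examples
#' rec <- generate_torsion_cycles(loading_protocol(n_cycles = 2),
#'                                torsion_truth(noise_sd = 0), seed = 1)
#' tidy(torsional_parameters(extract_last_cycle(rec)))
#' @export
torsional_parameters <- function(segment, window = 15, se_growth = 0.10,
                                 fraction = 0.20, se_type = "residual",
                                 nz_domain = c("sweep", "loading"),
                                 torque_range_limb = c("loading", "unloading")) {
  stopifnot(inherits(segment, "cycle_segment"))
  nz_domain <- match.arg(nz_domain)
  torque_range_limb <- match.arg(torque_range_limb)
  cw <- limb_stiffness(segment, "cw", fraction)
  ccw <- limb_stiffness(segment, "ccw", fraction)
  down <- sweep_points(segment, "down")
  up <- sweep_points(segment, "up")
  if (torque_range_limb == "loading") {
    # +amplitude is reached loading counterclockwise, -amplitude clockwise
    t_pos <- up$response[which.max(up$primary)]
    t_neg <- down$response[which.min(down$primary)]
  } else {
    t_pos <- down$response[which.max(down$primary)]
    t_neg <- up$response[which.min(up$primary)]
  }
  nz <- find_neutral_zone(nz_curve(segment, nz_domain), window, se_growth, se_type)
  params <- tibble::tibble(
    parameter = c("torsional_stiffness", "cw_stiffness", "ccw_stiffness",
                  "torque_range", "nz_length", "nz_stiffness"),
    value = c((cw + ccw) / 2, cw, ccw, abs(t_pos - t_neg),
              nz$nz_length, nz$nz_stiffness),
    unit = c("N.mm/deg", "N.mm/deg", "N.mm/deg", "N.mm", "deg", "N.mm/deg")
  )
  new_disc_params("torsion", params, nz, segment,
                  list(window = window, se_growth = se_growth,
                       fraction = fraction, se_type = se_type,
                       nz_domain = nz_domain, torque_range_limb = torque_range_limb))
}

# Neutral-zone search domain (see axial_parameters() Details).
nz_curve <- function(segment, nz_domain) {
  if (nz_domain == "sweep") {
    segment$data[segment$data$sweep == "first", c("primary", "response")]
  } else {
    mid <- (max(segment$data$primary) + min(segment$data$primary)) / 2
    up <- sweep_points(segment, "up")
    down <- sweep_points(segment, "down")
    tension_loading <- up[up$primary >= mid, , drop = FALSE]
    compression_loading <- down[down$primary <= mid, , drop = FALSE]
    # traversal order: from peak tension down through the neutral position
    out <- rbind(tension_loading[rev(seq_len(nrow(tension_loading))), ],
                 compression_loading)
    out[, c("primary", "response")]
  }
}

new_disc_params <- function(kind, parameters, nz, segment, settings) {
  structure(
    list(kind = kind, parameters = parameters, nz = nz, segment = segment,
         settings = settings),
    class = "disc_params"
  )
}

#' Analyze a cyclic axial record end to end
#'
#' Convenience wrapper: [extract_last_cycle()] then [axial_parameters()].
#'
#' @param series A cyclic axial time-series data frame.
#' @param ... Passed to [axial_parameters()].
#' @return A `disc_params` object.
#' @export
analyze_axial <- function(series, ...) {
  axial_parameters(extract_last_cycle(series), ...)
}

#' Analyze a cyclic torsion record end to end
#'
#' Convenience wrapper: [extract_last_cycle()] then [torsional_parameters()].
#'
#' @param series A cyclic torsion time-series data frame.
#' @param ... Passed to [torsional_parameters()].
#' @return A `disc_params` object.
#' @export
analyze_torsion <- function(series, ...) {
  torsional_parameters(extract_last_cycle(series), ...)
}

#' @export
print.disc_params <- function(x, ...) {
  cat(sprintf("<disc_params: %s>\n", x$kind))
  print(x$parameters)
  invisible(x)
}

#' Tidy a parameter or neutral-zone fit into a tibble
#'
#' @param x A `disc_params` or `nz_fit` object.
#' @param ... Unused.
#' @return A tibble: one row per parameter (`disc_params`) or one row
#'   describing the fitted region (`nz_fit`).
#' @method tidy disc_params
#' @export
tidy.disc_params <- function(x, ...) {
  dplyr::mutate(x$parameters, kind = x$kind, .before = 1)
}

#' @rdname tidy.disc_params
#' @method tidy nz_fit
#' @export
tidy.nz_fit <- function(x, ...) {
  tibble::tibble(
    start = x$start, end = x$end, n = x$n,
    slope = x$slope, std_error = x$se,
    nz_length = x$nz_length, nz_stiffness = x$nz_stiffness
  )
}

#' One-row fit summary
#'
#' @param x A `disc_params` object.
#' @param ... Unused.
#' @return A one-row tibble of quality-control quantities: samples in the
#'   cycle, complete cycles found, and the neutral-zone fit diagnostics.
#' @method glance disc_params
#' @export
glance.disc_params <- function(x, ...) {
  tibble::tibble(
    kind = x$kind,
    samples_per_cycle = nrow(x$segment$data),
    n_cycles_found = x$segment$n_cycles_found,
    nz_points = x$nz$n,
    nz_seed_se = x$nz$seed_se,
    nz_se = x$nz$se
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
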