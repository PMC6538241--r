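#' Plot a cyclic record's last-cycle analysis
#'
#' Force-displacement (or torque-rotation) loop of the analyzed cycle with
#' the neutral-zone region highlighted and its fitted slope drawn.
#'
#' @param object A [disc_params][axial_parameters()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot disc_params
#' @export
autoplot.disc_params <- function(object, ...) {
  seg <- object$segment$data
  nz <- object$nz
  units <- mech_units(object$kind)
  nz_pts <- nz$curve[nz$start:nz$end, ]
  mid_x <- mean(range(nz_pts$primary))
  mid_y <- mean(nz_pts$response)
  ggplot2::ggplot(seg, ggplot2::aes(x = .data$primary, y = .data$response)) +
    ggplot2::geom_path(ggplot2::aes(linetype = .data$sweep), colour = "grey40") +
    ggplot2::geom_point(data = nz_pts, colour = "#D55E00", size = 0.8) +
    ggplot2::geom_abline(slope = nz$slope,
                         intercept = mid_y - nz$slope * mid_x,
                         colour = "#D55E00", linetype = 2) +
    ggplot2::labs(
      x = sprintf("primary (%s)", units[["primary"]]),
      y = sprintf("response (%s)", units[["response"]]),
      title = sprintf("%s cycle: NZ length %.3g %s, NZ stiffness %.3g %s",
                      object$kind, nz$nz_length, units[["primary"]],
                      nz$nz_stiffness, units[["stiffness"]])
    ) +
    ggplot2::theme_minimal()
}

#' Plot a failure ramp with its detected peak
#'
#' @param ramp A failure-ramp time-series data frame.
#' @param area Disc cross-sectional area in mm^2.
#' @param result Optional [detect_failure()] result; computed when omitted.
#' @param ... Passed to [detect_failure()] when `result` is missing.
#' @return A ggplot object.
#' @export
plot_failure <- function(ramp, area, result = NULL, ...) {
  if (is.null(result)) result <- detect_failure(ramp, area, ...)
  ch <- mech_channels(ramp)
  df <- tibble::tibble(displacement = ch$primary,
                       stress = effective_stress(ch$response, area))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$displacement, y = .data$stress)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::labs(x = "displacement (mm)", y = "effective stress (MPa)") +
    ggplot2::theme_minimal()
  if (!is.na(result$peak_index)) {
    p <- p +
      ggplot2::annotate("point", x = df$displacement[result$peak_index],
                        y = result$failure_strength, colour = "#D55E00", size = 2) +
      ggplot2::labs(title = sprintf("failure: %.2f MPa, mode %s (heuristic)",
                                    result$failure_strength, result$failure_mode))
  } else {
    p <- p + ggplot2::labs(title = "no qualifying failure peak")
  }
  p
}

#' Plot digitized endplate profiles
#'
#' @param profile An [endplate_profile][generate_endplate_profiles()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_endplates <- function(profile, ...) {
  df <- dplyr::bind_rows(
    dplyr::mutate(profile$superior, endplate = "superior"),
    dplyr::mutate(profile$inferior, endplate = "inferior")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_px, y = .data$y_px,
                                   colour = .data$endplate)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "x (px)", y = "y (px)",
      title = sprintf("mean disc height %.2f mm (scale %.3g mm/px)",
                      average_disc_height(profile), profile$scale_mm_per_px)
    ) +
    ggplot2::theme_minimal()
}

#' Plot group summaries of a simulated cohort
#'
#' Mean +/- SD of the normalized ratio per group and parameter, with the
#' individual specimen ratios overlaid - the standard presentation of
#' intact-normalized biomechanical outcomes.
#'
#' @param cohort A [study_cohort][run_study()].
#' @param channel `"axial"` or `"torsion"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_cohort <- function(cohort, channel = "axial", ...) {
  stopifnot(inherits(cohort, "study_cohort"))
  df <- dplyr::filter(cohort$parameters, .data$channel == !!channel)
  summ <- dplyr::summarise(
    dplyr::group_by(df, .data$group, .data$parameter),
    mean = mean(.data$ratio, na.rm = TRUE),
    sd = stats::sd(.data$ratio),
    .groups = "drop"
  )
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey75") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.25) +
    ggplot2::geom_jitter(data = df, ggplot2::aes(y = .data$ratio),
                         width = 0.1, size = 0.8, alpha = 0.6) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "treated / intact",
                  title = sprintf("%s parameters, normalized to intact", channel)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
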