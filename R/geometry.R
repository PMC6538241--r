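#' Average disc height from digitized endplate profiles
#'
#' Mean vertical (axis-aligned) separation between the superior and inferior
#' endplate polylines, evaluated by linear interpolation of both polylines on
#' a dense common grid over their lateral overlap and converted to mm with
#' the image scale. Averaging over the full overlap is what handles the
#' convex curvature of bovine endplates.
#'
#' @param profile An [endplate_profile][generate_endplate_profiles()], or a
#'   list with elements `superior`, `inferior` (data frames with `x_px`,
#'   `y_px`) and `scale_mm_per_px`.
#' @param n_grid Number of interpolation points over the overlap.
#' @return Mean disc height in mm.
#' @examples
#' prof <- generate_endplate_profiles(8, curvature_depth = 0, seed = 1)
#' average_disc_height(prof)
#' @export
average_disc_height <- function(profile, n_grid = 1000) {
  sup <- profile$superior
  inf <- profile$inferior
  scale <- profile$scale_mm_per_px
  stopifnot(
    "scale must be positive" = scale > 0,
    "each polyline needs >= 2 points" = nrow(sup) >= 2 && nrow(inf) >= 2,
    "polyline x must be strictly increasing" =
      all(diff(sup$x_px) > 0) && all(diff(inf$x_px) > 0)
  )
  lo <- max(min(sup$x_px), min(inf$x_px))
  hi <- min(max(sup$x_px), max(inf$x_px))
  if (hi <= lo) stop("endplate polylines have no lateral overlap", call. = FALSE)
  grid <- seq(lo, hi, length.out = n_grid)
  ys <- stats::approx(sup$x_px, sup$y_px, xout = grid)$y
  yi <- stats::approx(inf$x_px, inf$y_px, xout = grid)$y
  mean(abs(ys - yi)) * scale
}

#' Disc height loss as effective engineering strain
#'
#' The axial deformation measured at the end of the cyclic loading period
#' divided by the initial disc height, as a percentage. Positive values are
#' height loss.
#'
#' @param initial_height Initial disc height in mm (> 0), from the pre-test
#'   radiograph.
#' @param end_of_test_axial_deformation Axial deformation at the final sample
#'   of cyclic loading, mm, relative to the post-preload reference position.
#' @return Height loss in percent.
#' @examples
#' disc_height_loss(10, 0.9)
#' @export
disc_height_loss <- function(initial_height, end_of_test_axial_deformation) {
  stopifnot("initial_height must be positive" = initial_height > 0)
  100 * end_of_test_axial_deformation / initial_height
}

#' Disc cross-sectional area
#'
#' Circular convention from a single diameter (bovine caudal discs are close
#' to circular); supplying a second diameter switches to the elliptical
#' convention pi * d1/2 * d2/2.
#'
#' @param diameter Disc diameter in mm (> 0).
#' @param diameter2 Optional second diameter for an elliptical section.
#' @return Area in mm^2.
#' @examples
#' cross_sectional_area(20)
#' cross_sectional_area(20, 10)
#' @export
cross_sectional_area <- function(diameter, diameter2 = NULL) {
  stopifnot("diameter must be positive" = diameter > 0)
  if (is.null(diameter2)) {
    pi * (diameter / 2)^2
  } else {
    stopifnot("diameter2 must be positive" = diameter2 > 0)
    pi * (diameter / 2) * (diameter2 / 2)
  }
}
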