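#' Effective stress
#'
#' Force divided by disc cross-sectional area, in MPa (N/mm^2).
#'
#' @param force Force in N.
#' @param area Cross-sectional area in mm^2 (> 0).
#' @return Effective stress in MPa.
#' @examples
#' effective_stress(1000, cross_sectional_area(20))
#' @export
effective_stress <- function(force, area) {
  if (!all(area > 0)) stop("area must be positive", call. = FALSE)
  force / area
}

#' Detect the failure peak on a compression-to-failure ramp
#'
#' Converts force to effective stress, lightly smooths it (centred moving
#' mean of `smooth` samples; 1 disables), and scans the stress-displacement
#' curve for the first local maximum followed by a relative stress drop of at
#' least `drop_threshold` within a forward displacement window. The stress at
#' that peak is the failure strength. When `classify = TRUE`, the failure
#' mode is labelled by a heuristic standing in for the visual confirmation
#' used at the bench: `"herniation"` if the stress re-rises after the drop
#' (soft-tissue extrusion lets the endplates approach and load again),
#' `"endplate"` if the drop is terminal. The heuristic nature is flagged in
#' the result.
#'
#' @param ramp A failure-ramp time-series data frame (columns `time_s`,
#'   `displacement_mm`, `force_N`); displacement must be monotone
#'   nondecreasing.
#' @param area Disc cross-sectional area in mm^2.
#' @param drop_threshold Minimum relative stress drop that qualifies a peak
#'   (default 0.10).
#' @param classify Attach the heuristic failure-mode label?
#' @param smooth Width (samples) of the centred moving-mean stress filter.
#' @param forward_window Displacement window (mm) searched beyond a candidate
#'   peak for the qualifying drop.
#' @param rebound_margin Post-drop stress re-rise, as a fraction of the peak
#'   stress, that labels a herniation.
#' @param min_peak Candidate peaks below this fraction of the record's
#'   maximum smoothed stress are ignored, so noise wiggles on the early
#'   low-stress toe cannot qualify as failure.
#' @return An object of class `failure_result`: `failure_strength` (MPa, NA
#'   when nothing qualifies), `failure_mode` (`"herniation"`, `"endplate"`,
#'   or `"none_detected"`), `peak_index`, `drop_fraction_observed`, and
#'   `classification = "heuristic"`.
#' @examples
#' ramp <- generate_failure_ramp(failure_truth("endplate"), area = 300, seed = 2)
#' detect_failure(ramp, area = 300)
#' @export
detect_failure <- function(ramp, area, drop_threshold = 0.10, classify = TRUE,
                           smooth = 5, forward_window = 2,
                           rebound_margin = 0.05, min_peak = 0.25) {
  ch <- mech_channels(ramp)
  if (any(diff(ch$primary) < 0)) {
    stop("failure ramp displacement must be monotone nondecreasing", call. = FALSE)
  }
  stress <- effective_stress(ch$response, area)
  s <- if (smooth > 1) moving_mean(stress, smooth) else stress
  d <- ch$primary
  n <- length(s)
  peaks <- which(diff(sign(diff(s))) < 0) + 1L
  peaks <- peaks[s[peaks] >= min_peak * max(s)]
  peak_idx <- NA_integer_
  for (p in peaks) {
    ahead <- which(d > d[p] & d <= d[p] + forward_window)
    if (length(ahead) == 0) next
    # a characteristic peak dominates its forward window; otherwise a noise
    # wiggle on the rising toe would borrow the true peak's drop
    if (max(s[ahead]) > s[p]) next
    if (min(s[ahead]) <= s[p] * (1 - drop_threshold)) {
      peak_idx <- p
      break
    }
  }
  if (is.na(peak_idx)) {
    return(new_failure_result(NA_real_, "none_detected", NA_integer_, NA_real_))
  }
  after <- seq(peak_idx, n)
  trough <- after[which.min(s[after])]
  drop_obs <- (s[peak_idx] - s[trough]) / s[peak_idx]
  mode <- NA_character_
  if (classify) {
    rerise <- if (trough < n) max(s[trough:n]) - s[trough] else 0
    mode <- if (rerise >= rebound_margin * s[peak_idx]) "herniation" else "endplate"
  }
  new_failure_result(s[peak_idx], mode, peak_idx, drop_obs)
}

moving_mean <- function(x, width) {
  half <- floor(width / 2)
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

new_failure_result <- function(strength, mode, peak_idx, drop_obs) {
  structure(
    list(
      failure_strength = strength,
      failure_mode = mode,
      peak_index = peak_idx,
      drop_fraction_observed = drop_obs,
      classification = "heuristic"
    ),
    class = "failure_result"
  )
}

#' @export
print.failure_result <- function(x, ...) {
  if (identical(x$failure_mode, "none_detected")) {
    cat("<failure_result: no qualifying peak detected>\n")
  } else {
    cat(sprintf("<failure_result: %.3f MPa at sample %d, mode %s (heuristic), drop %.0f%%>\n",
                x$failure_strength, x$peak_index,
                x$failure_mode %||% "unclassified",
                100 * x$drop_fraction_observed))
  }
  invisible(x)
}

#' @rdname tidy.disc_params
#' @method tidy failure_result
#' @export
tidy.failure_result <- function(x, ...) {
  tibble::tibble(
    failure_strength = x$failure_strength,
    failure_mode = x$failure_mode,
    peak_index = x$peak_index,
    drop_fraction_observed = x$drop_fraction_observed
  )
}
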