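#' Extract the last complete loading cycle from a cyclic record
#'
#' Delimits cycles by the turning points of the primary channel (displacement
#' or rotation) rather than by nominal time and frequency, so records with
#' drift or a truncated final cycle still segment correctly. Turning points
#' are found with a reversal (zigzag) filter of prominence
#' `prominence x primary range`; a complete cycle runs between two successive
#' extrema of the same type as the record's first extremum and must close on
#' itself (the primary values at its two ends agree within
#' `closure_tol x primary range`). The last such cycle is returned, split
#' into its two sweeps.
#'
#' @param series A mechanical time-series data frame (see
#'   [generate_axial_cycles()] for the column dialects).
#' @param n_cycles,frequency Optional protocol hints; when given, the number
#'   of cycles found is checked against `n_cycles` with a message (never an
#'   error) on mismatch.
#' @param prominence Reversal threshold as a fraction of the primary range.
#' @param closure_tol Cycle-closure tolerance as a fraction of the primary
#'   range.
#' @return An object of class `cycle_segment`: the cycle's samples with a
#'   `sweep` label (`"first"`/`"second"`), the turning-point indices, the
#'   channel kind and a QC count of complete cycles found.
#' @examples
#' rec <- generate_axial_cycles(loading_protocol(n_cycles = 3), curve_truth(), seed = 1)
#' seg <- extract_last_cycle(rec)
#' range_of_motion(seg)
#' @export
extract_last_cycle <- function(series, n_cycles = NULL, frequency = NULL,
                               prominence = 0.05, closure_tol = 0.15) {
  ch <- mech_channels(series)
  kind <- attr(ch, "kind")
  if (nrow(ch) < 30) stop("record too short to segment (need >= 30 samples)", call. = FALSE)
  p <- ch$primary
  rng <- diff(range(p))
  ext <- zigzag_extrema(p, prominence * rng)
  cycles <- complete_cycles(ext, p, closure_tol * rng)
  if (nrow(cycles) == 0) {
    stop(sprintf("no complete loading cycle found (%d turning points detected)",
                 length(ext$idx)), call. = FALSE)
  }
  if (!is.null(n_cycles) && nrow(cycles) != n_cycles) {
    message(sprintf("found %d complete cycles where the protocol specifies %d",
                    nrow(cycles), n_cycles))
  }
  last <- cycles[nrow(cycles), ]
  rows <- seq(last$i_start, last$i_end)
  data <- ch[rows, , drop = FALSE]
  i_mid <- last$i_mid - last$i_start + 1L
  data$sweep <- rep(c("first", "second"), c(i_mid, nrow(data) - i_mid))
  structure(
    list(
      data = tibble::as_tibble(data),
      i_mid = i_mid,
      first_sweep_direction = if (p[last$i_mid] < p[last$i_start]) "down" else "up",
      kind = kind,
      n_cycles_found = nrow(cycles),
      indices = c(start = last$i_start, mid = last$i_mid, end = last$i_end)
    ),
    class = "cycle_segment"
  )
}

# Reversal filter: confirms a running extremum once the primary moves away
# from it by more than `thresh`; record endpoints close the sequence.
zigzag_extrema <- function(p, thresh) {
  n <- length(p)
  idx <- integer(0)
  typ <- integer(0) # +1 max, -1 min
  hi <- 1L
  lo <- 1L
  dir <- 0L
  for (i in seq_len(n)[-1]) {
    if (p[i] > p[hi]) hi <- i
    if (p[i] < p[lo]) lo <- i
    if (dir <= 0 && p[i] - p[lo] > thresh) {
      idx <- c(idx, lo); typ <- c(typ, -1L)
      dir <- 1L; hi <- i
    } else if (dir >= 0 && p[hi] - p[i] > thresh) {
      idx <- c(idx, hi); typ <- c(typ, 1L)
      dir <- -1L; lo <- i
    }
  }
  # terminal candidate: the running extremum of the unfinished sweep
  if (dir == 1L) { idx <- c(idx, hi); typ <- c(typ, 1L) }
  if (dir == -1L) { idx <- c(idx, lo); typ <- c(typ, -1L) }
  list(idx = idx, typ = typ)
}

# Complete cycles: spans between successive extrema of the same type as the
# first extremum, requiring the primary value to close on itself.
complete_cycles <- function(ext, p, tol) {
  m <- length(ext$idx)
  if (m < 3) return(tibble::tibble(i_start = integer(0), i_mid = integer(0),
                                   i_end = integer(0)))
  type0 <- ext$typ[1]
  starts <- which(ext$typ == type0)
  keep <- starts[starts + 2 <= m]
  ok <- abs(p[ext$idx[keep + 2]] - p[ext$idx[keep]]) <= tol
  keep <- keep[ok]
  tibble::tibble(
    i_start = ext$idx[keep],
    i_mid = ext$idx[keep + 1],
    i_end = ext$idx[keep + 2]
  )
}

#' Range of motion of a loading cycle
#'
#' Total primary-axis excursion (maximum minus minimum displacement or
#' rotation) over the last complete cycle.
#'
#' @param segment A [cycle_segment][extract_last_cycle()], or any mechanical
#'   time-series data frame (then the whole record is used).
#' @return Range of motion in mm (axial) or degrees (torsion).
#' @examples
#' range_of_motion(data.frame(primary = c(-1, 0.2, 1.5), response = c(-5, 0, 9)))
#' @export
range_of_motion <- function(segment) {
  p <- if (inherits(segment, "cycle_segment")) segment$data$primary
       else mech_channels(segment)$primary
  rom <- max(p) - min(p)
  if (rom == 0) warning("zero-amplitude record: range of motion is 0", call. = FALSE)
  rom
}

#' Limb stiffness from the top fraction of loading points
#'
#' Slope of the response-versus-primary regression over the points of a
#' limb's loading portion carrying the largest response magnitude (by
#' default the top 20%), reported as a positive magnitude. The compressive
#' (or clockwise) loading portion is the sweep moving toward the negative
#' primary extreme; the tensile (counterclockwise) portion the sweep moving
#' toward the positive extreme.
#'
#' @param segment A [cycle_segment][extract_last_cycle()], or a plain data
#'   frame with `primary`/`response` columns that is treated directly as one
#'   limb's loading portion.
#' @param limb One of `"compressive"`, `"tensile"`, `"cw"`, `"ccw"`. Ignored
#'   when `segment` is a plain limb data frame.
#' @param fraction Fraction of the limb's points used, ranked by response
#'   magnitude; at least 3 points are required.
#' @return Stiffness magnitude in N/mm (axial) or N mm/deg (torsion).
#' @examples
#' limb <- data.frame(primary = seq(0, 1, 0.01), response = 100 * seq(0, 1, 0.01))
#' limb_stiffness(limb)
#' @export
limb_stiffness <- function(segment,
                           limb = c("compressive", "tensile", "cw", "ccw"),
                           fraction = 0.20) {
  if (inherits(segment, "cycle_segment")) {
    limb <- match.arg(limb)
    pts <- sweep_points(segment, toward = if (limb %in% c("compressive", "cw")) "down" else "up")
    if (nrow(pts) < 10) {
      stop(sprintf("%s limb holds %d points; >= 10 required", limb, nrow(pts)),
           call. = FALSE)
    }
    # rank by signed response on the limb's own side
    ord <- if (limb %in% c("compressive", "cw")) order(pts$response)
           else order(-pts$response)
  } else {
    pts <- mech_channels(segment)
    ord <- order(-abs(pts$response))
  }
  k <- ceiling(fraction * nrow(pts))
  if (k < 3) {
    stop(sprintf("top fraction selects %d points; >= 3 required", k), call. = FALSE)
  }
  sel <- pts[ord[seq_len(k)], ]
  abs(ols_slope(sel$primary, sel$response)$slope)
}

sweep_points <- function(segment, toward) {
  first_is <- segment$first_sweep_direction
  want <- if (first_is == toward) "first" else "second"
  segment$data[segment$data$sweep == want, , drop = FALSE]
}

ols_slope <- function(x, y) {
  n <- length(x)
  mx <- mean(x)
  my <- mean(y)
  dx <- x - mx
  sxx <- sum(dx^2)
  if (sxx == 0) return(list(slope = 0, se = Inf, rse = Inf, n = n))
  slope <- sum(dx * (y - my)) / sxx
  res <- y - my - slope * dx
  sig2 <- if (n > 2) sum(res^2) / (n - 2) else 0
  list(slope = slope, se = sqrt(sig2 / sxx), rse = sqrt(sig2), n = n)
}

#' Adaptive moving-window neutral-zone fit
#'
#' Locates the low-stiffness neutral zone of a load-displacement (or
#' torque-rotation) loading traversal. A `window`-point moving linear
#' regression is computed at every position along the curve; the window with
#' the smallest slope magnitude seeds the region, which is then grown one
#' point at a time, alternating sides, accepting a point only while the
#' refitted slope standard error stays within `(1 + se_growth)` times the
#' seed window's standard error. Ties for the minimal-slope window are broken
#' by proximity to the response zero-crossing, then by the lowest start
#' index. The region's primary-axis extent is the neutral-zone length and
#' its fitted slope magnitude the neutral-zone stiffness.
#'
#' @param curve Data frame with `primary` and `response` columns, ordered
#'   along the loading traversal (time order; a non-monotone primary due to
#'   noise is left as recorded).
#' @param window Moving-window width in points (default 15).
#' @param se_growth Allowed relative growth of the standard error during
#'   expansion (default 0.10).
#' @param se_type Which standard error governs expansion: `"residual"` (the
#'   residual standard error of the window fit, the default) or `"slope"`
#'   (the standard error of the fitted slope). The residual form is the
#'   default because its baseline tracks the response noise floor, so the
#'   10% growth bound stops expansion where systematic lack of fit emerges;
#'   the slope form's baseline shrinks with window length and admits grossly
#'   nonlinear expansions on noisy records (see the methods vignette).
#' @return An object of class `nz_fit`: start/end indices, fitted slope and
#'   its standard error, the seed window and its standard error, and
#'   `nz_length`/`nz_stiffness`.
#' @examples
#' curve <- data.frame(primary = seq(-1, 1, 0.01))
#' curve$response <- trilinear_demo(curve$primary)
#' find_neutral_zone(curve)
#' @export
find_neutral_zone <- function(curve, window = 15, se_growth = 0.10,
                              se_type = c("residual", "slope")) {
  se_type <- match.arg(se_type)
  x <- curve$primary
  y <- curve$response
  n <- length(x)
  if (n < window) {
    stop(sprintf("curve has %d points; the moving window needs %d", n, window),
         call. = FALSE)
  }
  fit_se <- function(f) if (se_type == "slope") f$se else f$rse
  starts <- seq_len(n - window + 1)
  fits <- lapply(starts, function(s) ols_slope(x[s:(s + window - 1)], y[s:(s + window - 1)]))
  slopes <- vapply(fits, `[[`, numeric(1), "slope")
  seed <- pick_min_slope(slopes, y, window)
  seed_fit <- fits[[seed]]
  seed_se <- fit_se(seed_fit)
  # Resolution floor: response deviations below 0.01% of the response range
  # are treated as indistinguishable from a perfect fit. This sits well
  # below the noise floor of any physical load cell but above double
  # rounding, so exact (noise-free) curves expand across their whole linear
  # plateau instead of being stopped by machine-epsilon residuals.
  xr <- diff(range(x))
  yr <- diff(range(y))
  eps <- if (se_type == "residual") 1e-4 * yr else 1e-4 * yr / if (xr > 0) xr else 1
  limit <- (1 + se_growth) * seed_se + eps
  lo <- seed
  hi <- seed + window - 1
  alive <- c(left = lo > 1, right = hi < n)
  side <- "left"
  while (any(alive)) {
    if (!alive[[side]]) side <- setdiff(c("left", "right"), side)
    cand_lo <- if (side == "left") lo - 1 else lo
    cand_hi <- if (side == "left") hi else hi + 1
    f <- ols_slope(x[cand_lo:cand_hi], y[cand_lo:cand_hi])
    if (fit_se(f) <= limit) {
      lo <- cand_lo
      hi <- cand_hi
      alive["left"] <- lo > 1
      alive["right"] <- hi < n
    } else {
      alive[[side]] <- FALSE
    }
    side <- setdiff(c("left", "right"), side)
  }
  final <- ols_slope(x[lo:hi], y[lo:hi])
  structure(
    list(
      start = lo, end = hi, n = hi - lo + 1,
      slope = final$slope, se = final$se, rse = final$rse,
      seed_start = seed, seed_se = seed_se,
      nz_length = max(x[lo:hi]) - min(x[lo:hi]),
      nz_stiffness = abs(final$slope),
      window = window, se_growth = se_growth, se_type = se_type,
      curve = tibble::tibble(primary = x, response = y)
    ),
    class = "nz_fit"
  )
}

# Seed window choice: minimal |slope|; ties by window-centre proximity to the
# response zero-crossing, then lowest start index.
pick_min_slope <- function(slopes, y, window) {
  m <- min(abs(slopes))
  cand <- which(abs(slopes) == m)
  if (length(cand) > 1) {
    zc <- which.min(abs(y))
    centres <- cand + (window - 1) / 2
    cand <- cand[order(abs(centres - zc), cand)]
  }
  cand[1]
}

#' @export
print.nz_fit <- function(x, ...) {
  cat(sprintf("<nz_fit: points %d-%d (%d), slope %.4g, SE %.3g (%s), length %.4g>\n",
              x$start, x$end, x$n, x$slope, x$se, x$se_type, x$nz_length))
  invisible(x)
}

#' Demonstration trilinear response
#'
#' Small helper used in examples: the default [curve_truth()] law with no
#' hysteresis or noise, evaluated at `d`.
#'
#' @param d Primary positions.
#' @param truth A [curve_truth()].
#' @return Response values.
#' @export
trilinear_demo <- function(d, truth = curve_truth(noise_sd = 0, hysteresis_offset = 0)) {
  trilinear_response(d, truth)
}
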