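#' Read and write mechanical test CSV records
#'
#' The on-disk dialects mirror a servohydraulic rig export: axial and failure
#' records carry columns `time_s,displacement_mm,force_N`; torsional records
#' `time_s,rotation_deg,torque_Nmm`.
#'
#' @param path CSV file path.
#' @param kind Optional channel kind (`"axial"`, `"torsion"`, `"failure"`);
#'   inferred from the header when omitted.
#' @return `read_mechanical_csv()` returns a `mech_series` tibble;
#'   `write_mechanical_csv()` returns `path` invisibly.
#' @examples
#' path <- tempfile(fileext = ".csv")
#' rec <- generate_axial_cycles(loading_protocol(n_cycles = 2), curve_truth(), seed = 1)
#' write_mechanical_csv(rec, path)
#' head(read_mechanical_csv(path))
#' @export
read_mechanical_csv <- function(path, kind = NULL) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  if (is.null(kind)) {
    kind <- if (all(torsion_cols %in% names(x))) "torsion" else "axial"
  }
  new_mech_series(x, kind = kind)
}

#' @rdname read_mechanical_csv
#' @param series A mechanical time-series data frame.
#' @export
write_mechanical_csv <- function(series, path) {
  keep <- intersect(c(axial_cols, torsion_cols), names(series))
  readr::write_csv(as.data.frame(series)[, keep], path)
  invisible(path)
}

#' Read and write digitized endplate profiles
#'
#' Each endplate is a CSV point list with columns `x_px,y_px`; the image
#' scale travels in a JSON sidecar `{"scale_mm_per_px": <mm/px>}` stored next
#' to the superior file as `<stem>_scale.json` (or at `sidecar`).
#'
#' @param superior,inferior Paths to the two polyline CSVs.
#' @param sidecar Optional explicit sidecar path.
#' @param scale Image scale in mm/pixel; overrides the sidecar when given.
#' @return `read_endplate_profile()` returns an `endplate_profile`;
#'   `write_endplate_profile()` returns the sidecar path invisibly.
#' @examples
#' prof <- generate_endplate_profiles(8, seed = 1)
#' dir <- tempfile(); dir.create(dir)
#' write_endplate_profile(prof, file.path(dir, "sup.csv"), file.path(dir, "inf.csv"))
#' average_disc_height(read_endplate_profile(file.path(dir, "sup.csv"),
#'                                           file.path(dir, "inf.csv")))
#' @export
read_endplate_profile <- function(superior, inferior, sidecar = NULL, scale = NULL) {
  if (is.null(scale)) {
    if (is.null(sidecar)) {
      sidecar <- paste0(sub("\\.csv$", "", superior), "_scale.json")
    }
    if (!file.exists(sidecar)) {
      stop("no scale supplied and sidecar not found: ", sidecar, call. = FALSE)
    }
    scale <- jsonlite::read_json(sidecar)$scale_mm_per_px
  }
  structure(
    list(
      superior = readr::read_csv(superior, show_col_types = FALSE),
      inferior = readr::read_csv(inferior, show_col_types = FALSE),
      scale_mm_per_px = as.numeric(scale)
    ),
    class = "endplate_profile"
  )
}

#' @rdname read_endplate_profile
#' @param profile An `endplate_profile`.
#' @export
write_endplate_profile <- function(profile, superior, inferior, sidecar = NULL) {
  readr::write_csv(profile$superior, superior)
  readr::write_csv(profile$inferior, inferior)
  if (is.null(sidecar)) {
    sidecar <- paste0(sub("\\.csv$", "", superior), "_scale.json")
  }
  jsonlite::write_json(list(scale_mm_per_px = profile$scale_mm_per_px), sidecar,
                       auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Export an analysis result as a JSON record
#'
#' One JSON object per analyzed test: identifiers, the extracted parameters,
#' the neutral-zone region, and quality-control counts.
#'
#' @param x A [disc_params][axial_parameters()] object.
#' @param path Output JSON path.
#' @param test_id Identifier stored in the record.
#' @return `path`, invisibly.
#' @export
write_parameters_json <- function(x, path, test_id = "test") {
  stopifnot(inherits(x, "disc_params"))
  rec <- list(
    test_id = test_id,
    kind = x$kind,
    parameters = as.list(stats::setNames(x$parameters$value, x$parameters$parameter)),
    nz = list(start = x$nz$start, end = x$nz$end,
              slope = x$nz$slope, se = x$nz$se),
    qc = list(n_cycles_found = x$segment$n_cycles_found,
              samples_per_cycle = nrow(x$segment$data))
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
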