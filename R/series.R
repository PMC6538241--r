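# Channel handling for mechanical time series.
#
# User-facing functions accept any data frame whose columns follow one of the
# recorded dialects (axial: time_s, displacement_mm, force_N; torsion:
# time_s, rotation_deg, torque_Nmm) or the generic names time, primary,
# response. Internally everything runs on time/primary/response.

axial_cols <- c("time_s", "displacement_mm", "force_N")
torsion_cols <- c("time_s", "rotation_deg", "torque_Nmm")

mech_channels <- function(x) {
  nm <- names(x)
  if (all(axial_cols %in% nm)) {
    kind <- attr(x, "kind") %||% "axial"
    out <- tibble::tibble(time = x$time_s, primary = x$displacement_mm,
                          response = x$force_N)
  } else if (all(torsion_cols %in% nm)) {
    kind <- "torsion"
    out <- tibble::tibble(time = x$time_s, primary = x$rotation_deg,
                          response = x$torque_Nmm)
  } else if (all(c("primary", "response") %in% nm)) {
    kind <- attr(x, "kind") %||% "generic"
    out <- tibble::tibble(time = x$time %||% seq_len(nrow(x)),
                          primary = x$primary, response = x$response)
  } else {
    stop("unrecognized mechanical time-series columns: ",
         paste(nm, collapse = ", "), call. = FALSE)
  }
  if (nrow(out) >= 2 && any(diff(out$time) <= 0)) {
    stop("time must be strictly increasing", call. = FALSE)
  }
  attr(out, "kind") <- kind
  out
}

mech_units <- function(kind) {
  switch(kind,
    axial = c(primary = "mm", response = "N", stiffness = "N/mm"),
    torsion = c(primary = "deg", response = "N.mm", stiffness = "N.mm/deg"),
    c(primary = "primary", response = "response", stiffness = "response/primary")
  )
}

#' @export
print.mech_series <- function(x, ...) {
  kind <- attr(x, "kind") %||% "generic"
  cat(sprintf("<mech_series: %s, %d samples>\n", kind, nrow(x)))
  NextMethod()
}
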