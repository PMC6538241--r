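#' Normalize treated parameters to the intact state
#'
#' Every specimen is tested twice - intact first, then treated - and the
#' treated parameters are expressed relative to the intact ones. Returns the
#' elementwise ratio treated/intact and the percent change
#' `100 * (ratio - 1)`. A zero intact value leaves that parameter's ratio
#' undefined (NA, flagged) without failing.
#'
#' @param intact,treated Matching parameter sets: named numeric vectors,
#'   data frames with `parameter`/`value` columns, or
#'   [disc_params][axial_parameters()] objects.
#' @return A tibble with columns `parameter`, `intact`, `treated`, `ratio`,
#'   `pct_change`, `defined`.
#' @examples
#' normalize_to_intact(c(stiffness = 10), c(stiffness = 9))
#' @export
normalize_to_intact <- function(intact, treated) {
  a <- as_param_vector(intact)
  b <- as_param_vector(treated)
  if (!setequal(names(a), names(b))) {
    stop("intact and treated parameter sets must share the same keys", call. = FALSE)
  }
  b <- b[names(a)]
  ratio <- ifelse(a == 0, NA_real_, b / a)
  tibble::tibble(
    parameter = names(a),
    intact = unname(a),
    treated = unname(b),
    ratio = unname(ratio),
    pct_change = unname(100 * (ratio - 1)),
    defined = unname(a != 0)
  )
}

as_param_vector <- function(x) {
  if (inherits(x, "disc_params")) {
    stats::setNames(x$parameters$value, x$parameters$parameter)
  } else if (is.data.frame(x) && all(c("parameter", "value") %in% names(x))) {
    stats::setNames(x$value, x$parameter)
  } else if (is.numeric(x) && !is.null(names(x))) {
    x
  } else {
    stop("expected a named numeric vector, a parameter/value data frame, or a disc_params object",
         call. = FALSE)
  }
}

#' Study design for a simulated cohort
#'
#' Declares the experimental groups, their sizes, and the ground-truth
#' perturbations the treatment applies to each group in simulation. A
#' perturbation row states that, for specimens of `group`, the named
#' constitutive-truth `parameter` of the given `channel` is multiplied by
#' `1 + pct/100` with `pct ~ Normal(pct_mean, pct_sd)` drawn per specimen.
#'
#' @param groups A tibble/data frame with columns `group` and `n`, or a named
#'   integer vector of group sizes.
#' @param perturbations Optional tibble with columns `group`, `channel`
#'   (`"axial"` or `"torsion"`), `parameter` (a [curve_truth()] field),
#'   `pct_mean`, `pct_sd`.
#' @param failure Optional tibble with columns `group`, `mode`,
#'   `peak_stress`, giving each group's failure ground truth; groups absent
#'   from it use `failure_truth("herniation")`.
#' @param height_loss Optional tibble with columns `group`,
#'   `deformation_mean_mm`, `deformation_sd_mm` for the end-of-test axial
#'   deformation; defaults to 0.8 +/- 0.15 mm for every group.
#' @return An object of class `study_design`.
#' @examples
#' study_design(c(intact = 4, defect = 4),
#'   perturbations = tibble::tibble(group = "defect", channel = "axial",
#'     parameter = "tensile_stiffness", pct_mean = -30, pct_sd = 0))
#' @export
study_design <- function(groups, perturbations = NULL, failure = NULL,
                         height_loss = NULL) {
  if (is.numeric(groups) && !is.null(names(groups))) {
    groups <- tibble::tibble(group = names(groups), n = as.integer(groups))
  }
  stopifnot(
    all(c("group", "n") %in% names(groups)),
    "group sizes must be >= 1" = all(groups$n >= 1)
  )
  if (!is.null(perturbations)) {
    stopifnot(all(c("group", "channel", "parameter", "pct_mean", "pct_sd") %in%
                    names(perturbations)))
    bad <- setdiff(perturbations$group, groups$group)
    if (length(bad)) stop("perturbations reference undeclared groups: ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(
    list(groups = tibble::as_tibble(groups),
         perturbations = perturbations,
         failure = failure,
         height_loss = height_loss),
    class = "study_design"
  )
}

#' Run a full simulated study
#'
#' End-to-end emulation of the paired testing sequence: for every specimen,
#' generate and analyze intact axial and torsion records, apply the group's
#' truth perturbation, generate and analyze the treated records, normalize
#' treated to intact, then run the treated specimen to failure and compute
#' radiographic height loss. Fully seeded: the cohort is a pure function of
#' (design, protocol, truths, seed). A stage failure is recorded on the
#' specimen and does not abort the cohort.
#'
#' @param design A [study_design()].
#' @param protocol A [loading_protocol()].
#' @param seed Integer master seed; per-specimen sub-seeds derive from it.
#' @param axial_truth Baseline axial [curve_truth()].
#' @param torsional_truth Baseline [torsion_truth()].
#' @param area Disc cross-sectional area, mm^2.
#' @param intact_cv Specimen-to-specimen coefficient of variation applied
#'   multiplicatively to the baseline truth stiffnesses and neutral-zone
#'   width; the same specimen truth underlies both test rounds, so it
#'   cancels in the normalized ratios.
#' @param endplate_height Mean disc height (mm) of the simulated pre-test
#'   radiograph.
#' @param ... Passed to [axial_parameters()] and [torsional_parameters()]
#'   (e.g. `window`, `se_growth`, `fraction`).
#' @return An object of class `study_cohort`: `parameters` (one row per
#'   specimen x channel x parameter with intact, treated, ratio, percent
#'   change) and `specimens` (per-specimen failure strength/mode, disc
#'   height loss, and any stage error).
#' @examples
#' des <- study_design(c(defect = 2),
#'   perturbations = tibble::tibble(group = "defect", channel = "axial",
#'     parameter = "tensile_stiffness", pct_mean = -30, pct_sd = 0))
#' coh <- run_study(des, loading_protocol(n_cycles = 2, samples_per_cycle = 120),
#'                  seed = 1, axial_truth = curve_truth(noise_sd = 0),
#'                  torsional_truth = torsion_truth(noise_sd = 0))
#' summarize_groups(coh)
#' @export
run_study <- function(design, protocol = loading_protocol(), seed = 1L,
                      axial_truth = curve_truth(),
                      torsional_truth = torsion_truth(),
                      area = cross_sectional_area(20),
                      intact_cv = 0.08,
                      endplate_height = 8,
                      ...) {
  stopifnot(inherits(design, "study_design"))
  roster <- tidyr::uncount(design$groups, .data$n, .id = "replicate")
  roster$specimen <- sprintf("%s_%02d", roster$group, roster$replicate)
  n_spec <- nrow(roster)
  seeds <- withr::with_seed(seed, matrix(sample.int(.Machine$integer.max - 1, n_spec * 8),
                                         nrow = n_spec))
  results <- purrr::pmap(
    list(roster$group, roster$specimen, seq_len(n_spec)),
    function(group, specimen, i) {
      tryCatch(
        simulate_specimen(group, specimen, seeds[i, ], design, protocol,
                          axial_truth, torsional_truth, area, intact_cv,
                          endplate_height, ...),
        error = function(e) {
          list(parameters = NULL,
               specimen_row = tibble::tibble(
                 specimen = specimen, group = group,
                 failure_strength = NA_real_, failure_mode = NA_character_,
                 initial_height_mm = NA_real_, disc_height_loss_pct = NA_real_,
                 error = conditionMessage(e)))
        }
      )
    }
  )
  structure(
    list(
      parameters = dplyr::bind_rows(purrr::map(results, "parameters")),
      specimens = dplyr::bind_rows(purrr::map(results, "specimen_row")),
      seed = seed
    ),
    class = "study_cohort"
  )
}

simulate_specimen <- function(group, specimen, sub_seeds, design, protocol,
                              axial_truth, torsional_truth, area, intact_cv,
                              endplate_height, ...) {
  jitter_fields <- c("compressive_stiffness", "tensile_stiffness",
                     "nz_stiffness", "nz_half_width", "hysteresis_offset")
  ax_int <- jitter_truth(axial_truth, jitter_fields, intact_cv, sub_seeds[1])
  to_int <- jitter_truth(torsional_truth, jitter_fields, intact_cv, sub_seeds[2])
  pert <- design$perturbations
  ax_trt <- perturb_truth(ax_int, pert, group, "axial", sub_seeds[3])
  to_trt <- perturb_truth(to_int, pert, group, "torsion", sub_seeds[3] + 1L)

  intact_ax <- analyze_axial(generate_axial_cycles(protocol, ax_int, sub_seeds[4], area), ...)
  intact_to <- analyze_torsion(generate_torsion_cycles(protocol, to_int, sub_seeds[5]), ...)
  treat_ax <- analyze_axial(generate_axial_cycles(protocol, ax_trt, sub_seeds[6], area), ...)
  treat_to <- analyze_torsion(generate_torsion_cycles(protocol, to_trt, sub_seeds[7]), ...)

  params <- dplyr::bind_rows(
    dplyr::mutate(normalize_to_intact(intact_ax, treat_ax), channel = "axial"),
    dplyr::mutate(normalize_to_intact(intact_to, treat_to), channel = "torsion")
  )
  params <- dplyr::mutate(params, specimen = specimen, group = group,
                          .before = 1)

  f_truth <- group_failure_truth(design$failure, group)
  ramp <- generate_failure_ramp(f_truth, area, seed = sub_seeds[8])
  fail <- detect_failure(ramp, area)

  hl <- group_height_loss(design$height_loss, group)
  prof <- generate_endplate_profiles(endplate_height, curvature_depth = 1,
                                     seed = sub_seeds[8] + 1L)
  h0 <- average_disc_height(prof)
  deformation <- withr::with_seed(
    sub_seeds[8] + 2L,
    stats::rnorm(1, hl$deformation_mean_mm, hl$deformation_sd_mm)
  )
  list(
    parameters = params,
    specimen_row = tibble::tibble(
      specimen = specimen, group = group,
      failure_strength = fail$failure_strength,
      failure_mode = fail$failure_mode,
      initial_height_mm = h0,
      disc_height_loss_pct = disc_height_loss(h0, deformation),
      error = NA_character_
    )
  )
}

jitter_truth <- function(truth, fields, cv, seed) {
  if (cv == 0) return(truth)
  vals <- unclass(truth)
  mult <- withr::with_seed(seed, 1 + stats::rnorm(length(fields), 0, cv))
  vals[fields] <- purrr::map2(vals[fields], mult, `*`)
  do.call(curve_truth, vals)
}

perturb_truth <- function(truth, pert, group, channel, seed) {
  if (is.null(pert)) return(truth)
  rows <- pert[pert$group == group & pert$channel == channel, , drop = FALSE]
  if (nrow(rows) == 0) return(truth)
  vals <- unclass(truth)
  pct <- withr::with_seed(seed, stats::rnorm(nrow(rows), rows$pct_mean, rows$pct_sd))
  for (j in seq_len(nrow(rows))) {
    par <- rows$parameter[j]
    if (is.null(vals[[par]])) stop("unknown truth parameter: ", par, call. = FALSE)
    vals[[par]] <- vals[[par]] * (1 + pct[j] / 100)
  }
  do.call(curve_truth, vals)
}

group_failure_truth <- function(failure, group) {
  if (!is.null(failure) && group %in% failure$group) {
    row <- failure[failure$group == group, , drop = FALSE][1, ]
    args <- as.list(row[setdiff(names(row), "group")])
    do.call(failure_truth, args)
  } else {
    failure_truth("herniation")
  }
}

group_height_loss <- function(height_loss, group) {
  if (!is.null(height_loss) && group %in% height_loss$group) {
    height_loss[height_loss$group == group, , drop = FALSE][1, ]
  } else {
    tibble::tibble(deformation_mean_mm = 0.8, deformation_sd_mm = 0.15)
  }
}

#' @export
print.study_cohort <- function(x, ...) {
  cat(sprintf("<study_cohort: %d specimens, %d parameter rows>\n",
              nrow(x$specimens), nrow(x$parameters)))
  print(utils::head(x$specimens))
  invisible(x)
}

#' @rdname tidy.disc_params
#' @method tidy study_cohort
#' @export
tidy.study_cohort <- function(x, ...) x$parameters

#' Per-group mean and SD summaries
#'
#' Group-wise mean and sample standard deviation of every numeric outcome
#' column, by parameter where a `parameter` column is present. No inferential
#' statistics are computed; the summary table is the hand-off point to
#' whichever ANOVA/post-hoc machinery the analyst prefers. Single-specimen
#' groups report an undefined (NA) SD.
#'
#' @param cohort A [study_cohort][run_study()], the tibble returned by
#'   [generate_cohort()], or any data frame with a `group` column and
#'   numeric outcomes.
#' @return A tibble with one row per group (x parameter), columns `n` and
#'   `<outcome>_mean` / `<outcome>_sd`.
#' @examples
#' summarize_groups(data.frame(group = "g", parameter = "k",
#'                             ratio = c(0.9, 1.0, 1.1)))
#' @export
summarize_groups <- function(cohort) {
  if (inherits(cohort, "study_cohort")) {
    mech <- summarize_groups(cohort$parameters)
    spec <- summarize_groups(dplyr::select(cohort$specimens, -"specimen", -"error"))
    return(list(parameters = mech, specimens = spec))
  }
  stopifnot("group" %in% names(cohort))
  keys <- intersect(c("group", "channel", "parameter"), names(cohort))
  drop <- intersect(c("specimen", "defined"), names(cohort))
  out <- dplyr::summarise(
    dplyr::group_by(dplyr::select(cohort, -dplyr::any_of(drop)),
                    dplyr::across(dplyr::all_of(keys))),
    n = dplyr::n(),
    dplyr::across(dplyr::where(is.numeric) & !dplyr::matches("^n$"),
                  list(mean = ~mean(.x, na.rm = TRUE),
                       sd = ~stats::sd(.x))),
    .groups = "drop"
  )
  out
}
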