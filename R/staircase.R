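#' Convert perimeter attenuation (dB) to log threshold
#'
#' The device expresses stimulus intensity as attenuation from its maximum:
#' 10 dB equals one log unit. `db_to_log()` maps an attenuation in the 0--36
#' dB dynamic range to a log-intensity threshold via a calibration constant
#' (the log intensity of the unattenuated stimulus, default 2.0 logUnits).
#' Note the device floor `db_to_log(36) = -1.6` lies below the -1.4 logUnits
#' RIT criterion, so rod intercept times are measurable within range.
#'
#' @param level_db Numeric attenuation in dB, within \[0, 36\].
#' @param cal_const Calibration constant, logUnits at 0 dB (default 2.0).
#' @return Threshold in logUnits, strictly decreasing in `level_db`.
#' @examples
#' db_to_log(c(0, 10, 36))
#' @export
db_to_log <- function(level_db, cal_const = 2.0) {
  if (!is.numeric(level_db) || any(!is.finite(level_db))) {
    abort_da("level_db must be finite numeric", "da_invalid_input")
  }
  if (any(level_db < 0 | level_db > 36)) {
    abort_da("level_db outside the 0-36 dB dynamic range", "da_range_error")
  }
  cal_const - level_db / 10
}

#' Extract threshold points from staircase presentations
#'
#' Under the 5-up/1-down staircase each *seen* presentation yields one
#' threshold datum, timestamped at that presentation and converted to
#' logUnits via [db_to_log()]. Not-seen presentations contribute no point.
#'
#' @param presentations Data frame of presentation records with columns
#'   `t_min`, `level_db`, `seen` plus any identifying columns
#'   (`subject_id`, `group`, `age`, `eccentricity_deg`, `color`), which are
#'   carried through.
#' @param cal_const Passed to [db_to_log()].
#' @return A tibble of threshold points: the identifying columns present in
#'   the input plus `t_min`, `threshold_log`, `at_floor` (point sits at the
#'   device floor, 36 dB; retained but flagged — such points carry censoring
#'   information) and `bracketed` (the staircase had just stepped up from a
#'   miss, so the stimulus lies within one up-step of the true threshold;
#'   unbracketed points from the initial descent can sit several dB above
#'   threshold).
#' @export
extract_thresholds <- function(presentations, cal_const = 2.0) {
  d <- tibble::as_tibble(presentations)
  need <- c("t_min", "level_db", "seen")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    abort_da(paste0("missing columns: ", paste(miss, collapse = ", ")),
             "da_schema_error")
  }
  if (nrow(d) == 0L) {
    return(dplyr::mutate(d[0, ], threshold_log = numeric(0),
                         at_floor = logical(0), bracketed = logical(0)))
  }
  keys <- intersect(c("subject_id", "eccentricity_deg", "color"), names(d))
  unsorted <- d |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(bad = is.unsorted(.data$t_min), .groups = "drop")
  if (any(unsorted$bad)) {
    warn("presentations not sorted by t_min; sorting internally")
  }
  d |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::arrange(.data$t_min, .by_group = TRUE) |>
    dplyr::mutate(bracketed = !dplyr::lag(as.logical(.data$seen),
                                          default = TRUE)) |>
    dplyr::ungroup() |>
    dplyr::filter(as.logical(.data$seen)) |>
    dplyr::mutate(threshold_log = db_to_log(.data$level_db, cal_const),
                  at_floor = .data$level_db >= 36) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(keys, "t_min")))) |>
    dplyr::select(-dplyr::any_of("seen"))
}

#' Detect rod function from cyan/red separation
#'
#' Rod-mediated detection of the cyan (505 nm) stimulus implies that late in
#' the session cyan thresholds separate downward from red (627 nm,
#' cone-mediated) thresholds. When no such separation exists within the test,
#' there is no evidence of a cone--rod break and the locus is treated as
#' cone-mediated throughout. This rule automates the manual curve review:
#' rod function is present iff, within the final `window` minutes of the
#' session, the median cyan threshold lies more than `margin` logUnits below
#' the median red threshold.
#'
#' @param cyan_points,red_points Data frames of threshold points for one
#'   locus (columns `t_min`, `threshold_log`).
#' @param margin Required cyan-below-red separation, logUnits (default 0.3).
#' @param window Length of the terminal comparison window, minutes
#'   (default 10).
#' @return A single logical. Degenerate inputs (either list empty in the
#'   window) return `FALSE`.
#' @export
detect_rod_function <- function(cyan_points, red_points,
                                margin = 0.3, window = 10) {
  cy <- tibble::as_tibble(cyan_points)
  rd <- tibble::as_tibble(red_points)
  if (nrow(cy) == 0L) return(FALSE)
  if (nrow(rd) == 0L) {
    warn("no red threshold points: cannot establish cyan/red separation")
    return(FALSE)
  }
  t_end <- max(cy$t_min, rd$t_min)
  cy_w <- cy$threshold_log[cy$t_min >= t_end - window]
  rd_w <- rd$threshold_log[rd$t_min >= t_end - window]
  if (!length(cy_w) || !length(rd_w)) return(FALSE)
  median(cy_w) < median(rd_w) - margin
}
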