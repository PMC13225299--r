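presentation_cols <- c("subject_id", "group", "age", "eccentricity_deg",
                       "color", "t_min", "level_db", "seen")

validate_rows <- function(d, checks) {
  reasons <- rep(NA_character_, nrow(d))
  for (nm in names(checks)) {
    bad <- !checks[[nm]](d)
    bad[is.na(bad)] <- TRUE
    reasons[bad & is.na(reasons)] <- nm
  }
  reasons
}

#' Read presentation records from CSV
#'
#' Reads the `presentations.csv` schema (`subject_id`, `group`, `age`,
#' `eccentricity_deg`, `color`, `t_min`, `level_db`, `seen` as 0/1; UTF-8,
#' '.' decimal, header required). Rows violating the record invariants
#' (attenuation outside 0--36 dB, negative time, eccentricity not in
#' \{2,4,6\}, unknown color) are rejected with line-numbered warnings and
#' returned in the `"rejected"` attribute of the result.
#'
#' @param path Path to a CSV file.
#' @return A tibble of validated presentation records.
#' @export
read_presentations <- function(path) {
  if (!file.exists(path)) {
    abort_da(paste0("file not found: ", path), "da_path_error")
  }
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(presentation_cols, names(d))
  if (length(miss)) {
    abort_da(paste0("missing columns in ", path, ": ",
                    paste(miss, collapse = ", ")), "da_schema_error")
  }
  if (nrow(d) == 0L) {
    warn("empty presentations file")
    return(tibble::as_tibble(d))
  }
  reasons <- validate_rows(d, list(
    "level_db outside [0,36]" = function(d) {
      d$level_db >= 0 & d$level_db <= 36
    },
    "t_min negative" = function(d) d$t_min >= 0,
    "eccentricity not in {2,4,6}" = function(d) {
      d$eccentricity_deg %in% c(2, 4, 6)
    },
    "unknown color" = function(d) d$color %in% c("cyan505", "red627"),
    "seen not 0/1" = function(d) d$seen %in% c(0, 1, TRUE, FALSE)))
  bad <- !is.na(reasons)
  if (any(bad)) {
    lines <- which(bad) + 1L # header line offset
    warn(paste0("rejected ", sum(bad), " row(s): ",
                paste0("line ", head(lines, 5), " (",
                       head(reasons[bad], 5), ")", collapse = "; "),
                if (sum(bad) > 5) " ..." else ""))
  }
  out <- tibble::as_tibble(d[!bad, ])
  out$seen <- as.logical(out$seen)
  attr(out, "rejected") <- tibble::tibble(line = which(bad) + 1L,
                                          reason = reasons[bad])
  out
}

#' Read pre-extracted threshold time series from CSV
#'
#' Alternative entry point when thresholds were already extracted:
#' columns `subject_id`, `group`, `age`, `eccentricity_deg`, `color`,
#' `t_min`, `threshold_log`.
#'
#' @param path Path to a CSV file.
#' @return A tibble of threshold points.
#' @export
read_thresholds <- function(path) {
  if (!file.exists(path)) {
    abort_da(paste0("file not found: ", path), "da_path_error")
  }
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("subject_id", "group", "age", "eccentricity_deg", "color",
            "t_min", "threshold_log")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    abort_da(paste0("missing columns in ", path, ": ",
                    paste(miss, collapse = ", ")), "da_schema_error")
  }
  tibble::as_tibble(d)
}

#' Serialize a normative model to JSON (and back)
#'
#' @param model A `da_normative` object.
#' @param path Output (input) JSON path.
#' @return `normative_to_json()` returns `path` invisibly;
#'   `normative_from_json()` returns a `da_normative` object (REML-style:
#'   posterior draws are not serialized).
#' @export
normative_to_json <- function(model, path) {
  stopifnot(inherits(model, "da_normative"))
  x <- model[c("outcome_name", "backend", "sd_subject", "sd_resid",
               "ecc_levels", "ref_ecc", "age_range", "n_subjects",
               "n_loci")]
  x$fixef <- as.list(model$fixef)
  x$fixef_se <- as.list(model$fixef_se)
  if (!is.null(model$fixef_vcov)) x$fixef_vcov <- model$fixef_vcov
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname normative_to_json
#' @export
normative_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fe <- unlist(x$fixef)
  vc <- x$fixef_vcov
  if (!is.null(vc)) {
    vc <- matrix(unlist(vc), length(fe), length(fe), byrow = TRUE,
                 dimnames = list(names(fe), names(fe)))
  }
  structure(list(outcome_name = x$outcome_name, backend = x$backend,
                 fixef = fe, fixef_se = unlist(x$fixef_se),
                 fixef_vcov = vc,
                 sd_subject = x$sd_subject,
                 sd_resid = x$sd_resid, ecc_levels = x$ecc_levels,
                 ref_ecc = x$ref_ecc, age_range = x$age_range,
                 n_subjects = x$n_subjects, n_loci = x$n_loci,
                 draws = NULL),
            class = "da_normative")
}

#' Serialize curve parameters to/from JSON
#'
#' Field names are exactly `ct, t0, tau, S2, CRB, tf`.
#'
#' @param params A [da_params()] object.
#' @param path JSON path.
#' @return `params_to_json()` returns `path` invisibly;
#'   `params_from_json()` returns a `da_params` object.
#' @export
params_to_json <- function(params, path) {
  p <- coerce_params(params)
  jsonlite::write_json(unclass(p), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname params_to_json
#' @export
params_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(da_params, as.list(x[c("ct", "t0", "tau", "S2", "CRB", "tf")]))
}
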