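#' Analysis configuration
#'
#' Bundles the tunable settings of the pipeline: the RIT criterion
#' (logUnits, must be negative and within the dynamic range implied by the
#' calibration constant), the session cap, the device calibration, fitting
#' mode and seeds, the normative backend and the adjusted-ROC settings.
#'
#' @param criterion RIT criterion, logUnits (default -1.4).
#' @param t_max Session cap, minutes (default 60).
#' @param cal_const Device calibration constant, logUnits at 0 dB.
#' @param fit_mode `"map_penalized"` or `"mcmc"`.
#' @param n_starts Multistart count for the curve fit.
#' @param normative_backend `"reml"` or `"bayes"`.
#' @param n_boot Bootstrap replicates for adjusted-ROC intervals.
#' @param level Prediction-interval coverage.
#' @param margin,window Rod-function detection settings.
#' @param markers Markers to run through the adjusted ROC.
#' @return A `da_config` list.
#' @export
da_config <- function(criterion = -1.4, t_max = 60, cal_const = 2.0,
                      fit_mode = "map_penalized", n_starts = 10,
                      normative_backend = "reml", n_boot = 500,
                      level = 0.95, margin = 0.3, window = 10,
                      markers = c("RIT", "FT", "CT")) {
  if (criterion >= 0 || criterion < cal_const - 3.6) {
    abort_da("criterion must be negative and within the dynamic range",
             "da_invalid_input")
  }
  structure(as.list(environment()), class = "da_config")
}

#' Run the full dark-adaptation analysis pipeline
#'
#' Composes the stages: threshold extraction, per-locus curve fitting and
#' outcome derivation, healthy-eye normative models for RIT/CT/FT,
#' deviations from normative limits, covariate-adjusted ROC per marker and
#' eccentricity, and (when subject biomarker covariates are available) the
#' structure-function regression. Writes CSV/JSON artifacts into `out_dir`
#' when given, along with a run-metadata JSON (seed, config hash, package
#' version). Any stage failure aborts with a stage-labeled message.
#'
#' @param presentations Presentation records (tibble or path to CSV).
#' @param subjects Optional tibble of per-subject covariates (`subject_id`,
#'   `sdd`, `diagnosis_se`, `diagnosis_fe`); enables the regression stage.
#'   A [generate_cohort()] table works directly.
#' @param config A [da_config()].
#' @param seed Integer seed for every stochastic stage.
#' @param out_dir Optional output directory.
#' @return A list bundle: `outcomes`, `models`, `deviations`,
#'   `aroc` (glance tibble), `aroc_objects`, `structfun`, `metadata`.
#' @export
run_da_pipeline <- function(presentations, subjects = NULL,
                            config = da_config(), seed = 1,
                            out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort_da(paste0("stage [", name, "] failed: ", conditionMessage(e)),
               "da_stage_error")
    })
  }
  if (is.character(presentations)) {
    presentations <- stage("read", read_presentations(presentations))
  }
  thresholds <- stage("extract",
                      extract_thresholds(presentations, config$cal_const))
  outcomes <- stage("fit", fit_da_loci(
    thresholds, mode = config$fit_mode, n_starts = config$n_starts,
    seed = seed, margin = config$margin, window = config$window,
    criterion = config$criterion, t_max = config$t_max))
  models <- stage("normative", {
    setNames(purrr::map(config$markers, function(oc) {
      fit_normative(outcomes, outcome = oc,
                    backend = config$normative_backend, seed = seed)
    }), config$markers)
  })
  deviations <- stage("deviations",
                      compute_deviations(outcomes, models,
                                         level = config$level))
  aroc_objects <- stage("aroc", {
    d <- dplyr::mutate(outcomes, diseased = .data$group == "AMD")
    grid <- tidyr::expand_grid(marker = config$markers,
                               ecc = sort(unique(d$eccentricity_deg)))
    purrr::pmap(grid, function(marker, ecc) {
      covariate_adjusted_roc(
        dplyr::filter(d, .data$eccentricity_deg == ecc),
        marker = marker, disease = "diseased", covariate = "age",
        direction = "higher_is_diseased", n_boot = config$n_boot,
        seed = seed) |>
        (\(a) { a$eccentricity_deg <- ecc; a })()
    })
  })
  aroc <- purrr::map(aroc_objects, function(a) {
    dplyr::mutate(glance(a), eccentricity_deg = a$eccentricity_deg,
                  .after = "marker")
  }) |>
    dplyr::bind_rows()
  structfun <- NULL
  if (!is.null(subjects)) {
    structfun <- stage("structfun", {
      covars <- subjects |>
        tibble::as_tibble() |>
        dplyr::distinct(.data$subject_id, .data$sdd, .data$diagnosis_se,
                        .data$diagnosis_fe)
      merged <- dplyr::inner_join(outcomes, covars, by = "subject_id")
      structure_function_fit(merged, outcome = "RIT")
    })
  }
  metadata <- list(seed = seed,
                   config = unclass(config),
                   config_hash = rlang::hash(unclass(config)),
                   package_version = as.character(
                     utils::packageVersion("darkadaptr")),
                   schema_version = "1",
                   n_subjects = dplyr::n_distinct(outcomes$subject_id),
                   n_loci = nrow(outcomes))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(outcomes, file.path(out_dir, "locus_outcomes.csv"))
    readr::write_csv(deviations, file.path(out_dir, "deviations.csv"))
    readr::write_csv(aroc, file.path(out_dir, "aroc_results.csv"))
    jsonlite::write_json(
      purrr::map(aroc_objects, function(a) {
        list(marker = a$marker_name, eccentricity_deg = a$eccentricity_deg,
             fpf = a$fpf_grid, tpf = a$tpf, aauc = a$aauc,
             ci = c(a$ci_low, a$ci_high))
      }),
      file.path(out_dir, "aroc_curves.json"), auto_unbox = TRUE, digits = NA)
    for (oc in names(models)) {
      normative_to_json(models[[oc]],
                        file.path(out_dir, paste0("normative_", oc, ".json")))
    }
    if (!is.null(structfun)) {
      readr::write_csv(tidy(structfun),
                       file.path(out_dir, "regression_results.csv"))
    }
    jsonlite::write_json(metadata, file.path(out_dir, "run_metadata.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(outcomes = outcomes, models = models, deviations = deviations,
       aroc = aroc, aroc_objects = aroc_objects, structfun = structfun,
       metadata = metadata)
}
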