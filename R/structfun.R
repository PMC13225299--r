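#' Structure-function regression of RIT on AMD biomarkers
#'
#' Per-eccentricity ordinary least squares of an outcome (default `RIT`) on
#' the established structural determinants of rod dysfunction: presence of
#' subretinal drusenoid deposits (`sdd`), study-eye diagnosis and fellow-eye
#' diagnosis (categorical, reference level `"none"` carried by healthy
#' controls), and age per decade. Reports Wald 95% CIs, per-coefficient
#' t-test p-values, and (adjusted) R-squared.
#'
#' @param data Long tibble with one row per subject x eccentricity:
#'   columns `eccentricity_deg`, the outcome column, `sdd` (logical),
#'   `diagnosis_se`, `diagnosis_fe` (character/factor with levels among
#'   none, eAMD, iAMD, lateAMD), `age`.
#' @param outcome Name of the outcome column (default `"RIT"`).
#' @return A `da_structfun` object (list of per-eccentricity `lm` summaries);
#'   see [tidy.da_structfun()] and [glance.da_structfun()].
#' @export
structure_function_fit <- function(data, outcome = "RIT") {
  d <- tibble::as_tibble(data)
  need <- c("eccentricity_deg", outcome, "sdd", "diagnosis_se",
            "diagnosis_fe", "age")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    abort_da(paste0("missing columns: ", paste(miss, collapse = ", ")),
             "da_schema_error")
  }
  lev <- c("none", "eAMD", "iAMD", "lateAMD")
  d$..y <- d[[outcome]]
  d <- d |>
    dplyr::mutate(
      sdd = as.logical(.data$sdd),
      age_decade = .data$age / 10,
      diagnosis_se = factor(as.character(.data$diagnosis_se),
                            levels = intersect(lev, unique(as.character(.data$diagnosis_se)))),
      diagnosis_fe = factor(as.character(.data$diagnosis_fe),
                            levels = intersect(lev, unique(as.character(.data$diagnosis_fe)))))
  fits <- d |>
    dplyr::group_by(.data$eccentricity_deg) |>
    dplyr::group_split() |>
    purrr::map(function(g) {
      terms <- c("sdd")
      if (nlevels(droplevels(g$diagnosis_se)) > 1) terms <- c(terms, "diagnosis_se")
      if (nlevels(droplevels(g$diagnosis_fe)) > 1) terms <- c(terms, "diagnosis_fe")
      terms <- c(terms, "age_decade")
      form <- as.formula(paste("..y ~", paste(terms, collapse = " + ")))
      mm <- model.matrix(form, g)
      qr_mm <- qr(mm)
      if (qr_mm$rank < ncol(mm)) {
        aliased <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
        abort_da(paste0("rank-deficient design; aliased columns: ",
                        paste(aliased, collapse = ", ")),
                 "da_collinearity_error")
      }
      fit <- lm(form, data = g)
      list(eccentricity_deg = g$eccentricity_deg[1], fit = fit, n = nrow(g))
    })
  structure(list(outcome = outcome, fits = fits), class = "da_structfun")
}

#' Tidy/glance methods for structure-function regressions
#'
#' @param x A `da_structfun` object.
#' @param ... Unused.
#' @return `tidy()`: per eccentricity x term: `estimate`, `conf.low`,
#'   `conf.high`, `p.value`; `glance()`: per eccentricity: `r.squared`,
#'   `adj.r.squared`, `sigma`, `nobs`.
#' @method tidy da_structfun
#' @export
tidy.da_structfun <- function(x, ...) {
  purrr::map(x$fits, function(f) {
    s <- summary(f$fit)$coefficients
    ci <- confint(f$fit)
    tibble::tibble(eccentricity_deg = f$eccentricity_deg,
                   term = rownames(s), estimate = unname(s[, 1]),
                   std.error = unname(s[, 2]),
                   conf.low = unname(ci[, 1]), conf.high = unname(ci[, 2]),
                   p.value = unname(s[, 4]))
  }) |>
    dplyr::bind_rows()
}

#' @rdname tidy.da_structfun
#' @method glance da_structfun
#' @export
glance.da_structfun <- function(x, ...) {
  purrr::map(x$fits, function(f) {
    s <- summary(f$fit)
    tibble::tibble(eccentricity_deg = f$eccentricity_deg,
                   r.squared = s$r.squared,
                   adj.r.squared = s$adj.r.squared,
                   sigma = s$sigma, nobs = f$n)
  }) |>
    dplyr::bind_rows()
}

#' @export
print.da_structfun <- function(x, ...) {
  cat("<da_structfun>", x$outcome, "~ sdd + diagnosis + age, per eccentricity\n")
  print(glance(x))
  invisible(x)
}
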