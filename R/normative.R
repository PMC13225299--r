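#' Fit the healthy-eye normative model for a dark-adaptation outcome
#'
#' Models an outcome (`RIT`, `CT` or `FT`) in healthy eyes as a linear
#' function of age (entered in decades for numerical conditioning) with a
#' fixed categorical eccentricity effect (2 degrees as reference) and a
#' random intercept per subject. The default backend is REML via
#' \pkg{lme4}; the `"bayes"` backend runs a conjugate Gibbs sampler over the
#' same Gaussian random-intercept model with weakly informative priors
#' (coefficients N(0, 100^2); variances inverse-gamma(0.01, 0.01)) and
#' reports posterior medians. Both backends target the same quantities and
#' feed the same prediction-interval machinery.
#'
#' @param outcomes Tibble of per-locus outcomes including columns
#'   `subject_id`, `group`, `age`, `eccentricity_deg` and the outcome
#'   column. Only rows with `group == "healthy"` enter the fit.
#' @param outcome One of `"RIT"`, `"CT"`, `"FT"` (any numeric column works).
#' @param backend `"reml"` (default) or `"bayes"`.
#' @param exclude_censored If `TRUE`, censored RIT values (`rit_censored`)
#'   are dropped from the normative fit; by default the recorded 60-minute
#'   values are used as-is (expected to be rare in healthy eyes).
#' @param n_iter,n_burn Gibbs iterations kept / burned (bayes backend).
#' @param seed Seed for the Gibbs sampler.
#' @return A `da_normative` object with fixed effects, variance components
#'   (between-subject and residual SD), eccentricity levels, training age
#'   range and fit metadata.
#' @seealso [predict_interval()], [compute_deviations()]
#' @export
fit_normative <- function(outcomes, outcome = c("RIT", "CT", "FT"),
                          backend = c("reml", "bayes"),
                          exclude_censored = FALSE,
                          n_iter = 2000, n_burn = 500, seed = 1) {
  outcome <- if (is.character(outcome) && length(outcome) > 1) {
    match.arg(outcome)
  } else outcome
  backend <- match.arg(backend)
  d <- tibble::as_tibble(outcomes)
  need <- c("subject_id", "age", "eccentricity_deg", outcome)
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    abort_da(paste0("missing columns: ", paste(miss, collapse = ", ")),
             "da_schema_error")
  }
  if ("group" %in% names(d)) d <- dplyr::filter(d, .data$group == "healthy")
  if (exclude_censored && outcome == "RIT" && "rit_censored" %in% names(d)) {
    d <- dplyr::filter(d, !.data$rit_censored)
  }
  d <- d[is.finite(d[[outcome]]), ]
  if (dplyr::n_distinct(d$subject_id) < 10) {
    abort_da("need >= 10 healthy subjects for the normative fit",
             "da_insufficient_data")
  }
  d$..y <- d[[outcome]]
  d$..age_dec <- d$age / 10
  ecc_levels <- sort(unique(d$eccentricity_deg))
  d$..ecc <- factor(d$eccentricity_deg, levels = ecc_levels)
  if (length(ecc_levels) == 1 && var(d$age) < 1e-12) {
    abort_da("degenerate design: single eccentricity and constant age",
             "da_degenerate_design")
  }
  use_ecc <- length(ecc_levels) > 1
  fix_names <- function(x) {
    sub("^\\.\\.ecc", "ecc", sub("^\\.\\.age_dec", "age_decade",
                                 sub("\\(Intercept\\)", "intercept", x)))
  }
  lm_form <- if (use_ecc) ..y ~ ..age_dec + ..ecc else ..y ~ ..age_dec
  ols <- lm(lm_form, data = d)
  ols_sigma <- suppressWarnings(summary(ols)$sigma)
  one_per_subject <- max(table(d$subject_id)) == 1
  if (backend == "reml" && (ols_sigma < 1e-8 || one_per_subject)) {
    # exact interpolation limit, or one locus per subject (between-subject
    # and residual variation inseparable): OLS with the total variation in
    # the residual component
    fe <- coef(ols)
    names(fe) <- fix_names(names(fe))
    fe_se <- suppressWarnings(
      setNames(summary(ols)$coefficients[, 2], names(fe)))
    fe_vcov <- suppressWarnings(stats::vcov(ols))
    if (ols_sigma < 1e-8) {
      fe_se[] <- 0
      fe_vcov[] <- 0
    }
    dimnames(fe_vcov) <- list(names(fe), names(fe))
    sd_subject <- 0
    sd_resid <- ols_sigma
    draws <- NULL
  } else if (backend == "reml") {
    form <- if (use_ecc) {
      ..y ~ ..age_dec + ..ecc + (1 | subject_id)
    } else {
      ..y ~ ..age_dec + (1 | subject_id)
    }
    fit <- suppressWarnings(suppressMessages(
      lme4::lmer(form, data = d, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))))
    fe <- lme4::fixef(fit)
    fe_vcov <- as.matrix(stats::vcov(fit))
    fe_se <- sqrt(diag(fe_vcov))
    vc <- as.data.frame(lme4::VarCorr(fit))
    sd_subject <- vc$sdcor[vc$grp == "subject_id"][1]
    sd_resid <- vc$sdcor[vc$grp == "Residual"][1]
    names(fe) <- fix_names(names(fe))
    names(fe_se) <- names(fe)
    dimnames(fe_vcov) <- list(names(fe), names(fe))
    draws <- NULL
  } else {
    X <- model.matrix(if (use_ecc) ~ ..age_dec + ..ecc else ~ ..age_dec, d)
    colnames(X) <- sub("^\\.\\.ecc", "ecc", sub("^\\.\\.age_dec", "age_decade",
                                                sub("\\(Intercept\\)", "intercept", colnames(X))))
    g <- gibbs_lmm(d$..y, X, as.integer(factor(d$subject_id)),
                   n_iter = n_iter, n_burn = n_burn, seed = seed)
    fe <- apply(g$beta, 2, median)
    fe_se <- apply(g$beta, 2, sd)
    fe_vcov <- stats::cov(g$beta)
    names(fe) <- colnames(X)
    names(fe_se) <- colnames(X)
    dimnames(fe_vcov) <- list(colnames(X), colnames(X))
    sd_subject <- median(sqrt(g$sigma2_b))
    sd_resid <- median(sqrt(g$sigma2_e))
    draws <- g
  }
  structure(list(outcome_name = outcome, backend = backend, fixef = fe,
                 fixef_se = fe_se, fixef_vcov = fe_vcov,
                 sd_subject = sd_subject, sd_resid = sd_resid,
                 ecc_levels = ecc_levels, ref_ecc = ecc_levels[1],
                 age_range = range(d$age),
                 n_subjects = dplyr::n_distinct(d$subject_id),
                 n_loci = nrow(d), draws = draws),
            class = "da_normative")
}

# conjugate Gibbs sampler for y = X beta + b[subj] + e
gibbs_lmm <- function(y, X, subj, n_iter, n_burn, seed,
                      beta_sd = 100, a0 = 0.01, b0 = 0.01) {
  local_seed_if(seed)
  n <- length(y); p <- ncol(X); m <- max(subj)
  XtX <- crossprod(X)
  beta <- qr.solve(XtX + diag(1e-8, p), crossprod(X, y))
  b <- rep(0, m)
  s2e <- var(y - X %*% beta)[1] + 1e-6
  s2b <- s2e / 2 + 1e-6
  keep <- list(beta = matrix(NA_real_, n_iter, p),
               sigma2_b = numeric(n_iter), sigma2_e = numeric(n_iter))
  ns <- tabulate(subj, m)
  for (it in seq_len(n_burn + n_iter)) {
    # beta | rest
    Vinv <- XtX / s2e + diag(1 / beta_sd^2, p)
    V <- solve(Vinv)
    mu <- V %*% (crossprod(X, y - b[subj]) / s2e)
    beta <- as.numeric(mu + t(chol(V)) %*% rnorm(p))
    # b | rest
    r <- as.numeric(y - X %*% beta)
    rs <- tapply(r, subj, sum)
    post_var <- 1 / (ns / s2e + 1 / s2b)
    b <- rnorm(m, post_var * rs / s2e, sqrt(post_var))
    # variances
    e <- r - b[subj]
    s2e <- 1 / stats::rgamma(1, a0 + n / 2, b0 + sum(e^2) / 2)
    s2b <- 1 / stats::rgamma(1, a0 + m / 2, b0 + sum(b^2) / 2)
    if (it > n_burn) {
      k <- it - n_burn
      keep$beta[k, ] <- beta
      keep$sigma2_b[k] <- s2b
      keep$sigma2_e[k] <- s2e
    }
  }
  colnames(keep$beta) <- colnames(X)
  keep
}

#' @export
print.da_normative <- function(x, ...) {
  cat("<da_normative>", x$outcome_name, "(", x$backend, ")\n")
  print(x$fixef)
  cat("between-subject SD:", signif(x$sd_subject, 4),
      " residual SD:", signif(x$sd_resid, 4), "\n")
  invisible(x)
}

#' Tidy/glance methods for normative models
#'
#' @param x A `da_normative` object.
#' @param ... Unused.
#' @return `tidy()`: fixed effects as a tibble; `glance()`: one row with
#'   variance components and sample sizes.
#' @method tidy da_normative
#' @export
tidy.da_normative <- function(x, ...) {
  tibble::tibble(term = names(x$fixef), estimate = unname(x$fixef),
                 std.error = if (is.null(x$fixef_se)) NA_real_ else
                   unname(x$fixef_se[names(x$fixef)]))
}

#' @rdname tidy.da_normative
#' @method glance da_normative
#' @export
glance.da_normative <- function(x, ...) {
  tibble::tibble(outcome = x$outcome_name, backend = x$backend,
                 sd_subject = x$sd_subject, sd_resid = x$sd_resid,
                 n_subjects = x$n_subjects, n_loci = x$n_loci)
}

# design matrix rows for new observations, in the model's coefficient order
pred_design <- function(model, age, eccentricity_deg) {
  nms <- names(model$fixef)
  X <- matrix(0, length(age), length(nms), dimnames = list(NULL, nms))
  X[, "intercept"] <- 1
  X[, "age_decade"] <- age / 10
  for (e in model$ecc_levels) {
    nm <- paste0("ecc", e)
    if (nm %in% nms) X[eccentricity_deg == e, nm] <- 1
  }
  X
}

normative_fixed_pred <- function(model, age, eccentricity_deg) {
  fe <- model$fixef
  pred <- fe[["intercept"]] + fe[["age_decade"]] * age / 10
  if (length(model$ecc_levels) > 1) {
    off <- purrr::map_dbl(eccentricity_deg, function(e) {
      if (e == model$ref_ecc) return(0)
      nm <- paste0("ecc", e)
      if (!nm %in% names(fe)) {
        abort_da(paste0("eccentricity ", e, " not in normative model"),
                 "da_invalid_input")
      }
      fe[[nm]]
    })
    pred <- pred + off
  }
  pred
}

#' Normative prediction interval for a new eye
#'
#' Prediction interval for a *new subject at a new locus*: the fixed-effect
#' prediction plus/minus `z(level)` times the total SD
#' `sqrt(sd_subject^2 + sd_resid^2)` (REML backend), or posterior-predictive
#' quantiles of the normal mixture over the Gibbs draws (bayes backend).
#' Interval width is constant in age and shared across eccentricities.
#'
#' @param model A `da_normative` object.
#' @param age Numeric vector of ages, years. Ages more than 10 years outside
#'   the training range trigger an extrapolation warning.
#' @param eccentricity_deg Vector of eccentricities (recycled against `age`).
#' @param level Coverage level (default 0.95).
#' @return A tibble with `age`, `eccentricity_deg`, `pi_low`,
#'   `predicted_median`, `pi_high`.
#' @export
predict_interval <- function(model, age, eccentricity_deg, level = 0.95) {
  if (!inherits(model, "da_normative")) {
    abort_da("model must be a fitted da_normative object", "da_state_error")
  }
  n <- max(length(age), length(eccentricity_deg))
  age <- rep_len(age, n)
  eccentricity_deg <- rep_len(eccentricity_deg, n)
  if (any(age < model$age_range[1] - 10 | age > model$age_range[2] + 10)) {
    warn("age outside training range +/- 10 years: extrapolating")
  }
  med <- normative_fixed_pred(model, age, eccentricity_deg)
  if (model$backend == "reml" || is.null(model$draws)) {
    # predictive variance for a new subject at a new locus: both variance
    # components plus the fixed-effect estimation uncertainty x' V x
    est_var <- rep(0, n)
    if (!is.null(model$fixef_vcov)) {
      X <- pred_design(model, age, eccentricity_deg)
      est_var <- rowSums((X %*% model$fixef_vcov) * X)
    }
    hw <- qnorm((1 + level) / 2) *
      sqrt(model$sd_subject^2 + model$sd_resid^2 + est_var)
    lo <- med - hw; hi <- med + hw
  } else {
    qs <- purrr::map(seq_len(n), function(i) {
      posterior_predictive_q(model, age[i], eccentricity_deg[i],
                             c((1 - level) / 2, 0.5, (1 + level) / 2))
    })
    lo <- purrr::map_dbl(qs, 1)
    med <- purrr::map_dbl(qs, 2)
    hi <- purrr::map_dbl(qs, 3)
  }
  tibble::tibble(age = age, eccentricity_deg = eccentricity_deg,
                 pi_low = lo, predicted_median = med, pi_high = hi)
}

# quantiles of the posterior-predictive normal mixture, solved numerically
posterior_predictive_q <- function(model, age, ecc, probs) {
  g <- model$draws
  fe_names <- colnames(g$beta)
  x <- setNames(rep(0, length(fe_names)), fe_names)
  x["intercept"] <- 1
  x["age_decade"] <- age / 10
  nm <- paste0("ecc", ecc)
  if (nm %in% fe_names) x[nm] <- 1
  mu <- as.numeric(g$beta %*% x)
  s <- sqrt(g$sigma2_b + g$sigma2_e)
  cdf <- function(q) mean(pnorm(q, mu, s))
  rng <- range(mu) + c(-1, 1) * 8 * max(s)
  vapply(probs, function(p) {
    uniroot(function(q) cdf(q) - p, lower = rng[1], upper = rng[2],
            tol = 1e-6)$root
  }, numeric(1))
}

#' Express outcomes as deviations from normative limits
#'
#' Applies the study's sign conventions: for thresholds (`CT`, `FT`) the
#' deviation is `predicted_median - observed`, so sensitivity loss (an
#' elevated threshold) is negative; for `RIT` the deviation is the *RIT
#' delay* `observed - predicted_median`, positive when recovery is delayed.
#' An eye is abnormal when its observed value falls outside the prediction
#' interval. Censored RIT values (recorded 60) are compared as-is; a
#' censored 60 above `pi_high` is abnormal and its delay is a lower bound,
#' flagged via `censored`.
#'
#' @param outcomes Tibble with `subject_id`, `age`, `eccentricity_deg`, the
#'   outcome columns named in `models`, and optionally `group` and
#'   `rit_censored`.
#' @param models Named list of `da_normative` objects, e.g.
#'   `list(RIT = ..., CT = ..., FT = ...)`. Every requested outcome must
#'   have a model.
#' @param outcome_names Outcomes to process (default: the names of
#'   `models`).
#' @param level Prediction-interval coverage (default 0.95).
#' @return A long tibble of deviation records: identifying columns plus
#'   `outcome_name`, `observed`, `predicted_median`, `pi_low`, `pi_high`,
#'   `deviation`, `abnormal`, `censored`.
#' @export
compute_deviations <- function(outcomes, models,
                               outcome_names = names(models), level = 0.95) {
  d <- tibble::as_tibble(outcomes)
  miss_m <- setdiff(outcome_names, names(models))
  if (length(miss_m)) {
    abort_da(paste0("no normative model supplied for: ",
                    paste(miss_m, collapse = ", ")), "da_config_error")
  }
  miss_c <- setdiff(outcome_names, names(d))
  if (length(miss_c)) {
    abort_da(paste0("missing outcome columns: ",
                    paste(miss_c, collapse = ", ")), "da_schema_error")
  }
  carry <- intersect(c("subject_id", "group", "age", "eccentricity_deg"),
                     names(d))
  purrr::map(outcome_names, function(oc) {
    m <- models[[oc]]
    pi <- predict_interval(m, d$age, d$eccentricity_deg, level = level)
    obs <- d[[oc]]
    deviation <- if (oc == "RIT") {
      obs - pi$predicted_median
    } else {
      pi$predicted_median - obs
    }
    cens <- if (oc == "RIT" && "rit_censored" %in% names(d)) {
      tidyr::replace_na(d$rit_censored, FALSE)
    } else {
      rep(FALSE, nrow(d))
    }
    dplyr::bind_cols(
      d[carry],
      tibble::tibble(outcome_name = oc, observed = obs,
                     predicted_median = pi$predicted_median,
                     pi_low = pi$pi_low, pi_high = pi$pi_high,
                     deviation = deviation,
                     abnormal = obs < pi$pi_low | obs > pi$pi_high,
                     censored = cens))
  }) |>
    dplyr::bind_rows()
}
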