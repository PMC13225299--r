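#' Covariate-adjusted ROC curve (AROC)
#'
#' Diagnostic accuracy of a marker adjusted for a covariate (age) via the
#' induced-linear-model estimator: (1) the marker is regressed on the
#' covariate in the *healthy* group (Gaussian linear model); (2) each
#' diseased subject gets a placement value — the estimated probability that
#' a healthy subject with the same covariate value has a *more extreme*
#' marker (per `direction`); (3) the adjusted ROC curve is the empirical CDF
#' of those placement values over `fpf_grid`, and the adjusted AUC (AAUC) is
#' its trapezoidal integral. Because the healthy reference is conditioned on
#' the covariate, confounding by (say) age cannot inflate the AAUC — the
#' estimate is more conservative than a pooled ROC when the groups differ in
#' the covariate. Uncertainty comes from a stratified percentile bootstrap
#' over subjects.
#'
#' @param data Data frame containing the marker, disease-indicator and
#'   covariate columns.
#' @param marker Name of the numeric marker column (e.g. `"RIT"`).
#' @param disease Name of a logical (or 0/1) column: `TRUE` = diseased.
#' @param covariate Name of the covariate column (default `"age"`).
#' @param direction `"higher_is_diseased"` (default; used for RIT and for
#'   thresholds in logUnits, where elevation means loss) or
#'   `"lower_is_diseased"`.
#' @param n_boot Bootstrap replicates for the percentile CI (default 500;
#'   0 skips the CI).
#' @param seed Seed for the bootstrap.
#' @param fpf_grid Grid of false-positive fractions (default 101 points).
#' @return A `da_aroc` object with elements `marker_name`, `fpf_grid`,
#'   `tpf`, `aauc`, `ci_low`, `ci_high`, `n_healthy`, `n_diseased`,
#'   `n_boot`, `direction`, `boot_aauc`.
#' @seealso [empirical_auc()] for the unadjusted (pooled) comparison.
#' @export
covariate_adjusted_roc <- function(data, marker, disease = "diseased",
                                   covariate = "age",
                                   direction = c("higher_is_diseased",
                                                 "lower_is_diseased"),
                                   n_boot = 500, seed = 1,
                                   fpf_grid = seq(0, 1, length.out = 101)) {
  direction <- match.arg(direction)
  d <- tibble::as_tibble(data)
  miss <- setdiff(c(marker, disease, covariate), names(d))
  if (length(miss)) {
    abort_da(paste0("missing columns: ", paste(miss, collapse = ", ")),
             "da_schema_error")
  }
  y <- d[[marker]]; dis <- as.logical(d[[disease]]); x <- d[[covariate]]
  ok <- is.finite(y) & !is.na(dis) & is.finite(x)
  y <- y[ok]; dis <- dis[ok]; x <- x[ok]
  n_h <- sum(!dis); n_d <- sum(dis)
  if (n_h < 10 || n_d < 10) {
    abort_da("need >= 10 subjects per class", "da_insufficient_data")
  }

  aauc_of <- function(yh, xh, yd, xd) {
    fit <- lm(yh ~ xh)
    sig <- sqrt(sum(fit$residuals^2) / fit$df.residual)
    if (!is.finite(sig) || sig < 1e-10) {
      abort_da("zero healthy residual variance", "da_degenerate_error")
    }
    z <- (yd - (coef(fit)[1] + coef(fit)[2] * xd)) / sig
    u <- if (direction == "higher_is_diseased") 1 - pnorm(z) else pnorm(z)
    tpf <- vapply(fpf_grid, function(p) mean(u <= p), numeric(1))
    list(tpf = tpf, aauc = trapz(fpf_grid, tpf))
  }

  full <- aauc_of(y[!dis], x[!dis], y[dis], x[dis])
  ci <- c(NA_real_, NA_real_)
  boot_aauc <- NULL
  if (n_boot > 0) {
    local_seed_if(seed)
    ih <- which(!dis); id <- which(dis)
    boot_aauc <- vapply(seq_len(n_boot), function(b) {
      bh <- sample(ih, n_h, replace = TRUE)
      bd <- sample(id, n_d, replace = TRUE)
      tryCatch(aauc_of(y[bh], x[bh], y[bd], x[bd])$aauc,
               darkadaptr_error = function(e) NA_real_)
    }, numeric(1))
    ci <- unname(quantile(boot_aauc, c(0.025, 0.975), na.rm = TRUE))
    # percentile interval; clip to contain the point estimate
    ci[1] <- min(ci[1], full$aauc)
    ci[2] <- max(ci[2], full$aauc)
  }
  structure(list(marker_name = marker, fpf_grid = fpf_grid, tpf = full$tpf,
                 aauc = full$aauc, ci_low = ci[1], ci_high = ci[2],
                 n_healthy = n_h, n_diseased = n_d, n_boot = n_boot,
                 direction = direction, boot_aauc = boot_aauc),
            class = "da_aroc")
}

#' @export
print.da_aroc <- function(x, ...) {
  cat("<da_aroc>", x$marker_name, " AAUC:", signif(x$aauc, 3))
  if (is.finite(x$ci_low)) {
    cat(" (95% CI ", signif(x$ci_low, 3), "-", signif(x$ci_high, 3), ")")
  }
  cat("\n")
  invisible(x)
}

#' Tidy/glance methods for adjusted ROC objects
#'
#' @param x A `da_aroc` object.
#' @param ... Unused.
#' @return `tidy()`: the adjusted ROC curve as a tibble (`fpf`, `tpf`);
#'   `glance()`: one row with the AAUC, its bootstrap CI and sample sizes.
#' @method tidy da_aroc
#' @export
tidy.da_aroc <- function(x, ...) {
  tibble::tibble(fpf = x$fpf_grid, tpf = x$tpf)
}

#' @rdname tidy.da_aroc
#' @method glance da_aroc
#' @export
glance.da_aroc <- function(x, ...) {
  tibble::tibble(marker = x$marker_name, aauc = x$aauc, ci_low = x$ci_low,
                 ci_high = x$ci_high, n_healthy = x$n_healthy,
                 n_diseased = x$n_diseased, n_boot = x$n_boot)
}

#' Pooled (unadjusted) empirical AUC
#'
#' Wilcoxon/Mann-Whitney estimate of `P(marker_diseased > marker_healthy)`
#' with tie correction. Used as the unadjusted comparator for the
#' covariate-adjusted AUC.
#'
#' @param marker Numeric marker values.
#' @param diseased Logical disease indicator.
#' @return The pooled empirical AUC in \[0, 1\].
#' @export
empirical_auc <- function(marker, diseased) {
  diseased <- as.logical(diseased)
  r <- rank(marker)
  n1 <- sum(diseased); n0 <- sum(!diseased)
  (sum(r[diseased]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
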