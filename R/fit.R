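#' Parameter box for curve fitting
#'
#' Broad, physiologically plausible bounds used both as optimizer box
#' constraints and to center the weak truncated-normal priors (mean at the
#' box midpoint, SD equal to the half-width). The boxes for `t0` and `tf`
#' are conditional on `ct` (`t0 >= ct`, `tf <= ct`); internally the fit works
#' on the non-negative offsets `d0 = t0 - ct` and `df = ct - tf`.
#'
#' @return A named list of bounds.
#' @export
da_fit_bounds <- function() {
  list(ct = c(-1.5, 1.5),
       t0_max = 4.5,
       tau = c(0.05, 10),
       S2 = c(-1.0, -0.01),
       CRB = c(1, 45),
       tf_min = -3.5,
       d0 = c(0, 6),
       df = c(0, 5))
}

theta_to_params <- function(theta) {
  list(ct = theta[[1]], t0 = theta[[1]] + theta[[2]], tau = theta[[3]],
       S2 = theta[[4]], CRB = theta[[5]], tf = theta[[1]] - theta[[6]])
}

# threshold curve on raw parameter list, no validation (hot loop)
eval_curve_raw <- function(p, t) {
  cone <- p$ct + (p$t0 - p$ct) * exp(-t / p$tau)
  late <- t > p$CRB
  if (any(late)) {
    cone[late] <- cone[late] +
      log10(10^(p$S2 * (t[late] - p$CRB)) + 10^(p$tf - p$ct))
  }
  cone
}

# Weak truncated-normal prior penalty: -log density kernel, centered at the
# (possibly ct-conditional) box midpoint with SD = half-width, plus a stiff
# penalty keeping tf above its floor.
prior_penalty <- function(p, b) {
  pen <- function(x, lo, hi) {
    mid <- (lo + hi) / 2
    s <- (hi - lo) / 2
    0.5 * ((x - mid) / s)^2
  }
  pen(p$ct, b$ct[1], b$ct[2]) +
    pen(p$t0, p$ct, b$t0_max) +
    pen(p$tau, b$tau[1], b$tau[2]) +
    pen(p$S2, b$S2[1], b$S2[2]) +
    pen(p$CRB, b$CRB[1], b$CRB[2]) +
    pen(p$tf, b$tf_min, p$ct) +
    1e4 * max(0, b$tf_min - p$tf)^2
}

fit_objective <- function(theta, t, y, b) {
  p <- theta_to_params(theta)
  r <- y - eval_curve_raw(p, t)
  n <- length(y)
  rss <- sum(r * r)
  0.5 * n * log((rss + 1e-12) / n) + prior_penalty(p, b)
}

theta_box <- function(b) {
  list(lower = c(b$ct[1], b$d0[1], b$tau[1], b$S2[1], b$CRB[1], b$df[1]),
       upper = c(b$ct[2], b$d0[2], b$tau[2], b$S2[2], b$CRB[2], b$df[2]))
}

# Data-driven starts. Early points ride the staircase catch-up (biased above
# threshold), so the cone plateau is estimated as the *minimum* before each
# candidate break time; one start per candidate break covers the basins.
smart_starts <- function(t, y, b) {
  tf0 <- min(max(median(y[t >= quantile(t, 0.8)]), b$tf_min + 0.1), 1.4)
  crb_cands <- unique(pmin(pmax(c(5, 8, 12, 18, 28), b$CRB[1]), b$CRB[2]))
  purrr::map(crb_cands, function(g) {
    pre <- y[t <= g & t >= 2]
    ct0 <- if (length(pre)) min(pre) else median(y)
    ct0 <- min(max(ct0, tf0, b$ct[1] + 0.05), b$ct[2] - 0.05)
    d00 <- min(max(max(y) - ct0, 0.1), b$d0[2])
    c(ct0, d00, 1.2, -0.24, g, max(ct0 - tf0, 0.05))
  })
}

#' Fit the biphasic dark-adaptation curve to cyan threshold points
#'
#' Fits the six-parameter biphasic recovery model to a cyan-stimulus
#' threshold time series by penalized Gaussian maximum likelihood (mode
#' `"map_penalized"`, the default: multistart box-constrained quasi-Newton
#' optimization of the profile negative log-likelihood plus the weak
#' truncated-normal prior penalty of [da_fit_bounds()]), or by random-walk
#' Metropolis MCMC over the same posterior (mode `"mcmc"`; point estimates
#' are posterior medians). The same prior structure is used for every locus.
#'
#' @param points Data frame of cyan threshold points with columns `t_min`
#'   and `threshold_log` (see [extract_thresholds()]). At least 8 points
#'   spanning at least 15 minutes are required.
#' @param mode `"map_penalized"` (default) or `"mcmc"`.
#' @param n_starts Number of multistart draws in MAP mode (default 10).
#' @param n_iter,n_burn MCMC iterations kept / burned (mcmc mode).
#' @param seed Integer seed making the multistart (or chain) deterministic.
#' @param bounds Parameter box, see [da_fit_bounds()].
#' @return A `da_fit` object: list with elements `params` ([da_params()]),
#'   `se` (per-parameter uncertainty; posterior SD in mcmc mode, inverse
#'   curvature in MAP mode), `resid_sd`, `n`, `mode`, `objective`,
#'   `converged`, `seed`, and (mcmc mode) `draws`.
#' @seealso [tidy.da_fit()], [derive_outcome()], [fit_da_loci()]
#' @export
fit_da_curve <- function(points, mode = c("map_penalized", "mcmc"),
                         n_starts = 10, n_iter = 3000, n_burn = 1500,
                         seed = 1, bounds = da_fit_bounds()) {
  mode <- match.arg(mode)
  d <- tibble::as_tibble(points)
  if (!all(c("t_min", "threshold_log") %in% names(d))) {
    abort_da("points must have columns t_min and threshold_log",
             "da_schema_error")
  }
  d <- dplyr::arrange(dplyr::distinct(d, .data$t_min, .data$threshold_log),
                      .data$t_min)
  t <- d$t_min; y <- d$threshold_log
  if (length(t) < 8 || diff(range(t)) < 15) {
    abort_da("need >= 8 cyan points spanning >= 15 minutes",
             "da_insufficient_data")
  }
  b <- bounds
  box <- theta_box(b)
  local_seed_if(seed)

  structured <- smart_starts(t, y, b)
  starts <- c(structured,
              purrr::map(seq_len(max(n_starts - length(structured), 1)),
                         function(i) runif(6, box$lower, box$upper)))
  fits <- purrr::map(starts, function(s) {
    tryCatch(
      optim(s, fit_objective, t = t, y = y, b = b, method = "L-BFGS-B",
            lower = box$lower, upper = box$upper,
            control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
  })
  fits <- purrr::compact(fits)
  if (!length(fits)) {
    abort_da("optimizer failed to converge from every start", "da_fit_failure")
  }
  best <- fits[[which.min(purrr::map_dbl(fits, "value"))]]
  # Nelder-Mead polish (box enforced by clamping)
  clamp_obj <- function(th) {
    fit_objective(pmin(pmax(th, box$lower), box$upper), t, y, b)
  }
  pol <- tryCatch(optim(best$par, clamp_obj, method = "Nelder-Mead",
                        control = list(maxit = 1000, reltol = 1e-12)),
                  error = function(e) best)
  if (pol$value < best$value) {
    best <- pol
    best$par <- pmin(pmax(best$par, box$lower), box$upper)
  }
  p_hat <- theta_to_params(best$par)
  rss <- sum((y - eval_curve_raw(p_hat, t))^2)
  resid_sd <- sqrt(rss / length(y))

  if (mode == "map_penalized") {
    se <- map_se(best$par, t, y, b)
    out <- list(params = do.call(da_params, p_hat), se = se,
                resid_sd = resid_sd, n = length(y), mode = mode,
                objective = best$value, converged = TRUE, seed = seed,
                draws = NULL)
  } else {
    draws <- run_mcmc(best$par, t, y, b, box, n_iter = n_iter,
                      n_burn = n_burn)
    med <- apply(draws$theta, 2, median)
    p_hat <- theta_to_params(med)
    par_draws <- cbind(ct = draws$theta[, 1],
                       t0 = draws$theta[, 1] + draws$theta[, 2],
                       tau = draws$theta[, 3], S2 = draws$theta[, 4],
                       CRB = draws$theta[, 5],
                       tf = draws$theta[, 1] - draws$theta[, 6])
    rss <- sum((y - eval_curve_raw(p_hat, t))^2)
    out <- list(params = do.call(da_params, p_hat),
                se = apply(par_draws, 2, sd),
                resid_sd = sqrt(rss / length(y)), n = length(y), mode = mode,
                objective = NA_real_, converged = TRUE, seed = seed,
                draws = tibble::as_tibble(par_draws))
  }
  structure(out, class = "da_fit")
}

# curvature-based SEs in the natural parameterization (delta method on the
# (ct, d0, tau, S2, CRB, df) covariance); NA where the Hessian is not PD
map_se <- function(theta, t, y, b) {
  nm <- c("ct", "t0", "tau", "S2", "CRB", "tf")
  H <- tryCatch(optimHess(theta, fit_objective, t = t, y = y, b = b),
                error = function(e) NULL)
  se <- setNames(rep(NA_real_, 6), nm)
  if (is.null(H)) return(se)
  V <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(V) || any(!is.finite(diag(V))) || any(diag(V) < 0)) return(se)
  # jacobian of (ct, t0, tau, S2, CRB, tf) wrt theta
  J <- diag(6)
  J[2, ] <- c(1, 1, 0, 0, 0, 0)
  J[6, ] <- c(1, 0, 0, 0, 0, -1)
  J[3, 3] <- 1; J[4, 4] <- 1; J[5, 5] <- 1
  Vp <- J %*% V %*% t(J)
  dv <- diag(Vp)
  se[dv >= 0] <- sqrt(dv[dv >= 0])
  se
}

# adaptive random-walk Metropolis over (theta, log sigma)
run_mcmc <- function(theta0, t, y, b, box, n_iter, n_burn) {
  n <- length(y)
  log_post <- function(theta, lsig) {
    if (any(theta < box$lower) || any(theta > box$upper)) return(-Inf)
    p <- theta_to_params(theta)
    sig <- exp(lsig)
    rss <- sum((y - eval_curve_raw(p, t))^2)
    -n * lsig - rss / (2 * sig^2) - prior_penalty(p, b) -
      0.5 * (sig / 0.5)^2 + lsig # half-normal(0, 0.5) prior on sigma, jacobian
  }
  widths <- box$upper - box$lower
  prop <- c(widths / 60, 0.1)
  cur <- c(theta0, log(max(sd(y) / 5, 0.02)))
  lp <- log_post(cur[1:6], cur[7])
  keep <- matrix(NA_real_, n_iter, 7)
  acc <- 0L
  total <- n_burn + n_iter
  for (i in seq_len(total)) {
    cand <- cur + rnorm(7) * prop
    lp_c <- log_post(cand[1:6], cand[7])
    if (is.finite(lp_c) && log(runif(1)) < lp_c - lp) {
      cur <- cand; lp <- lp_c; acc <- acc + 1L
    }
    if (i <= n_burn && i %% 100 == 0) { # adapt toward ~0.23 acceptance
      rate <- acc / 100
      prop <- prop * exp(rate - 0.23)
      acc <- 0L
    }
    if (i > n_burn) keep[i - n_burn, ] <- cur
  }
  list(theta = keep[, 1:6], log_sigma = keep[, 7])
}

#' @export
print.da_fit <- function(x, ...) {
  cat("<da_fit> mode:", x$mode, " n:", x$n,
      " resid SD:", signif(x$resid_sd, 3), "\n")
  print(unlist(x$params))
  invisible(x)
}

#' Tidy a fitted dark-adaptation curve
#'
#' @param x A `da_fit` object.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`.
#' @method tidy da_fit
#' @export
tidy.da_fit <- function(x, ...) {
  tibble::tibble(term = names(x$params),
                 estimate = unlist(x$params, use.names = FALSE),
                 std.error = unname(x$se[names(x$params)]))
}

#' @rdname tidy.da_fit
#' @return For `glance()`: a one-row tibble with fit summaries.
#' @method glance da_fit
#' @export
glance.da_fit <- function(x, ...) {
  tibble::tibble(sigma = x$resid_sd, objective = x$objective, nobs = x$n,
                 mode = x$mode, converged = x$converged)
}

#' Derive the clinical outcome of one locus
#'
#' Combines a fitted curve with the rod-function flag into the per-locus
#' outcome: cone threshold `CT = ct`; if rod function is present, final rod
#' threshold `FT = tf` and RIT from [rod_intercept_time()]; otherwise the
#' final threshold is cone-mediated (`FT = CT`) and RIT is recorded as
#' `t_max` (censored). A fitted rod plateau above the criterion likewise
#' yields a censored RIT.
#'
#' @param fit A `da_fit` object (or a [da_params()] set).
#' @param rod_function Logical from [detect_rod_function()].
#' @param criterion,t_max Passed to [rod_intercept_time()].
#' @return A one-row tibble with `CT`, `FT`, `RIT`, `rit_censored`,
#'   `rod_function_present`, `fit_quality` (residual SD).
#' @export
derive_outcome <- function(fit, rod_function, criterion = -1.4, t_max = 60) {
  stopifnot(is_flag(rod_function))
  p <- if (inherits(fit, "da_fit")) fit$params else coerce_params(fit)
  fq <- if (inherits(fit, "da_fit")) fit$resid_sd else NA_real_
  if (!rod_function) {
    return(tibble::tibble(CT = p$ct, FT = p$ct, RIT = t_max,
                          rit_censored = TRUE, rod_function_present = FALSE,
                          fit_quality = fq))
  }
  rit <- rod_intercept_time(p, criterion = criterion, t_max = t_max)
  tibble::tibble(CT = p$ct, FT = p$tf, RIT = rit$rit,
                 rit_censored = rit$censored, rod_function_present = TRUE,
                 fit_quality = fq)
}

#' Fit all loci of a threshold-point table
#'
#' The workhorse verb of the fitting stage: groups a threshold-point table by
#' subject and eccentricity, fits the biphasic model to the cyan points of
#' each locus, checks for rod function via the cyan/red separation rule, and
#' derives `CT`, `FT` and `RIT` per locus. Loci whose fit fails (too few
#' points, non-convergence, or a cone plateau at or below the criterion) are
#' returned with `NA` outcomes and a warning.
#'
#' @param thresholds Tibble of threshold points (from [extract_thresholds()]
#'   or [read_thresholds()]): columns `subject_id`, `eccentricity_deg`,
#'   `color`, `t_min`, `threshold_log` (plus `group`, `age`, carried
#'   through).
#' @param mode,n_starts,seed,bounds Passed to [fit_da_curve()]; per-locus
#'   seeds are derived deterministically from `seed`.
#' @param margin,window Passed to [detect_rod_function()].
#' @param criterion,t_max Passed to [derive_outcome()].
#' @return A tibble, one row per subject x eccentricity, with identifying
#'   columns and the outcome columns of [derive_outcome()].
#' @export
fit_da_loci <- function(thresholds, mode = "map_penalized", n_starts = 10,
                        seed = 1, bounds = da_fit_bounds(), margin = 0.3,
                        window = 10, criterion = -1.4, t_max = 60,
                        min_points = 8, min_span = 15) {
  d <- tibble::as_tibble(thresholds)
  need <- c("subject_id", "eccentricity_deg", "color", "t_min",
            "threshold_log")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    abort_da(paste0("missing columns: ", paste(miss, collapse = ", ")),
             "da_schema_error")
  }
  carry <- intersect(c("group", "age"), names(d))
  groups <- d |>
    dplyr::group_by(.data$subject_id, .data$eccentricity_deg) |>
    dplyr::group_split()
  purrr::imap(groups, function(g, i) {
    id <- g |>
      dplyr::slice(1) |>
      dplyr::select(dplyr::all_of(c("subject_id", carry, "eccentricity_deg")))
    cyan <- dplyr::filter(g, .data$color == "cyan505")
    # Fit on bracketed points (staircase within one up-step of threshold):
    # unbracketed catch-up points from the initial descent sit well above
    # threshold and would bias the cone branch. Floor-railed points are kept
    # regardless (the staircase cannot bracket at the device floor, yet the
    # rail is the measured rod plateau).
    cyan_fit <- cyan
    if (all(c("bracketed", "at_floor") %in% names(cyan))) {
      br <- dplyr::filter(cyan, .data$bracketed | .data$at_floor)
      if (nrow(br) >= min_points && diff(range(br$t_min)) >= min_span) {
        cyan_fit <- br
      }
    }
    red <- dplyr::filter(g, .data$color == "red627")
    rod <- detect_rod_function(cyan, red, margin = margin, window = window)
    out <- tryCatch({
      fit <- fit_da_curve(cyan_fit, mode = mode, n_starts = n_starts,
                          seed = seed + i, bounds = bounds)
      derive_outcome(fit, rod, criterion = criterion, t_max = t_max)
    }, darkadaptr_error = function(e) {
      warn(paste0("locus ", id$subject_id, " @", id$eccentricity_deg,
                  " deg failed: ", conditionMessage(e)))
      tibble::tibble(CT = NA_real_, FT = NA_real_, RIT = NA_real_,
                     rit_censored = NA, rod_function_present = rod,
                     fit_quality = NA_real_)
    })
    dplyr::bind_cols(id, out)
  }) |>
    dplyr::bind_rows()
}
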