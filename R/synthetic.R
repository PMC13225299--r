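#' Specification of a synthetic dark-adaptometry cohort
#'
#' Defines the statistical structure of a simulated study cohort: group
#' sizes and age ranges mirror the study design (35 AMD patients aged
#' roughly 47--86 with 28.6% SDD prevalence and an early/intermediate/late
#' severity mix of 11/20/4, versus 35 healthy volunteers aged 22--82);
#' effect sizes on rod intercept time are anchored to the structure-function
#' regression (SDD about +20 min, intermediate/late AMD about +25--28 min,
#' early AMD near zero), with a multiplicative eccentricity gradient making
#' 2 degrees the most affected locus; the healthy RIT age slope (1
#' min/decade) sits in the published 0.6--1.2 min/decade range; healthy
#' steady-state anchors are CT -0.7 / FT -2.2 logUnits (0.2 logUnits more
#' sensitive than the reported AMD medians -0.49/-1.99). All values are
#' overridable.
#'
#' @param n_healthy,n_amd Group sizes.
#' @param age_range_healthy,age_range_amd Uniform age ranges, years.
#' @param prop_sdd Proportion of AMD subjects with subretinal drusenoid
#'   deposits.
#' @param severity_props Named proportions (`eAMD`, `iAMD`, `lateAMD`) of
#'   study-eye diagnosis among AMD subjects; must sum to 1.
#' @param fellow_props Same, for the fellow eye.
#' @param rit_intercept Healthy RIT fixed intercept at 2 degrees and age 0,
#'   minutes.
#' @param rit_age_slope Healthy RIT age slope, min/decade.
#' @param rit_ecc_offsets Named additive offsets (minutes) for 2/4/6 deg.
#' @param rit_disease Named RIT prolongations (minutes) by study-eye
#'   diagnosis.
#' @param rit_sdd_effect RIT prolongation for SDD presence, minutes.
#' @param ecc_disease_scale Named multiplier applied to disease + SDD
#'   effects per eccentricity (gradient; 2 deg worst).
#' @param rit_between_sd,rit_resid_sd Between-subject and locus-level SD of
#'   RIT, minutes.
#' @param ct_healthy,ct_age_slope,ct_disease,ct_sdd_effect,ct_between_sd,ct_resid_sd
#'   Cone-threshold anchors/effects, logUnits (positive shifts = elevation).
#' @param ft_healthy,ft_age_slope,ft_disease,ft_sdd_effect,ft_between_sd,ft_resid_sd
#'   Final-rod-threshold anchors/effects, logUnits.
#' @param t0_mean,t0_sd,tau_mean,tau_sd,S2_mean,S2_sd Remaining curve
#'   parameter distributions.
#' @param psycho_slope Psychometric function slope, logUnits.
#' @param lapse,guess Lapse and guess rates of the simulated observer.
#' @param criterion,t_max RIT criterion (logUnits) and session cap (min).
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_healthy = 35, n_amd = 35,
                        age_range_healthy = c(21.7, 82.0),
                        age_range_amd = c(47.3, 86.2),
                        prop_sdd = 10 / 35,
                        severity_props = c(eAMD = 11 / 35, iAMD = 20 / 35,
                                           lateAMD = 4 / 35),
                        fellow_props = c(none = 2 / 35, eAMD = 10 / 35,
                                         iAMD = 16 / 35, lateAMD = 7 / 35),
                        rit_intercept = 10, rit_age_slope = 1.0,
                        rit_ecc_offsets = c(`2` = 0, `4` = -1, `6` = -2),
                        rit_disease = c(eAMD = 3, iAMD = 28, lateAMD = 26),
                        rit_sdd_effect = 20,
                        ecc_disease_scale = c(`2` = 1.25, `4` = 1.0,
                                              `6` = 0.85),
                        rit_between_sd = 2, rit_resid_sd = 2,
                        ct_healthy = -0.7, ct_age_slope = 0.02,
                        ct_disease = c(eAMD = 0.05, iAMD = 0.12,
                                       lateAMD = 0.15),
                        ct_sdd_effect = 0.05,
                        ct_between_sd = 0.08, ct_resid_sd = 0.06,
                        ft_healthy = -2.2, ft_age_slope = 0.03,
                        ft_disease = c(eAMD = 0.05, iAMD = 0.3,
                                       lateAMD = 0.45),
                        ft_sdd_effect = 0.25,
                        ft_between_sd = 0.12, ft_resid_sd = 0.1,
                        t0_mean = 2.8, t0_sd = 0.2,
                        tau_mean = 1.2, tau_sd = 0.15,
                        S2_mean = -0.24, S2_sd = 0.02,
                        psycho_slope = 0.1, lapse = 0.02, guess = 0.01,
                        criterion = -1.4, t_max = 60) {
  spec <- as.list(environment())
  props_ok <- function(p) all(p >= 0 & p <= 1) && abs(sum(p) - 1) < 1e-8
  if (!props_ok(severity_props) || !props_ok(fellow_props)) {
    abort_da("severity/fellow proportions must be in [0,1] and sum to 1",
             "da_invalid_input")
  }
  if (prop_sdd < 0 || prop_sdd > 1) {
    abort_da("prop_sdd must be in [0,1]", "da_invalid_input")
  }
  sds <- c(rit_between_sd, rit_resid_sd, ct_between_sd, ct_resid_sd,
           ft_between_sd, ft_resid_sd, t0_sd, tau_sd, S2_sd)
  if (any(sds < 0)) abort_da("SDs must be >= 0", "da_invalid_input")
  structure(spec, class = "cohort_spec")
}

#' Staircase protocol parameters
#'
#' Two-color (cyan 505 nm / red 627 nm) Goldmann III protocol at 2, 4 and 6
#' degrees temporal: 5-up/1-down staircase (5 dB darker after a seen
#' response, 1 dB brighter after a miss) over a 0--36 dB dynamic range,
#' locus advancing after each seen response in ascending order, up to a
#' 60-minute session with early termination once steady-state *rod*
#' thresholds (stable cyan levels separated below red) are reached at all
#' loci. A locus that produces no seen response for `anti_starvation`
#' consecutive presentations yields its turn so the rotation cannot stall.
#'
#' @param eccentricities Test loci, degrees temporal.
#' @param step_down_db,step_up_db Staircase steps, dB.
#' @param db_range Dynamic range, dB.
#' @param t_max Session cap, minutes.
#' @param interval_s Inter-presentation interval, seconds.
#' @param start_level_db Initial attenuation, dB.
#' @param stimulus_ms Stimulus duration, ms (metadata only).
#' @param min_session Minimum session length (minutes) before early
#'   termination is considered.
#' @param steady_n,steady_span_db A locus is rod-steady when its last
#'   `steady_n` seen cyan levels span less than `steady_span_db` dB (and
#'   cyan sits below red by the separation margin).
#' @param steady_margin Cyan-below-red separation (logUnits) required before
#'   a stable plateau counts as a *rod* plateau.
#' @param anti_starvation Consecutive misses before the scheduler advances
#'   anyway.
#' @return A `protocol_spec` list.
#' @export
protocol_spec <- function(eccentricities = c(2, 4, 6), step_down_db = 5,
                          step_up_db = 1, db_range = c(0, 36), t_max = 60,
                          interval_s = 4, start_level_db = 0,
                          stimulus_ms = 200, min_session = 20,
                          steady_n = 5, steady_span_db = 1,
                          steady_margin = 0.3, anti_starvation = 10) {
  if (step_down_db <= 0 || step_up_db <= 0) {
    abort_da("staircase steps must be positive", "da_invalid_input")
  }
  if (t_max > 60) abort_da("session cap must be <= 60 min", "da_invalid_input")
  structure(as.list(environment()), class = "protocol_spec")
}

# Allocate n category labels matching the given proportions exactly
# (largest-remainder rounding), in random order. Keeps the cohort
# composition fixed at the study proportions for every seed, which also
# guarantees an estimable diagnosis design downstream.
allocate_labels <- function(props, n) {
  raw <- props * n
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    order_rem <- order(raw - counts, decreasing = TRUE)
    counts[order_rem[seq_len(short)]] <- counts[order_rem[seq_len(short)]] + 1
  }
  sample(rep(names(props), counts))
}

# Solve the crossing time of the biphasic curve with the criterion, with no
# session cap (used when calibrating CRB/S2 to a target RIT).
crossing_time <- function(p, criterion, t_hi = 5000) {
  f <- function(t) {
    p$ct + (p$t0 - p$ct) * exp(-t / p$tau) +
      log10(10^(p$S2 * (t - p$CRB)) + 10^(p$tf - p$ct)) - criterion
  }
  lo <- p$CRB + 1e-6
  if (f(lo) <= 0) return(lo)
  if (f(t_hi) > 0) return(Inf)
  uniroot(f, lower = lo, upper = t_hi, tol = 1e-4)$root
}

# Calibrate CRB (then, at the CRB bounds, S2) so the implied rod intercept
# time equals the target; clamp with a warning when unattainable.
calibrate_crb_s2 <- function(ct, t0, tau, S2, tf, target, criterion,
                             crb_box = c(1, 45), s2_box = c(-1.0, -0.01)) {
  if (tf > criterion) { # rod plateau above criterion: RIT censors regardless
    return(list(CRB = min(max(target * 0.6, crb_box[1]), crb_box[2]),
                S2 = S2, clamped = FALSE))
  }
  base <- list(ct = ct, t0 = t0, tau = tau, S2 = S2, tf = tf)
  t_at_crb <- function(crb) {
    crossing_time(c(base, CRB = crb), criterion)
  }
  t_lo <- t_at_crb(crb_box[1]); t_hi <- t_at_crb(crb_box[2])
  if (target >= t_lo && target <= t_hi) {
    crb <- uniroot(function(c) t_at_crb(c) - target,
                   lower = crb_box[1], upper = crb_box[2], tol = 1e-4)$root
    return(list(CRB = crb, S2 = S2, clamped = FALSE))
  }
  # target outside CRB range: re-solve the rod slope at the nearest bound
  crb <- if (target < t_lo) crb_box[1] else crb_box[2]
  t_at_s2 <- function(s2) {
    crossing_time(list(ct = ct, t0 = t0, tau = tau, S2 = s2, CRB = crb,
                       tf = tf), criterion)
  }
  t_steep <- t_at_s2(s2_box[1]); t_flat <- t_at_s2(s2_box[2])
  if (target >= t_steep && target <= t_flat) {
    s2 <- uniroot(function(s) t_at_s2(s) - target,
                  lower = s2_box[1], upper = s2_box[2], tol = 1e-5)$root
    return(list(CRB = crb, S2 = s2, clamped = FALSE))
  }
  s2 <- if (target < t_steep) s2_box[1] else s2_box[2]
  list(CRB = crb, S2 = s2, clamped = TRUE)
}

#' Generate a synthetic cohort with ground-truth recovery curves
#'
#' Draws subjects (ages uniform within group ranges; SDD status, study- and
#' fellow-eye diagnoses per the spec proportions) and builds per-locus
#' ground-truth biphasic curve parameters: steady-state thresholds and a
#' target RIT are assembled from the healthy anchors plus age slope,
#' eccentricity offsets, disease and SDD effects (scaled by the
#' eccentricity gradient), a between-subject random intercept and
#' locus-level noise; the cone--rod break (and, at its bounds, the rod
#' slope) is then solved so the implied [rod_intercept_time()] matches the
#' target. Censoring at `t_max` arises naturally when the target RIT is 60
#' minutes or more, or when the drawn rod plateau lies above the criterion
#' (no measurable rod function).
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @return A tibble, one row per subject x eccentricity: identifiers,
#'   covariates, the six true curve parameters, the latent (uncensored)
#'   `rit_latent` target, and `true_CT`, `true_FT`, `true_RIT`,
#'   `true_rit_censored` consistent with the truth parameters by
#'   construction.
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  local_seed_if(seed)
  n <- spec$n_healthy + spec$n_amd
  subjects <- tibble::tibble(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = rep(c("healthy", "AMD"), c(spec$n_healthy, spec$n_amd)),
    age = c(runif(spec$n_healthy, spec$age_range_healthy[1],
                  spec$age_range_healthy[2]),
            runif(spec$n_amd, spec$age_range_amd[1], spec$age_range_amd[2])),
    sdd = c(rep(FALSE, spec$n_healthy),
            allocate_labels(c(`FALSE` = 1 - spec$prop_sdd,
                              `TRUE` = spec$prop_sdd),
                            spec$n_amd) == "TRUE"),
    diagnosis_se = c(rep("none", spec$n_healthy),
                     allocate_labels(spec$severity_props, spec$n_amd)),
    diagnosis_fe = c(rep("none", spec$n_healthy),
                     allocate_labels(spec$fellow_props, spec$n_amd)),
    b_rit = rnorm(n, 0, spec$rit_between_sd),
    b_ct = rnorm(n, 0, spec$ct_between_sd),
    b_ft = rnorm(n, 0, spec$ft_between_sd))

  eff <- function(tbl, diag) ifelse(diag == "none", 0, tbl[diag])
  grid <- tidyr::expand_grid(subjects,
                             eccentricity_deg = c(2, 4, 6)) |>
    dplyr::mutate(
      ecc_chr = as.character(.data$eccentricity_deg),
      scale = spec$ecc_disease_scale[.data$ecc_chr],
      age_dec = .data$age / 10,
      ct = spec$ct_healthy + spec$ct_age_slope * .data$age_dec +
        (eff(spec$ct_disease, .data$diagnosis_se) +
           spec$ct_sdd_effect * .data$sdd) * .data$scale +
        .data$b_ct + rnorm(dplyr::n(), 0, spec$ct_resid_sd),
      ct = pmin(pmax(.data$ct, -1.2), 1.2),
      tf = spec$ft_healthy + spec$ft_age_slope * .data$age_dec +
        (eff(spec$ft_disease, .data$diagnosis_se) +
           spec$ft_sdd_effect * .data$sdd) * .data$scale +
        .data$b_ft + rnorm(dplyr::n(), 0, spec$ft_resid_sd),
      tf = pmin(pmax(.data$tf, -3.4), .data$ct - 0.01),
      t0 = pmax(rnorm(dplyr::n(), spec$t0_mean, spec$t0_sd),
                .data$ct + 0.5),
      tau = pmin(pmax(rnorm(dplyr::n(), spec$tau_mean, spec$tau_sd), 0.3), 5),
      S2_draw = pmin(pmax(rnorm(dplyr::n(), spec$S2_mean, spec$S2_sd),
                          -1.0), -0.01),
      rit_latent = pmax(
        spec$rit_intercept + spec$rit_age_slope * .data$age_dec +
          spec$rit_ecc_offsets[.data$ecc_chr] +
          (eff(spec$rit_disease, .data$diagnosis_se) +
             spec$rit_sdd_effect * .data$sdd) * .data$scale +
          .data$b_rit + rnorm(dplyr::n(), 0, spec$rit_resid_sd),
        8))

  cal <- purrr::pmap(
    list(grid$ct, grid$t0, grid$tau, grid$S2_draw, grid$tf,
         grid$rit_latent),
    function(ct, t0, tau, s2, tf, target) {
      calibrate_crb_s2(ct, t0, tau, s2, tf, target, spec$criterion)
    })
  grid$CRB <- purrr::map_dbl(cal, "CRB")
  grid$S2 <- purrr::map_dbl(cal, "S2")
  n_clamped <- sum(purrr::map_lgl(cal, "clamped"))
  if (n_clamped > 0) {
    warn(paste0(n_clamped,
                " loci had target RIT unattainable within parameter bounds;",
                " clamped"))
  }
  rit <- purrr::pmap(
    list(grid$ct, grid$t0, grid$tau, grid$S2, grid$CRB, grid$tf),
    function(ct, t0, tau, S2, CRB, tf) {
      rod_intercept_time(list(ct = ct, t0 = t0, tau = tau, S2 = S2,
                              CRB = CRB, tf = tf),
                         criterion = spec$criterion, t_max = spec$t_max)
    }) |>
    dplyr::bind_rows()
  grid |>
    dplyr::mutate(dplyr::across(dplyr::all_of(c("ct", "tf", "t0", "tau",
                                                "rit_latent", "CRB", "S2")),
                                unname)) |>
    dplyr::mutate(true_CT = .data$ct, true_FT = .data$tf,
                  true_RIT = rit$rit, true_rit_censored = rit$censored) |>
    dplyr::select(-dplyr::all_of(c("b_rit", "b_ct", "b_ft", "ecc_chr",
                                   "scale", "age_dec", "S2_draw")))
}

#' Simulate one staircase dark-adaptometry session
#'
#' Runs the full two-color, three-locus adaptive staircase against a
#' subject's ground-truth curves. One staircase state is kept per
#' (locus, color); the scheduler cycles (2 cyan, 2 red, 4 cyan, ..., 6 red),
#' advancing after each seen response (or after `anti_starvation` misses).
#' At each presentation, time has advanced in real time
#' (`interval_s` seconds per presentation), the true threshold is the
#' biphasic curve for cyan and the cone-only branch for red (627 nm
#' detection stays cone-mediated), and the observer sees with probability
#' `guess + (1 - guess - lapse) * Phi((stim_log - threshold_log)/slope)` —
#' i.e. more often the brighter the stimulus is relative to threshold
#' (`slope = 0` gives the deterministic ideal observer). Levels are clamped
#' to the 0--36 dB range. The session stops at `t_max` or as soon as every
#' locus shows a steady rod plateau.
#'
#' @param truth Tibble of truth rows for one subject (one row per
#'   eccentricity, as produced by [generate_cohort()]), with the curve
#'   parameter columns `ct, t0, tau, S2, CRB, tf`.
#' @param protocol A [protocol_spec()].
#' @param slope,lapse,guess Psychometric observer parameters (logUnits /
#'   rates).
#' @param cal_const Device calibration, see [db_to_log()].
#' @param seed Integer seed.
#' @return A tibble of presentation records: `subject_id`, `group`, `age`,
#'   `eye`, `eccentricity_deg`, `color`, `t_min`, `level_db`, `seen`.
#' @export
simulate_session <- function(truth, protocol = protocol_spec(), slope = 0.1,
                             lapse = 0.02, guess = 0.01, cal_const = 2.0,
                             seed = 1) {
  tr <- tibble::as_tibble(truth)
  eccs <- protocol$eccentricities
  if (!all(eccs %in% tr$eccentricity_deg)) {
    abort_da("truth lacks parameters for some protocol eccentricities",
             "da_invalid_input")
  }
  local_seed_if(seed)
  tr <- tr[match(eccs, tr$eccentricity_deg), ]
  params <- purrr::map(seq_along(eccs), function(i) {
    list(ct = tr$ct[i], t0 = tr$t0[i], tau = tr$tau[i], S2 = tr$S2[i],
         CRB = tr$CRB[i], tf = tr$tf[i])
  })
  sched <- tidyr::expand_grid(ecc_i = seq_along(eccs),
                              color = c("cyan505", "red627"))
  ns <- nrow(sched)
  level <- rep(protocol$start_level_db, ns)
  misses <- rep(0L, ns)
  seen_hist <- purrr::map(seq_len(ns), function(i) numeric(0))
  last_seen_log <- rep(NA_real_, ns)
  max_pres <- ceiling(protocol$t_max * 60 / protocol$interval_s)
  rec <- vector("list", max_pres)
  cur <- 1L
  p_seen <- function(stim_log, thr_log) {
    base <- if (slope <= 1e-9) {
      as.numeric(stim_log >= thr_log)
    } else {
      pnorm((stim_log - thr_log) / slope)
    }
    guess + (1 - guess - lapse) * base
  }
  rod_steady <- function() {
    all(purrr::map_lgl(seq_along(eccs), function(e) {
      i_cy <- which(sched$ecc_i == e & sched$color == "cyan505")
      i_rd <- which(sched$ecc_i == e & sched$color == "red627")
      h <- seen_hist[[i_cy]]
      if (length(h) < protocol$steady_n) return(FALSE)
      h5 <- tail(h, protocol$steady_n)
      if (diff(range(h5)) >= protocol$steady_span_db) return(FALSE)
      cy <- db_to_log(median(h5), cal_const)
      rd <- last_seen_log[i_rd]
      is.finite(rd) && cy < rd - protocol$steady_margin
    }))
  }
  for (k in seq_len(max_pres)) {
    t_min <- k * protocol$interval_s / 60
    if (t_min > protocol$t_max) break
    e <- sched$ecc_i[cur]
    col <- sched$color[cur]
    thr <- if (col == "cyan505") {
      eval_curve_raw(params[[e]], t_min)
    } else {
      cone_threshold_curve(params[[e]], t_min)
    }
    stim_log <- cal_const - level[cur] / 10
    seen <- runif(1) < p_seen(stim_log, thr)
    rec[[k]] <- list(eccentricity_deg = eccs[e], color = col, t_min = t_min,
                     level_db = level[cur], seen = seen)
    if (seen) {
      if (col == "cyan505") {
        seen_hist[[cur]] <- c(seen_hist[[cur]], level[cur])
      }
      last_seen_log[cur] <- stim_log
      level[cur] <- min(level[cur] + protocol$step_down_db,
                        protocol$db_range[2])
      misses[cur] <- 0L
      cur <- if (cur == ns) 1L else cur + 1L
    } else {
      level[cur] <- max(level[cur] - protocol$step_up_db,
                        protocol$db_range[1])
      misses[cur] <- misses[cur] + 1L
      if (misses[cur] >= protocol$anti_starvation) {
        misses[cur] <- 0L
        cur <- if (cur == ns) 1L else cur + 1L
      }
    }
    if (t_min >= protocol$min_session && k %% 25 == 0 && rod_steady()) break
  }
  out <- dplyr::bind_rows(purrr::compact(rec))
  id_cols <- tibble::tibble(
    subject_id = tr$subject_id[1] %||% "S001",
    group = (tr$group[1] %||% NA_character_),
    age = (tr$age[1] %||% NA_real_),
    eye = "study")
  dplyr::bind_cols(id_cols[rep(1, nrow(out)), ], out)
}

#' Simulate staircase sessions for a whole cohort
#'
#' @param cohort Truth tibble from [generate_cohort()].
#' @param protocol A [protocol_spec()].
#' @param spec The [cohort_spec()] supplying observer parameters
#'   (psychometric slope, lapse, guess).
#' @param cal_const Device calibration constant.
#' @param seed Integer seed; per-subject seeds are derived from it.
#' @return Presentation records for all subjects (schema of
#'   [simulate_session()]).
#' @export
simulate_cohort <- function(cohort, protocol = protocol_spec(),
                            spec = cohort_spec(), cal_const = 2.0,
                            seed = 1) {
  ids <- unique(cohort$subject_id)
  purrr::imap(split(tibble::as_tibble(cohort), cohort$subject_id)[ids],
              function(tr, id) {
                i <- match(id, ids)
                simulate_session(tr, protocol = protocol,
                                 slope = spec$psycho_slope,
                                 lapse = spec$lapse, guess = spec$guess,
                                 cal_const = cal_const,
                                 seed = (as.integer(seed) %% 1000003L) *
                                   1000L + i)
              }) |>
    dplyr::bind_rows()
}
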