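# direct generator for healthy normative data (random-intercept LMM)
simulate_healthy_lmm <- function(n_subj = 35, slope = 1.0, intercept = 10,
                                 ecc_off = c(`2` = 0, `4` = -1, `6` = -2),
                                 sd_subj = 2, sd_resid = 2, seed = 1) {
  withr::with_seed(seed, {
    subj <- tibble::tibble(subject_id = sprintf("H%03d", seq_len(n_subj)),
                           group = "healthy",
                           age = runif(n_subj, 20, 80),
                           b = rnorm(n_subj, 0, sd_subj))
    tidyr::expand_grid(subj, eccentricity_deg = c(2, 4, 6)) |>
      dplyr::mutate(RIT = intercept + slope * age / 10 +
                      ecc_off[as.character(eccentricity_deg)] + b +
                      rnorm(dplyr::n(), 0, sd_resid)) |>
      dplyr::select(-b)
  })
}

test_that("normative fit recovers a known age slope", {
  d <- simulate_healthy_lmm(seed = 8)
  m <- fit_normative(d, "RIT")
  td <- tidy(m)
  slope <- td$estimate[td$term == "age_decade"]
  se <- td$std.error[td$term == "age_decade"]
  expect_true(slope - 1.96 * se <= 1.0 && 1.0 <= slope + 1.96 * se)
  expect_gt(m$sd_subject, 0.5)
  expect_gt(m$sd_resid, 1)
})

test_that("zero-noise data are interpolated exactly", {
  d <- simulate_healthy_lmm(sd_subj = 0, sd_resid = 0, seed = 3)
  m <- fit_normative(d, "RIT")
  expect_equal(unname(m$fixef[c("intercept", "age_decade", "ecc4", "ecc6")]),
               c(10, 1, -1, -2), tolerance = 1e-7)
  # interval collapses to the point prediction
  pi <- predict_interval(m, 50, 4)
  expect_equal(pi$pi_low, pi$pi_high, tolerance = 1e-6)
  expect_equal(pi$predicted_median, 10 + 5 - 1, tolerance = 1e-6)
})

test_that("single-eccentricity designs fit a reduced model", {
  d <- dplyr::filter(simulate_healthy_lmm(seed = 4), eccentricity_deg == 4)
  m <- fit_normative(d, "RIT")
  expect_false(any(grepl("^ecc", names(m$fixef))))
  expect_silent(predict_interval(m, 50, 4))
})

test_that("degenerate and undersized designs are rejected", {
  d <- simulate_healthy_lmm(seed = 5) |>
    dplyr::filter(eccentricity_deg == 2) |>
    dplyr::mutate(age = 50)
  expect_error(fit_normative(d, "RIT"), class = "da_degenerate_design")
  expect_error(fit_normative(simulate_healthy_lmm(n_subj = 5, seed = 6),
                             "RIT"),
               class = "da_insufficient_data")
})

test_that("prediction interval matches the closed form", {
  m <- structure(list(outcome_name = "RIT", backend = "reml",
                      fixef = c(intercept = 10, age_decade = 1),
                      fixef_se = c(intercept = 0, age_decade = 0),
                      sd_subject = 2, sd_resid = 2, ecc_levels = 2,
                      ref_ecc = 2, age_range = c(20, 80), n_subjects = 35,
                      n_loci = 105, draws = NULL),
                 class = "da_normative")
  pi <- predict_interval(m, 60, 2)
  expect_equal(pi$predicted_median, 16.0)
  expect_equal(pi$pi_high - pi$predicted_median, 1.96 * sqrt(8),
               tolerance = 1e-3)
  # width constant in age and across eccentricities
  pis <- predict_interval(m, c(30, 50, 70), 2)
  expect_equal(diff(range(pis$pi_high - pis$pi_low)), 0, tolerance = 1e-10)
})

test_that("95 percent interval covers about 95 percent of fresh loci", {
  # coverage of the procedure, averaged over training replicates so the
  # check measures calibration rather than one training draw
  cover <- purrr::map_dbl(1:6, function(r) {
    train <- simulate_healthy_lmm(seed = 140 + r)
    m <- fit_normative(train, "RIT")
    fresh <- simulate_healthy_lmm(n_subj = 334, seed = 150 + r)[1:1000, ]
    pi <- predict_interval(m, fresh$age, fresh$eccentricity_deg)
    mean(fresh$RIT >= pi$pi_low & fresh$RIT <= pi$pi_high)
  })
  expect_gte(mean(cover), 0.93)
  expect_lte(mean(cover), 0.97)
})

test_that("bayes backend agrees with REML on recovery", {
  d <- simulate_healthy_lmm(seed = 14)
  mr <- fit_normative(d, "RIT", backend = "reml")
  mb <- fit_normative(d, "RIT", backend = "bayes", seed = 14)
  expect_lt(abs(mr$fixef[["age_decade"]] - mb$fixef[["age_decade"]]), 0.15)
  expect_lt(abs(mr$sd_resid - mb$sd_resid), 0.4)
  # posterior-predictive interval close to the normal-theory one
  pr <- predict_interval(mr, 60, 4)
  pb <- predict_interval(mb, 60, 4)
  expect_lt(abs(pr$predicted_median - pb$predicted_median), 0.5)
  expect_lt(abs((pr$pi_high - pr$pi_low) - (pb$pi_high - pb$pi_low)), 1.5)
})

test_that("deviations follow the study sign conventions", {
  m_rit <- structure(list(outcome_name = "RIT", backend = "reml",
                          fixef = c(intercept = 20, age_decade = 0),
                          fixef_se = c(intercept = 0, age_decade = 0),
                          sd_subject = 2.55, sd_resid = 2.55,
                          ecc_levels = 2, ref_ecc = 2, age_range = c(20, 80),
                          n_subjects = 35, n_loci = 105, draws = NULL),
                     class = "da_normative")
  m_ft <- structure(list(outcome_name = "FT", backend = "reml",
                         fixef = c(intercept = -2, age_decade = 0),
                         fixef_se = c(intercept = 0, age_decade = 0),
                         sd_subject = 0.15, sd_resid = 0.15,
                         ecc_levels = 2, ref_ecc = 2, age_range = c(20, 80),
                         n_subjects = 35, n_loci = 105, draws = NULL),
                    class = "da_normative")
  outcomes <- tibble::tibble(subject_id = c("A", "B", "C"), group = "AMD",
                             age = 60, eccentricity_deg = 2,
                             RIT = c(20, 60, 25), rit_censored = c(FALSE, TRUE, FALSE),
                             FT = c(-2, -1, -2.05))
  dev <- compute_deviations(outcomes, list(RIT = m_rit, FT = m_ft))
  rit <- dplyr::filter(dev, outcome_name == "RIT")
  # observed at the median: deviation zero, normal
  expect_equal(rit$deviation[1], 0)
  expect_false(rit$abnormal[1])
  # censored 60 versus predicted 20 (pi_high 30): delay 40 is a lower bound
  expect_equal(rit$deviation[2], 40)
  expect_true(rit$abnormal[2])
  expect_true(rit$censored[2])
  ft <- dplyr::filter(dev, outcome_name == "FT")
  # elevated threshold means sensitivity loss: negative deviation
  expect_equal(ft$deviation[2], -1)
  expect_true(ft$abnormal[2])
  expect_false(any(ft$censored))
  # missing model is a configuration error
  expect_error(compute_deviations(outcomes, list(RIT = m_rit),
                                  outcome_names = c("RIT", "FT")),
               class = "da_config_error")
})

test_that("healthy flag rate and deviation centering are self-consistent", {
  run <- default_cohort_run()
  healthy <- dplyr::filter(run$deviations, group == "healthy")
  expect_gte(mean(healthy$abnormal, na.rm = TRUE), 0.02)
  expect_lte(mean(healthy$abnormal, na.rm = TRUE), 0.08)
  med <- healthy |>
    dplyr::filter(outcome_name == "RIT") |>
    dplyr::group_by(eccentricity_deg) |>
    dplyr::summarise(m = median(deviation, na.rm = TRUE))
  expect_true(all(abs(med$m) < 1.5))
})

test_that("extrapolating far outside the training ages warns", {
  m <- fit_normative(simulate_healthy_lmm(seed = 19), "RIT")
  expect_warning(predict_interval(m, 99, 2), "extrapolat")
  expect_error(predict_interval(structure(list(), class = "list"), 50, 2),
               class = "da_state_error")
})
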