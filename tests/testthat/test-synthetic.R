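test_that("cohorts are reproducible and spec invariants enforced", {
  spec <- cohort_spec(n_healthy = 6, n_amd = 6)
  c1 <- generate_cohort(spec, seed = 5)
  c2 <- generate_cohort(spec, seed = 5)
  expect_identical(c1, c2)
  c3 <- generate_cohort(spec, seed = 6)
  expect_false(identical(c1$age, c3$age))
  expect_error(cohort_spec(severity_props = c(eAMD = 0.5, iAMD = 0.2,
                                              lateAMD = 0.2)),
               class = "da_invalid_input")
  expect_error(cohort_spec(rit_between_sd = -1), class = "da_invalid_input")
})

test_that("an effectless zero-noise spec yields identical loci", {
  spec <- cohort_spec(n_healthy = 5, n_amd = 5,
                      age_range_healthy = c(50, 50),
                      age_range_amd = c(50, 50), prop_sdd = 0,
                      rit_disease = c(eAMD = 0, iAMD = 0, lateAMD = 0),
                      rit_sdd_effect = 0,
                      ct_disease = c(eAMD = 0, iAMD = 0, lateAMD = 0),
                      ct_sdd_effect = 0,
                      ft_disease = c(eAMD = 0, iAMD = 0, lateAMD = 0),
                      ft_sdd_effect = 0,
                      rit_between_sd = 0, rit_resid_sd = 0,
                      ct_between_sd = 0, ct_resid_sd = 0,
                      ft_between_sd = 0, ft_resid_sd = 0,
                      t0_sd = 0, tau_sd = 0, S2_sd = 0)
  co <- generate_cohort(spec, seed = 2)
  per_ecc <- co |>
    dplyr::group_by(eccentricity_deg) |>
    dplyr::summarise(dplyr::across(c(ct, t0, tau, S2, CRB, tf),
                                   dplyr::n_distinct))
  expect_true(all(per_ecc[, -1] == 1))
})

test_that("true RIT is consistent with the truth parameters", {
  co <- generate_cohort(cohort_spec(n_healthy = 8, n_amd = 8), seed = 9)
  for (i in seq_len(nrow(co))) {
    r <- rod_intercept_time(co[i, c("ct", "t0", "tau", "S2", "CRB", "tf")])
    expect_equal(r$rit, co$true_RIT[i], tolerance = 1e-6)
    expect_identical(r$censored, co$true_rit_censored[i])
  }
  # calibration: uncensored loci hit their latent target
  unc <- dplyr::filter(co, !true_rit_censored)
  expect_lt(max(abs(unc$true_RIT - unc$rit_latent)), 0.01)
})

test_that("the injected SDD effect is recovered from the generator itself", {
  spec <- cohort_spec(n_healthy = 0, n_amd = 500, prop_sdd = 0.5,
                      rit_sdd_effect = 20,
                      ecc_disease_scale = c(`2` = 1, `4` = 1, `6` = 1))
  co <- generate_cohort(spec, seed = 33)
  diff <- mean(co$rit_latent[co$sdd]) - mean(co$rit_latent[!co$sdd])
  expect_lt(abs(diff - 20), 3)
})

test_that("the ideal observer staircase converges within one step", {
  # static threshold -0.5 logUnits (25 dB): flat cone-only truth
  truth <- tidyr::expand_grid(subject_id = "S1", group = "healthy",
                              age = 50, eccentricity_deg = c(2, 4, 6)) |>
    dplyr::mutate(ct = -0.5, t0 = -0.5 + 1e-9, tau = 1, S2 = -0.001,
                  CRB = 59, tf = -0.51)
  pres <- simulate_session(truth, protocol_spec(t_max = 30), slope = 0,
                           lapse = 0, guess = 0, seed = 3)
  for (e in c(2, 4, 6)) {
    cy <- dplyr::filter(pres, eccentricity_deg == e, color == "cyan505")
    expect_gte(nrow(cy), 15)
    last_seen <- dplyr::last(cy$level_db[cy$seen])
    expect_lte(abs(last_seen - 25), 1)
  }
})

test_that("a threshold above the device maximum rails at 0 dB", {
  truth <- tidyr::expand_grid(subject_id = "S1", group = "healthy",
                              age = 50, eccentricity_deg = c(2, 4, 6)) |>
    dplyr::mutate(ct = 3, t0 = 3 + 1e-9, tau = 1, S2 = -0.001, CRB = 59,
                  tf = 2.9)
  pres <- simulate_session(truth, protocol_spec(t_max = 5), slope = 0,
                           lapse = 0, guess = 0, seed = 3)
  expect_false(any(pres$seen))
  expect_true(all(pres$level_db == 0))
})

test_that("intact rod function separates cyan below red late in session", {
  run <- small_cohort_run()
  healthy_id <- run$cohort$subject_id[run$cohort$group == "healthy"][1]
  pres <- dplyr::filter(run$pres, subject_id == healthy_id,
                        eccentricity_deg == 2)
  pts <- extract_thresholds(pres)
  cyan <- dplyr::filter(pts, color == "cyan505")
  red <- dplyr::filter(pts, color == "red627")
  t_end <- max(pts$t_min)
  expect_lt(median(cyan$threshold_log[cyan$t_min > t_end - 10]),
            median(red$threshold_log[red$t_min > t_end - 10]) - 0.3)
  expect_true(detect_rod_function(cyan, red))
})

test_that("sessions respect the protocol invariants", {
  run <- small_cohort_run()
  expect_true(all(run$pres$level_db >= 0 & run$pres$level_db <= 36))
  expect_true(all(run$pres$t_min > 0 & run$pres$t_min <= 60))
  expect_true(all(run$pres$eccentricity_deg %in% c(2, 4, 6)))
  # same seed, same sessions
  again <- simulate_cohort(run$cohort, spec = run$spec, seed = 11)
  expect_identical(run$pres, again)
  expect_error(protocol_spec(step_down_db = -5), class = "da_invalid_input")
  expect_error(protocol_spec(t_max = 90), class = "da_invalid_input")
})
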