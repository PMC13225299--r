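test_that("biphasic curve evaluates the printed formula exactly", {
  p <- da_params(ct = -0.5, t0 = 3.0, tau = 1.0, S2 = -0.25, CRB = 10,
                 tf = -2.0)
  # at t = 0 the exponential branch returns t0 exactly
  expect_identical(da_threshold(p, 0), 3.0)
  # just past the break the rod term contributes log10(1 + 10^(tf - ct))
  cone_at_crb <- -0.5 + 3.5 * exp(-10)
  expect_equal(da_threshold(p, 10 + 1e-12),
               cone_at_crb + log10(1 + 10^(-1.5)), tolerance = 1e-9)
  # t = CRB itself belongs to the cone-only branch
  expect_equal(da_threshold(p, 10), cone_at_crb, tolerance = 1e-12)
  # asymptote: both the exponential and the rod decay vanish
  expect_lt(abs(da_threshold(p, 60) - (-2.0)), 0.01)
})

test_that("curve matches an independent arithmetic oracle to 1e-12", {
  params <- random_valid_params(100, seed = 101)
  tt <- seq(0, 70, length.out = 100)
  for (p in params) {
    expect_equal(da_threshold(p, tt),
                 oracle_threshold(p$ct, p$t0, p$tau, p$S2, p$CRB, p$tf, tt),
                 tolerance = 1e-12)
  }
})

test_that("curve is continuous except for a bounded jump at the break", {
  params <- random_valid_params(30, seed = 7)
  for (p in params) {
    jump <- da_threshold(p, p$CRB + 1e-9) - da_threshold(p, p$CRB)
    expect_gte(jump, 0)
    expect_lte(jump, log10(1 + 10^(p$tf - p$ct)) + 1e-6)
    if (p$tf - p$ct <= -1.5) expect_lt(jump, 0.014)
    # limit behaviour far beyond the break; the horizon must also let the
    # rod decay term fall two decades below the plateau term
    t_far <- max(10 * max(p$tau, p$CRB),
                 p$CRB + (p$ct - p$tf + 2) / abs(p$S2))
    expect_lt(abs(da_threshold(p, t_far) - p$tf), 0.02)
  }
})

test_that("invalid parameters and times are rejected", {
  expect_error(da_params(ct = 0, t0 = 1, tau = -1, S2 = -0.2, CRB = 5,
                         tf = -1), class = "da_invalid_input")
  expect_error(da_params(ct = 0, t0 = -1, tau = 1, S2 = -0.2, CRB = 5,
                         tf = -1), class = "da_invalid_input")
  expect_error(da_params(ct = 0, t0 = 1, tau = 1, S2 = -0.2, CRB = 5,
                         tf = 0.5), class = "da_invalid_input")
  expect_error(da_params(ct = 0, t0 = 1, tau = 1, S2 = 0.2, CRB = 5,
                         tf = -1), class = "da_invalid_input")
  p <- reference_params()
  expect_error(da_threshold(p, -1), class = "da_invalid_input")
  expect_error(da_threshold(p, NA_real_), class = "da_invalid_input")
})

test_that("rod intercept time censors when the plateau stays above criterion", {
  p <- da_params(ct = -0.5, t0 = 2.5, tau = 1, S2 = -0.25, CRB = 10,
                 tf = -1.0)
  r <- rod_intercept_time(p)
  expect_equal(r$rit, 60)
  expect_true(r$censored)
})

test_that("flat-cone crossing lands near the linear approximation", {
  p <- da_params(ct = -0.4, t0 = -0.4, tau = 1.0, S2 = -0.25, CRB = 10,
                 tf = -3.0)
  r <- rod_intercept_time(p)
  expect_false(r$censored)
  # approximately CRB + (criterion - ct)/S2 = 14 min
  expect_lt(abs(r$rit - 14.044), 0.05)
  expect_lt(abs(r$rit - oracle_rit(p)$rit), 0.01)
})

test_that("bisection RIT agrees with the dense-grid oracle", {
  params <- random_valid_params(40, seed = 21)
  for (p in params) {
    got <- rod_intercept_time(p)
    want <- oracle_rit(p)
    expect_identical(got$censored, want$censored)
    if (!got$censored) expect_lt(abs(got$rit - want$rit), 0.01)
  }
})

test_that("RIT is monotone in break time and rod slope", {
  base <- list(ct = -0.5, t0 = 2.5, tau = 1.2, tf = -2.5)
  withr::with_seed(31, {
    for (i in 1:20) {
      s2 <- runif(1, -0.5, -0.1)
      crbs <- sort(runif(2, 2, 35))
      r1 <- rod_intercept_time(da_params(base$ct, base$t0, base$tau, s2,
                                         crbs[1], base$tf))
      r2 <- rod_intercept_time(da_params(base$ct, base$t0, base$tau, s2,
                                         crbs[2], base$tf))
      expect_gte(r2$rit, r1$rit - 1e-6) # nondecreasing in CRB
      crb <- runif(1, 2, 30)
      s2s <- sort(runif(2, -0.6, -0.05)) # s2s[1] steeper
      r3 <- rod_intercept_time(da_params(base$ct, base$t0, base$tau, s2s[1],
                                         crb, base$tf))
      r4 <- rod_intercept_time(da_params(base$ct, base$t0, base$tau, s2s[2],
                                         crb, base$tf))
      expect_lte(r3$rit, r4$rit + 1e-6) # nonincreasing in |S2|
    }
  })
})

test_that("censoring flag matches the dense-grid minimum", {
  params <- random_valid_params(30, seed = 41)
  for (p in params) {
    grid <- seq(p$CRB + 0.001, 60, by = 0.01)
    reaches <- min(da_threshold(p, grid)) <= -1.4
    expect_identical(rod_intercept_time(p)$censored, !reaches)
  }
})

test_that("criterion at or above the cone plateau is a domain error", {
  p <- reference_params()
  expect_error(rod_intercept_time(p, criterion = -0.5),
               class = "da_domain_error")
  expect_error(rod_intercept_time(p, criterion = 0),
               class = "da_domain_error")
})

test_that("parameters serialize to JSON and back with exact field names", {
  p <- reference_params()
  path <- withr::local_tempfile(fileext = ".json")
  params_to_json(p, path)
  parsed <- jsonlite::read_json(path)
  expect_named(parsed, c("ct", "t0", "tau", "S2", "CRB", "tf"))
  expect_equal(params_from_json(path), p)
})
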