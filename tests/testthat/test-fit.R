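test_that("noiseless points recover all six parameters within 1 percent", {
  p <- reference_params()
  tt <- seq(0.5, 45, length.out = 40)
  pts <- tibble::tibble(t_min = tt, threshold_log = da_threshold(p, tt))
  fit <- fit_da_curve(pts, seed = 3)
  rel <- abs(unlist(fit$params) - unlist(p)) / abs(unlist(p))
  expect_true(all(rel < 0.01))
  expect_lt(fit$resid_sd, 1e-4)
})

test_that("noisy fits recover thresholds and RIT within stated tolerances", {
  # quick version (30 replicates); the acceptance suite runs 100
  p <- reference_params()
  true_rit <- rod_intercept_time(p)$rit
  tt <- seq(0.75, 45, length.out = 30)
  clean <- da_threshold(p, tt)
  errs <- withr::with_seed(17, {
    purrr::map(1:30, function(i) {
      pts <- tibble::tibble(t_min = tt,
                            threshold_log = clean + rnorm(30, 0, 0.1))
      f <- fit_da_curve(pts, seed = i)
      r <- rod_intercept_time(f$params)
      c(ct = abs(f$params$ct - p$ct), tf = abs(f$params$tf - p$tf),
        rit = abs(r$rit - true_rit))
    })
  })
  errs <- do.call(rbind, errs)
  expect_lte(median(errs[, "ct"]), 0.15)
  expect_lte(median(errs[, "tf"]), 0.15)
  expect_lte(median(errs[, "rit"]), 2)
})

test_that("a flat series degenerates to tf near ct", {
  pts <- withr::with_seed(5, tibble::tibble(
    t_min = seq(1, 40, length.out = 25),
    threshold_log = -0.5 + rnorm(25, 0, 0.02)))
  fit <- fit_da_curve(pts, seed = 2)
  expect_lt(abs(fit$params$ct - (-0.5)), 0.15)
  # the fitted curve stays flat over the sampled range (no spurious rod
  # branch inside the data); the rod-function flag resolves such loci
  pred <- da_threshold(fit$params, seq(1, 40, by = 0.5))
  expect_lt(max(abs(pred - (-0.5))), 0.15)
  out <- derive_outcome(fit, rod_function = FALSE)
  expect_equal(out$FT, out$CT)
  expect_equal(out$RIT, 60)
  expect_true(out$rit_censored)
})

test_that("fit is invariant to point order and duplicated rows", {
  p <- reference_params()
  tt <- seq(0.5, 42, length.out = 25)
  pts <- withr::with_seed(9, tibble::tibble(
    t_min = tt, threshold_log = da_threshold(p, tt) + rnorm(25, 0, 0.05)))
  f1 <- fit_da_curve(pts, seed = 4)
  f2 <- fit_da_curve(pts[sample(25), ], seed = 4)
  f3 <- fit_da_curve(dplyr::bind_rows(pts, pts[10, ]), seed = 4)
  expect_equal(unlist(f1$params), unlist(f2$params), tolerance = 1e-8)
  expect_equal(unlist(f1$params), unlist(f3$params), tolerance = 1e-8)
})

test_that("too few or too narrow data raise insufficient-data errors", {
  pts <- tibble::tibble(t_min = seq(1, 30, length.out = 5),
                        threshold_log = -0.5)
  expect_error(fit_da_curve(pts), class = "da_insufficient_data")
  pts2 <- tibble::tibble(t_min = seq(1, 10, length.out = 12),
                         threshold_log = -0.5)
  expect_error(fit_da_curve(pts2), class = "da_insufficient_data")
})

test_that("mcmc and penalized modes agree within combined uncertainty", {
  p <- reference_params()
  tt <- seq(0.75, 45, length.out = 35)
  pts <- withr::with_seed(12, tibble::tibble(
    t_min = tt, threshold_log = da_threshold(p, tt) + rnorm(35, 0, 0.08)))
  f_map <- fit_da_curve(pts, mode = "map_penalized", seed = 6)
  f_mc <- fit_da_curve(pts, mode = "mcmc", seed = 6,
                       n_iter = 3000, n_burn = 1500)
  for (nm in names(f_map$params)) {
    tol <- 2 * (f_map$se[[nm]] + f_mc$se[[nm]]) + 0.05 * abs(unlist(p)[[nm]])
    expect_lt(abs(f_map$params[[nm]] - f_mc$params[[nm]]), max(tol, 0.05))
  }
})

test_that("derived outcomes follow the censoring semantics", {
  p <- da_params(ct = -0.5, t0 = 2.5, tau = 1.2, S2 = -0.24, CRB = 12,
                 tf = -2.0)
  out <- derive_outcome(p, rod_function = TRUE)
  expect_false(out$rit_censored)
  expect_equal(out$FT, -2.0)
  # rod plateau above criterion: censored despite rod function
  p2 <- da_params(ct = -0.5, t0 = 2.5, tau = 1.2, S2 = -0.24, CRB = 12,
                  tf = -1.3)
  out2 <- derive_outcome(p2, rod_function = TRUE)
  expect_true(out2$rit_censored)
  expect_equal(out2$RIT, 60)
  expect_equal(out2$FT, -1.3)
  # no rod function: FT is cone-mediated
  out3 <- derive_outcome(p, rod_function = FALSE)
  expect_equal(out3$FT, out3$CT)
  expect_true(out3$rit_censored)
})

test_that("tidy and glance summarize fits", {
  p <- reference_params()
  tt <- seq(0.5, 45, length.out = 30)
  fit <- fit_da_curve(tibble::tibble(t_min = tt,
                                     threshold_log = da_threshold(p, tt)),
                      seed = 1)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error"))
  expect_equal(td$term, c("ct", "t0", "tau", "S2", "CRB", "tf"))
  gl <- glance(fit)
  expect_equal(gl$nobs, 30)
  expect_equal(gl$mode, "map_penalized")
})
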