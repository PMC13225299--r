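# Shared fixtures. The full-cohort pipeline run is expensive, so it is
# computed once per session and reused by the round-trip and end-to-end
# tests.

.da_cache <- new.env(parent = emptyenv())

reference_params <- function() {
  da_params(ct = -0.6, t0 = 2.8, tau = 1.3, S2 = -0.24, CRB = 12, tf = -2.1)
}

# independently written scalar evaluation of the biphasic model (oracle)
oracle_threshold <- function(ct, t0, tau, S2, CRB, tf, t) {
  out <- numeric(length(t))
  for (i in seq_along(t)) {
    v <- ct + (t0 - ct) * exp(-t[i] / tau)
    if (t[i] > CRB) {
      v <- v + log10(10^(S2 * (t[i] - CRB)) + 10^(tf - ct))
    }
    out[i] <- v
  }
  out
}

# dense-grid scan oracle for the rod intercept time
oracle_rit <- function(p, criterion = -1.4, t_max = 60, step = 0.001) {
  grid <- seq(p$CRB + step, t_max, by = step)
  hit <- which(da_threshold(p, grid) <= criterion)
  if (!length(hit)) list(rit = t_max, censored = TRUE)
  else list(rit = grid[hit[1]], censored = FALSE)
}

random_valid_params <- function(n, seed = 1) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      ct <- runif(1, -1.0, 0.5)
      da_params(ct = ct,
                t0 = ct + runif(1, 1, 3.5),
                tau = runif(1, 0.5, 3),
                S2 = runif(1, -0.6, -0.05),
                CRB = runif(1, 2, 40),
                tf = ct - runif(1, 0.3, 2.5))
    })
  })
}

# Full default-cohort pipeline (cohort -> sessions -> fits -> normative ->
# deviations), cached across tests.
default_cohort_run <- function() {
  if (!is.null(.da_cache$run)) return(.da_cache$run)
  spec <- cohort_spec()
  cohort <- generate_cohort(spec, seed = 42)
  pres <- simulate_cohort(cohort, spec = spec, seed = 42)
  thresholds <- extract_thresholds(pres)
  outcomes <- suppressWarnings(fit_da_loci(thresholds, seed = 42))
  models <- list(RIT = fit_normative(outcomes, "RIT"),
                 CT = fit_normative(outcomes, "CT"),
                 FT = fit_normative(outcomes, "FT"))
  deviations <- compute_deviations(outcomes, models)
  .da_cache$run <- list(spec = spec, cohort = cohort, pres = pres,
                        thresholds = thresholds, outcomes = outcomes,
                        models = models, deviations = deviations)
  .da_cache$run
}

# small cohort + sessions for cheaper tests
small_cohort_run <- function() {
  if (!is.null(.da_cache$small)) return(.da_cache$small)
  spec <- cohort_spec(n_healthy = 12, n_amd = 12)
  cohort <- generate_cohort(spec, seed = 11)
  pres <- simulate_cohort(cohort, spec = spec, seed = 11)
  .da_cache$small <- list(spec = spec, cohort = cohort, pres = pres)
  .da_cache$small
}
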