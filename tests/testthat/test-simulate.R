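# Synthetic cohort generator: marginals, dependence, proportional-hazards
# fidelity, censoring structure, determinism.

test_that("biomarker draws have the requested rank dependence", {
  spec <- data.frame(name = c("a", "b"), log_mean = 0, log_sd = 1)
  id2 <- diag(2); dimnames(id2) <- list(spec$name, spec$name)

  x <- simulate_biomarkers(50000, spec, id2, seed = 1)
  expect_lt(abs(cor(x[, 1], x[, 2], method = "spearman")), 0.02)

  rho <- matrix(c(1, 0.9, 0.9, 1), 2, dimnames = dimnames(id2))
  x <- simulate_biomarkers(50000, spec, rho, seed = 2)
  # independent Monte-Carlo oracle of the same generative model
  set.seed(99)
  z <- matrix(rnorm(2 * 50000), ncol = 2) %*% chol(rho)
  r_oracle <- cor(exp(z[, 1]), exp(z[, 2]), method = "spearman")
  expect_lt(abs(cor(x[, 1], x[, 2], method = "spearman") - r_oracle), 0.02)
})

test_that("log-normal marginals have the requested median", {
  spec <- data.frame(name = "a", log_mean = 0, log_sd = 1)
  x <- simulate_biomarkers(1e5, spec, matrix(1, 1, 1, dimnames = list("a", "a")),
                           seed = 3)
  expect_lt(abs(median(x) - 1), 0.02)
})

test_that("invalid correlation matrices are rejected with the eigenvalue", {
  spec <- data.frame(name = c("a", "b"), log_mean = 0, log_sd = 1)
  bad <- matrix(c(1, 1.2, 1.2, 1), 2, dimnames = list(spec$name, spec$name))
  expect_error(simulate_biomarkers(10, spec, bad), "eigenvalue")
  asym <- matrix(c(1, 0.2, 0.5, 1), 2, dimnames = list(spec$name, spec$name))
  expect_error(simulate_biomarkers(10, spec, asym), "symmetric")
})

test_that("event-time generator matches Weibull theory", {
  t1 <- simulate_event_times(rep(0, 1e5), shape = 1, scale = 3, seed = 4)
  se <- 3 / sqrt(1e5)   # exponential(mean 3)
  expect_lt(abs(mean(t1) - 3), 2 * se)

  t2 <- simulate_event_times(rep(0, 1e5), shape = 2, scale = 10, seed = 5)
  expect_lt(abs(mean(t2 <= 10) - (1 - exp(-1))), 0.01)

  expect_error(simulate_event_times(c(0, Inf), 1, 1), "finite")
})

test_that("event-time generator obeys proportional hazards (Cox oracle)", {
  skip_if_not_installed("survival")
  set.seed(6)
  n <- 50000
  g <- rep(c(0, 1), each = n / 2)
  tt <- simulate_event_times(g * log(2), shape = 1.5, scale = 12)
  fit <- survival::coxph(survival::Surv(tt, rep(1, n)) ~ g, ties = "breslow")
  expect_lt(abs(unname(coef(fit)) - log(2)), 0.03)
})

test_that("cohort simulation is bitwise deterministic under a fixed seed", {
  cfg <- sim_config(n_subjects = 500, seed = 42)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
})

test_that("observed follow-up respects the administrative horizon", {
  coh <- simulate_cohort(sim_config(n_subjects = 4000, seed = 8))
  expect_lte(max(coh$time_diabetes, coh$time_coronary), 18.2)
  expect_true(all(coh$time_diabetes > 0))
})

test_that("latent 10-year cumulative incidence is calibrated to target", {
  coh <- simulate_cohort(sim_config(n_subjects = 20000, seed = 9))
  tr <- attr(coh, "truth")$endpoints
  for (ep in c("diabetes", "coronary")) {
    target <- if (ep == "diabetes") 0.10 else 0.07
    p10 <- mean(1 - exp(-(10 / tr[[ep]]$scale)^tr[[ep]]$shape * exp(tr[[ep]]$lp)))
    expect_lt(abs(p10 - target), 0.02)
  }
})

test_that("single-covariate log-HR is recovered by an oracle Cox fit", {
  skip_if_not_installed("survival")
  coh <- simulate_cohort(single_marker_config(50000, loghr = log(1.5), seed = 10))
  z <- scale(coh$bm1)
  fit <- survival::coxph(
    survival::Surv(coh$time_diabetes, coh$status_diabetes) ~ z,
    ties = "breslow")
  expect_lt(abs(unname(coef(fit)) - log(1.5)), 0.05)
})

test_that("Spearman correlations are invariant to monotone biomarker maps", {
  coh <- simulate_cohort(sim_config(n_subjects = 400, seed = 11))
  bm <- attr(coh, "biomarkers")[1:4]
  m1 <- spearman_matrix(coh, bm)
  coh2 <- coh
  coh2[[bm[1]]] <- log(coh2[[bm[1]]])       # strictly monotone transform
  coh2[[bm[2]]] <- coh2[[bm[2]]]^3
  m2 <- spearman_matrix(coh2, bm)
  expect_equal(m1, m2, tolerance = 1e-12)
})

test_that("null-effect cohorts give calibrated Cox coefficients", {
  # all log-HRs zero: the fitted coefficient should lie within 3 SE of 0
  # in at least 94% of replicates
  hits <- 0L
  n_rep <- 200
  for (r in seq_len(n_rep)) {
    cfg <- single_marker_config(600, loghr = 0, seed = 1000 + r)
    coh <- simulate_cohort(cfg)
    coh$time <- coh$time_diabetes; coh$status <- coh$status_diabetes
    fit <- cch_cox(coh, model_spec("m", "bm1", z_terms = "bm1"))
    se <- sqrt(diag(fit$var))
    hits <- hits + as.integer(abs(coef(fit)) < 3 * se)
  }
  expect_gte(hits / n_rep, 0.94)
})
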