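# Weighted Cox fitter: oracle equivalence, toy likelihood maximization,
# weighting schemes, baseline hazard, risk prediction, pseudo-AIC.

test_that("z-transform closed forms", {
  expect_equal(z_transform(5, 5, 2), 0)
  expect_equal(z_transform(7, 5, 2), 1)
  # toy closed form: with the n-1 convention the SD of (5, 10, 15) is 5
  x <- c(5, 10, 15)
  expect_equal(z_transform(x, mean(x), sd(x)), c(-1, 0, 1))
  expect_error(z_transform(x, 0, 0), "positive")
})

test_that("census fits match the reference Cox implementation", {
  skip_if_not_installed("survival")
  set.seed(20)
  for (i in 1:10) {
    n <- sample(50:200, 1)
    d <- data.frame(
      time = round(rexp(n), 2) + 0.01,     # induces ties
      status = rbinom(n, 1, 0.6),
      x1 = rnorm(n), x2 = rbinom(n, 1, 0.4),
      g = factor(sample(c("a", "b", "c"), n, replace = TRUE),
                 levels = c("a", "b", "c")))
    if (sum(d$status) < 2) next
    fit <- cch_cox(d, c("x1", "x2", "g"))
    ref <- survival::coxph(survival::Surv(time, status) ~ x1 + x2 + g,
                           data = d, ties = "breslow", robust = TRUE)
    expect_lt(max(abs(unname(coef(fit)) - unname(coef(ref)))), 1e-6)
    expect_lt(max(abs(sqrt(diag(vcov(fit))) - sqrt(diag(ref$var)))), 1e-6)
  }
})

test_that("4-subject toy matches the brute-force likelihood maximizer", {
  d <- data.frame(time = c(1, 2, 3, 4), status = c(1, 1, 0, 1),
                  x = c(1, 0, 1, 0))
  fit <- cch_cox(d, "x")
  b_grid <- grid_search_cox(d$time, d$status, d$x)
  expect_lt(abs(unname(coef(fit)) - b_grid), 1e-4 / 2 + 1e-6)
  # the analytic optimum of the 3-term partial likelihood
  expect_equal(unname(coef(fit)), log(2) / 2, tolerance = 1e-6)
})

test_that("prentice and barlow weighted fits match a counting-process oracle", {
  skip_if_not_installed("survival")
  coh <- simulate_cohort(single_marker_config(4000, loghr = log(1.6), seed = 21))
  for (scheme in c("prentice", "barlow")) {
    smp <- draw_subcohort(coh, sampling_design(0.2, scheme = scheme, seed = 22),
                          "diabetes")
    fit <- cch_cox(smp, model_spec("m", "bm1", z_terms = "bm1",
                                   endpoint = "diabetes"))
    # oracle: survival::coxph on the same expanded risk-set representation
    rows <- cchpredict:::expand_risk_rows(smp, scheme)
    z <- (smp$bm1 - fit$scaling$bm1$center) / fit$scaling$bm1$scale
    od <- data.frame(start = rows$start, stop = rows$stop,
                     status = rows$status, w = rows$w, z = z[rows$id])
    ref <- survival::coxph(survival::Surv(start, stop, status) ~ z,
                           data = od, weights = w, ties = "breslow",
                           timefix = FALSE)
    expect_lt(abs(unname(coef(fit)) - unname(coef(ref))), 1e-6)
  }
})

test_that("scale equivariance of coefficients and z-invariance", {
  set.seed(23)
  n <- 300
  d <- data.frame(time = rexp(n), status = rbinom(n, 1, 0.5), x = rlnorm(n))
  f1 <- cch_cox(d, "x")
  d2 <- d; d2$x <- d2$x * 10
  f2 <- cch_cox(d2, "x")
  expect_equal(unname(coef(f2)), unname(coef(f1)) / 10, tolerance = 1e-8)
  fz1 <- cch_cox(d, "x", z_terms = "x")
  fz2 <- cch_cox(d2, "x", z_terms = "x")
  expect_equal(unname(coef(fz1)), unname(coef(fz2)), tolerance = 1e-8)
})

test_that("degenerate inputs raise informative errors", {
  d <- data.frame(time = 1:10, status = rep(c(1, 0), 5), x = 1)
  expect_error(cch_cox(d, "x"), "constant covariate")
  # complete separation: all x = 1 failures precede every x = 0 failure
  d2 <- data.frame(time = c(1:5, 101:105), status = 1,
                   x = rep(c(1, 0), each = 5))
  expect_error(cch_cox(d2, "x"), "monotone likelihood|separation")
  d3 <- data.frame(time = 1:4, status = c(1, 0, 0, 0), x = rnorm(4))
  expect_error(cch_cox(d3, "x"), "at least 2 events")
})

test_that("hazard-ratio table closed forms", {
  d <- data.frame(time = c(1, 2, 3, 4), status = c(1, 1, 0, 1),
                  x = c(1, 0, 1, 0))
  fit <- cch_cox(d, "x")
  hr <- hazard_ratios(fit)
  se <- unname(sqrt(diag(fit$var)))
  cf <- unname(coef(fit))
  expect_equal(hr$hr, exp(cf))
  expect_equal(hr$ci_low, exp(cf - qnorm(0.975) * se))
  expect_equal(hr$ci_high, exp(cf + qnorm(0.975) * se))
  expect_equal(hr$p, 2 * pnorm(-abs(cf / se)))
})

test_that("null-covariate robust CIs have nominal coverage", {
  set.seed(24)
  n_rep <- 200
  covered <- 0L
  for (r in seq_len(n_rep)) {
    n <- 150
    d <- data.frame(time = rexp(n), status = rbinom(n, 1, 0.6),
                    x = rnorm(n), noise = rnorm(n))
    fit <- cch_cox(d, c("x", "noise"))
    hr <- hazard_ratios(fit)
    covered <- covered + as.integer(hr$ci_low[2] <= 1 && hr$ci_high[2] >= 1)
  }
  expect_gte(covered / n_rep, 0.93)
})

test_that("Breslow baseline: hand-computable jump and Nelson-Aalen identity", {
  # single event at t = 1 among 4 at risk; the event subject sits at the
  # covariate mean and the others are symmetric, so beta-hat = 0 exactly
  # and the baseline is the Nelson-Aalen estimator: jump 1/4
  d2 <- data.frame(time = c(1, 2, 3, 3), status = c(1, 1, 0, 0),
                   x = c(0, 0, 0.5, -0.5))
  f2 <- cch_cox(d2, "x")
  H0 <- breslow_baseline(f2)
  expect_equal(unname(coef(f2)), 0, tolerance = 1e-8)
  expect_equal(H0(0.5), 0)
  expect_equal(H0(1), 0.25, tolerance = 1e-10)
  expect_equal(H0(2), 0.25 + 1 / 3, tolerance = 1e-10)
})

test_that("baseline cumulative hazard recovers the Weibull truth", {
  cfg <- single_marker_config(30000, loghr = log(1.5), seed = 26)
  coh <- simulate_cohort(cfg)
  tr <- attr(coh, "truth")$endpoints$diabetes
  coh$time <- coh$time_diabetes; coh$status <- coh$status_diabetes
  fit <- cch_cox(coh, model_spec("m", "bm1", z_terms = "bm1"))
  # baseline profile = mean-covariate subject; the generator's H(t) for a
  # subject at z = 0 on the *sample* scale is close to (t/scale)^shape
  # times the mean frailty-free hazard at z = 0
  H10_true <- (10 / tr$scale)^tr$shape
  H10_est <- breslow_baseline(fit)(10)
  expect_lt(abs(H10_est - H10_true) / H10_true, 0.05)
})

test_that("predicted risks follow the closed form and calibrate", {
  d <- data.frame(time = c(1, 2, 3, 4, 5, 6), status = c(1, 1, 0, 1, 0, 0),
                  x = c(0.3, -0.2, 0.1, 0.5, -0.4, 0))
  fit <- cch_cox(d, "x")
  H0 <- breslow_baseline(fit)(4)
  xc <- 0.9 - fit$scaling$x$center
  expect_equal(predict(fit, data.frame(x = 0.9), tau = 4),
               1 - exp(-H0 * exp(xc * unname(coef(fit)))), tolerance = 1e-12)
  expect_error(predict(fit, data.frame(y = 1), tau = 4), "missing")

  # closed-form spot value: H0(10) = 0.1, x'beta = log 2
  expect_equal(1 - exp(-0.1 * 2), 0.18126925, tolerance = 1e-7)

  # calibration-in-the-large on a simulated cohort
  coh <- simulate_cohort(single_marker_config(15000, loghr = log(1.5), seed = 27))
  coh$time <- coh$time_diabetes; coh$status <- coh$status_diabetes
  cfit <- cch_cox(coh, model_spec("m", "bm1", z_terms = "bm1"))
  mean_risk <- mean(predict(cfit, coh, tau = 10))
  km10 <- 1 - km_surv(weighted_km(coh$time, coh$status), 10)
  expect_lt(abs(mean_risk - km10), 0.015)
})

test_that("pseudo-AIC bookkeeping and delta-AIC behaviour", {
  set.seed(28)
  n <- 400
  d <- data.frame(time = rexp(n), status = rbinom(n, 1, 0.5),
                  x = rnorm(n), z = rnorm(n))
  f1 <- cch_cox(d, "x")
  f2 <- cch_cox(d, c("x", "z"))
  expect_equal(model_aic(f1), -2 * f1$loglik + 2 * f1$k)
  expect_equal(f1$k, 1); expect_equal(f2$k, 2)
  expect_equal(as.numeric(delta_aic(f1, f1)), 0)
  expect_error(delta_aic(f1, cch_cox(d[1:200, ], "x")), "same sample")

  # pure-noise covariate: delta in (-2, Inf), median near -2 + median chi2_1
  deltas <- vapply(1:200, function(r) {
    set.seed(2800 + r)
    dd <- data.frame(time = rexp(150), status = rbinom(150, 1, 0.6),
                     x = rnorm(150), noise = rnorm(150))
    as.numeric(delta_aic(cch_cox(dd, c("x", "noise")), cch_cox(dd, "x")))
  }, numeric(1))
  expect_true(all(deltas > -2 - 1e-8))
  expect_lt(abs(median(deltas) - (-2 + qchisq(0.5, 1))), 0.6)

  # one strong covariate with many events: essential difference
  coh <- simulate_cohort(single_marker_config(6000, loghr = 0.5, seed = 29))
  coh$time <- coh$time_diabetes; coh$status <- coh$status_diabetes
  fa <- cch_cox(coh, model_spec("a", "age"))
  fb <- cch_cox(coh, model_spec("b", c("age", "bm1"), z_terms = "bm1"))
  dl <- delta_aic(fb, fa)
  expect_gt(as.numeric(dl), 10)
  expect_true(attr(dl, "essential"))
})
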