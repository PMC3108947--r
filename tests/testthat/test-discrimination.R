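# Weighted KM, IPCW, time-horizon AUC, delta-AUC, IDI, NRI.

test_that("weighted KM closed forms", {
  # no censoring, unit weights: S(t) = 1 - ecdf
  tt <- c(2, 4, 6, 8); st <- rep(1, 4)
  km <- weighted_km(tt, st)
  expect_equal(km_surv(km, 5), 0.5)
  expect_equal(km_surv(km, 8), 0)

  # hand computation with censoring
  km2 <- weighted_km(c(1, 2, 3, 4), c(1, 0, 1, 0))
  expect_equal(km_surv(km2, 3), (3 / 4) * (1 / 2))
  expect_error(km_surv(km2, 5), "at risk")
})

test_that("case-cohort weighted KM tracks the full-cohort KM", {
  diffs <- vapply(1:200, function(r) {
    coh <- simulate_cohort(single_marker_config(4000, seed = 4000 + r))
    full <- 1 - km_surv(weighted_km(coh$time_diabetes, coh$status_diabetes), 10)
    smp <- draw_subcohort(coh, sampling_design(0.2, seed = r), "diabetes")
    cc <- 1 - km_surv(weighted_km(smp$time, smp$status, smp$weight), 10)
    cc - full
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 0.015)
})

test_that("IPCW weights: closed forms without informative censoring", {
  # no censoring at all
  u <- ipcw_weights(c(1, 5, 12, 15), c(1, 1, 1, 1), tau = 10)
  expect_equal(u, c(1, 1, 1, 1))
  # administrative censoring after the horizon only
  u2 <- ipcw_weights(c(3, 20, 20, 7), c(1, 0, 0, 1), tau = 10)
  expect_equal(u2, c(1, 1, 1, 1))
  # censored before tau: status unobservable, weight 0
  u3 <- ipcw_weights(c(3, 6, 20), c(1, 0, 0), tau = 10)
  expect_equal(u3[2], 0)
})

test_that("IPCW recovers the true incidence under heavy censoring", {
  set.seed(31)
  n <- 50000
  lambda <- 0.08
  tev <- rexp(n, lambda)
  cen <- runif(n, 0, 20)
  time <- pmin(tev, cen); status <- as.integer(tev <= cen)
  u <- ipcw_weights(time, status, tau = 10)
  est <- sum(u[status == 1 & time <= 10]) / sum(u)
  expect_lt(abs(est - (1 - exp(-10 * lambda))), 0.01)
})

test_that("AUC degenerate cases and brute-force equivalence", {
  tt <- c(1, 2, 11, 12, 13); st <- c(1, 1, 0, 0, 0)
  expect_equal(auc_tau(rep(0.4, 5), tt, st, tau = 10), 0.5)       # pure ties
  expect_equal(auc_tau(c(0.9, 0.8, 0.1, 0.2, 0.3), tt, st, tau = 10), 1)

  set.seed(32)
  for (r in 1:20) {
    n <- 30
    tev <- rexp(n, 0.1); cen <- runif(n, 0, 25)
    time <- pmin(tev, cen); status <- as.integer(tev <= cen)
    if (!any(status == 1 & time <= 10) || !any(time > 10)) next
    p <- runif(n); w <- runif(n, 0.5, 3)
    ip <- ipcw_weights(time, status, 10, weights = w)
    expect_equal(auc_tau(p, time, status, w, 10, ip),
                 brute_force_auc(p, time, status, w, 10, ip),
                 tolerance = 1e-12)
  }
})

test_that("AUC equals the Mann-Whitney statistic without censoring", {
  set.seed(33)
  n <- 80
  time <- runif(n, 1, 20); status <- rep(1, n)
  p <- runif(n)
  case <- time <= 10
  mw <- mean(outer(p[case], p[!case], function(a, b) (a > b) + 0.5 * (a == b)))
  expect_equal(auc_tau(p, time, status, tau = 10), mw, tolerance = 1e-12)
})

test_that("delta-AUC identities and rank invariance", {
  set.seed(34)
  n <- 50
  time <- runif(n, 1, 20); status <- rbinom(n, 1, 0.8)
  p <- runif(n)
  expect_equal(delta_auc(p, p, time, status, tau = 10), 0)
  expect_equal(delta_auc(plogis(5 * p - 2), p, time, status, tau = 10), 0)
  expect_error(delta_auc(p[-1], p, time, status, tau = 10), "align")
})

test_that("IDI identities and hand computation", {
  time <- c(1, 2, 11, 12); status <- c(1, 1, 0, 0)
  p_old <- c(0.2, 0.4, 0.1, 0.3)
  p_new <- c(0.3, 0.5, 0.1, 0.1)
  v <- idi(p_new, p_old, time, status, tau = 10)
  expect_equal(as.numeric(v), (0.4 - 0.1) - (0.3 - 0.2))
  expect_equal(as.numeric(idi(p_old, p_old, time, status, tau = 10)), 0)
  # slopes attribute reproduces the statistic
  s <- attr(v, "slopes")
  expect_equal(as.numeric(v), unname(s["new"] - s["old"]), tolerance = 1e-12)
})

test_that("NRI toy definitions and table bookkeeping", {
  cats <- nri_categories(c(0.03, 0.08, 0.15))
  # 10 cases, one moves up one category, controls unchanged
  pc_old <- c(rep(0.02, 9), 0.05); pc_new <- c(rep(0.02, 9), 0.10)
  pk <- rep(0.02, 12)
  time <- c(rep(1, 10), rep(12, 12)); status <- c(rep(1, 10), rep(0, 12))
  r <- nri(c(pc_new, pk), c(pc_old, pk), time, status, tau = 10, cats = cats)
  expect_equal(r$nri, 0.1)
  expect_equal(r$nri_case, 0.1); expect_equal(r$nri_control, 0)

  # 20 controls, one moves up, cases unchanged
  pc <- rep(0.5, 4)
  pk_old <- c(rep(0.02, 19), 0.05); pk_new <- c(rep(0.02, 19), 0.10)
  time2 <- c(rep(1, 4), rep(12, 20)); status2 <- c(rep(1, 4), rep(0, 20))
  r2 <- nri(c(pc, pk_new), c(pc, pk_old), time2, status2, tau = 10, cats = cats)
  expect_equal(r2$nri, -0.05)

  # identity: zero NRI, diagonal table, conserved margins
  r3 <- nri(c(pc, pk_old), c(pc, pk_old), time2, status2, tau = 10, cats = cats)
  expect_equal(r3$nri, 0)
  expect_equal(sum(r3$table_case) + sum(r3$table_control), 24)
  expect_true(all(r3$table_case[upper.tri(r3$table_case)] == 0))
  expect_true(all(r3$table_case[lower.tri(r3$table_case)] == 0))

  # category boundary: risk exactly 3% belongs to the lowest category
  expect_equal(cchpredict:::risk_category(c(0.03, 0.0301, 0.08, 0.15, 0.151),
                                          cats), c(1L, 2L, 2L, 3L, 4L))
  expect_error(nri_categories(c(0.08, 0.03)), "increasing")
})

test_that("NRI components stay within their bounds on random inputs", {
  set.seed(35)
  for (r in 1:25) {
    n <- 60
    time <- runif(n, 1, 20); status <- rbinom(n, 1, 0.7)
    if (!any(status == 1 & time <= 10) || !any(time > 10)) next
    res <- nri(runif(n), runif(n), time, status, tau = 10)
    expect_true(abs(res$nri_case) <= 1 && abs(res$nri_control) <= 1)
    expect_true(abs(res$nri) <= 2)
  }
})

test_that("evaluate_models: self-comparison gives all-zero deltas", {
  coh <- simulate_cohort(single_marker_config(3000, seed = 36))
  smp <- draw_subcohort(coh, sampling_design(0.3, seed = 37), "diabetes")
  f <- cch_cox(smp, model_spec("m", c("age", "bm1"), z_terms = "bm1",
                               endpoint = "diabetes"))
  ev <- evaluate_models(smp, list(none = f, same = f), baseline = "none")
  row <- ev$summary[ev$summary$model == "same", ]
  expect_equal(row$delta_auc, 0)
  expect_equal(row$idi, 0)
  expect_equal(row$nri, 0)
  expect_equal(row$delta_aic, 0)
})

test_that("case-cohort discrimination estimates track full-cohort values", {
  # reduced-scale version of the design-consistency property (the full-size
  # run lives in the acceptance suite)
  set.seed(38)
  d_auc <- d_idi <- d_nri <- numeric(30)
  for (r in 1:30) {
    coh <- simulate_cohort(single_marker_config(5000, seed = 5000 + r))
    tr <- attr(coh, "truth")$endpoints$diabetes
    p_new <- 1 - exp(-(10 / tr$scale)^tr$shape * exp(tr$lp))
    p_old <- 1 - exp(-(10 / tr$scale)^tr$shape * exp(0.3 * tr$lp))
    coh$time <- coh$time_diabetes; coh$status <- coh$status_diabetes
    full_auc <- auc_tau(p_new, coh$time, coh$status, tau = 10)
    full_idi <- as.numeric(idi(p_new, p_old, coh$time, coh$status, tau = 10))
    full_nri <- nri(p_new, p_old, coh$time, coh$status, tau = 10)$nri
    smp <- draw_subcohort(coh, sampling_design(0.2, seed = r), "diabetes")
    i <- match(smp$id, coh$id)
    ip <- ipcw_weights(smp$time, smp$status, 10, weights = smp$weight)
    d_auc[r] <- auc_tau(p_new[i], smp$time, smp$status, smp$weight, 10, ip) - full_auc
    d_idi[r] <- as.numeric(idi(p_new[i], p_old[i], smp$time, smp$status,
                               smp$weight, 10, ip)) - full_idi
    d_nri[r] <- nri(p_new[i], p_old[i], smp$time, smp$status, smp$weight,
                    10, ipcw = ip)$nri - full_nri
  }
  expect_lt(abs(mean(d_auc)), 0.01)
  expect_lt(abs(mean(d_idi)), 0.005)
  expect_lt(abs(mean(d_nri)), 0.02)
})
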