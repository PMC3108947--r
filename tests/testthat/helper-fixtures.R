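# Shared fixtures and independent oracles used across the suite.

# A single-biomarker cohort configuration for parameter-recovery work:
# one log-normal marker carrying the whole hazard signal, no frailty, no
# covariate effects, so the marginal model is exactly proportional hazards.
single_marker_config <- function(n, loghr = log(1.5), seed = 1L,
                                 target_cuminc = 0.10, log_sd = 0.5,
                                 shape = 1.6) {
  spec <- data.frame(name = "bm1", log_mean = 0, log_sd = log_sd,
                     stringsAsFactors = FALSE)
  sim_config(
    n_subjects = n,
    biomarker_spec = spec,
    biomarker_corr = matrix(1, 1, 1, dimnames = list("bm1", "bm1")),
    endpoint_spec = list(diabetes = list(shape = shape, scale = NULL,
                                         target_cuminc = target_cuminc,
                                         cuminc_horizon = 10,
                                         loghr = c(bm1 = loghr))),
    frailty_sd = 0,
    adiposity_loadings = c(leptin = 0),
    seed = seed
  )
}

# O(n^2) pairwise definition of the weighted tau-horizon AUC — the brute
# force oracle the rank-based implementation must reproduce.
brute_force_auc <- function(p, time, status, weights, tau, ipcw) {
  u <- weights * ipcw
  case <- which(status == 1 & time <= tau)
  ctrl <- which(time > tau)
  num <- 0; den <- 0
  for (i in case) for (j in ctrl) {
    uij <- u[i] * u[j]
    num <- num + uij * ((p[i] > p[j]) + 0.5 * (p[i] == p[j]))
    den <- den + uij
  }
  num / den
}

# Grid-search maximizer of an (unweighted, Breslow) Cox partial likelihood
# for a single covariate — independent of the Newton solver.
grid_search_cox <- function(time, status, x, grid = seq(-5, 5, by = 1e-4)) {
  ll <- vapply(grid, function(b) {
    eta <- b * x
    sum(vapply(which(status == 1), function(i) {
      eta[i] - log(sum(exp(eta[time >= time[i]])))
    }, numeric(1)))
  }, numeric(1))
  grid[which.max(ll)]
}

# Minimal uncensored toy sample wrapped as a weighted cch_sample (census).
toy_sample <- function(time, status, ..., weight = 1) {
  df <- data.frame(time = time, status = status, ...,
                   stringsAsFactors = FALSE)
  df$stratum <- "all"
  df$in_subcohort <- 1L
  df$is_case <- as.integer(status == 1)
  df$weight <- weight
  class(df) <- c("cch_sample", "data.frame")
  attr(df, "alphas") <- c(all = 1)
  attr(df, "scheme") <- "prentice"
  df
}
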