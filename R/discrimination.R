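# Censoring- and design-adjusted discrimination measures for 10-year risk:
# weighted Kaplan-Meier, IPCW weights, time-horizon AUC, delta-AUC, IDI and
# the category-based NRI with reclassification tables.

#' Weighted Kaplan-Meier estimator
#'
#' Product-limit estimator with weighted deaths and weighted risk sets:
#' `S(t) = prod_{t_i <= t} (1 - sum(w d_i) / sum(w Y_i))`.
#'
#' @param time follow-up times.
#' @param status event indicators (1 = event, 0 = censored).
#' @param weights optional nonnegative weights (default 1).
#' @return object of class `weighted_km` (step function table); evaluate
#'   with [km_surv()].
#' @export
weighted_km <- function(time, status, weights = NULL) {
  n <- length(time)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(status) == n, length(weights) == n, all(weights >= 0))
  et <- sort(unique(time[status == 1]))
  o <- order(time)
  ts <- time[o]; ws <- weights[o]
  cw <- c(0, cumsum(ws))
  y <- sum(ws) - cw[findInterval(et, ts, left.open = TRUE) + 1]  # weighted at risk
  evs <- status == 1
  d <- numeric(length(et))
  agg <- rowsum(weights[evs], match(time[evs], et), reorder = TRUE)
  d[as.integer(rownames(agg))] <- agg[, 1]
  surv <- cumprod(1 - d / y)
  structure(list(time = et, surv = surv, max_time = max(time)),
            class = "weighted_km")
}

#' Evaluate a weighted Kaplan-Meier curve
#'
#' @param km a [weighted_km()] object.
#' @param t evaluation time(s); must not exceed the last observed time.
#' @param left evaluate the left limit `S(t-)` instead of `S(t)`.
#' @return survival probabilities.
#' @export
km_surv <- function(km, t, left = FALSE) {
  if (any(t > km$max_time))
    stop("no subjects at risk at t = ", max(t), " (last observation ",
         format(km$max_time), ")")
  idx <- if (left) findInterval(t, km$time, left.open = TRUE)
         else findInterval(t, km$time)
  c(1, km$surv)[idx + 1]
}

#' Inverse-probability-of-censoring weights at a horizon
#'
#' The censoring distribution `G` is estimated by (weighted) Kaplan-Meier
#' with the roles of event and censoring exchanged. Subjects with an event
#' by `tau` receive `1/G(T-)`; subjects event-free past `tau` receive
#' `1/G(tau)`; subjects censored before `tau` (tau-horizon status
#' unobservable) receive 0.
#'
#' @param time,status follow-up data.
#' @param tau horizon in years.
#' @param weights optional design weights for estimating `G`.
#' @return per-subject censoring weights.
#' @export
ipcw_weights <- function(time, status, tau, weights = NULL) {
  if (tau <= 0) stop("tau must be positive")
  G <- weighted_km(time, 1 - status, weights = weights)
  u <- numeric(length(time))
  ev <- status == 1 & time <= tau
  fr <- time > tau
  if (any(ev)) {
    g <- km_surv(G, time[ev], left = TRUE)
    if (any(g <= 0))
      stop("censoring survival reaches 0 before tau; use an earlier tau")
    u[ev] <- 1 / g
  }
  if (any(fr)) {
    gtau <- km_surv(G, tau)
    if (gtau <= 0)
      stop("censoring survival reaches 0 before tau; use an earlier tau")
    u[fr] <- 1 / gtau
  }
  u
}

# tau-horizon case/control status and combined weights shared by the
# discrimination measures
horizon_weights <- function(time, status, weights, tau, ipcw = NULL) {
  n <- length(time)
  if (is.null(weights)) weights <- rep(1, n)
  if (is.null(ipcw)) ipcw <- ipcw_weights(time, status, tau, weights = weights)
  u <- weights * ipcw
  case <- status == 1 & time <= tau
  ctrl <- time > tau
  if (sum(u[case]) <= 0) stop("no weighted cases at tau")
  if (sum(u[ctrl]) <= 0) stop("no weighted controls at tau")
  list(u = u, case = case, ctrl = ctrl)
}

#' Time-horizon AUC under censoring and design weighting
#'
#' Probability that a subject with an event by `tau` gets a higher
#' predicted risk than an event-free subject, with ties counting 1/2:
#' `AUC = sum_{i case, j control} u_i u_j [1(p_i > p_j) + 0.5 1(p_i = p_j)]
#' / sum u_i u_j`, where `u` combines the design weight with the IPCW
#' weight. Computed by an O(n log n) rank sweep identical to the O(n^2)
#' pairwise definition.
#'
#' @param p predicted risks at `tau`.
#' @param time,status follow-up data.
#' @param weights design weights (default 1).
#' @param tau horizon (default 10 years).
#' @param ipcw optional precomputed censoring weights.
#' @return AUC in `[0, 1]`.
#' @export
auc_tau <- function(p, time, status, weights = NULL, tau = 10, ipcw = NULL) {
  hw <- horizon_weights(time, status, weights, tau, ipcw)
  u <- hw$u
  wc <- ifelse(hw$case, u, 0)
  wk <- ifelse(hw$ctrl, u, 0)
  o <- order(p)
  ps <- p[o]; wc <- wc[o]; wk <- wk[o]
  grp <- cumsum(c(TRUE, diff(ps) != 0))      # tie groups in ascending p
  ctrl_g <- as.vector(rowsum(wk, grp))
  case_g <- as.vector(rowsum(wc, grp))
  ctrl_below <- c(0, cumsum(ctrl_g))[seq_along(ctrl_g)]
  num <- sum(case_g * (ctrl_below + 0.5 * ctrl_g))
  num / (sum(wc) * sum(wk))
}

#' Difference in time-horizon AUC between two models
#'
#' @param p_new,p_old predicted risks from the two models on the same
#'   subjects.
#' @inheritParams auc_tau
#' @return `AUC(new) - AUC(old)`.
#' @export
delta_auc <- function(p_new, p_old, time, status, weights = NULL, tau = 10,
                      ipcw = NULL) {
  if (length(p_new) != length(p_old) || length(p_new) != length(time))
    stop("prediction vectors must align with the sample")
  auc_tau(p_new, time, status, weights, tau, ipcw) -
    auc_tau(p_old, time, status, weights, tau, ipcw)
}

#' Integrated discrimination improvement
#'
#' Difference of the weighted discrimination slopes (mean predicted risk
#' in tau-horizon cases minus controls) between the new and old model —
#' interpretable as the difference in the proportion of variance explained.
#'
#' @inheritParams delta_auc
#' @return IDI, with attribute `slopes` holding the two discrimination
#'   slopes.
#' @export
idi <- function(p_new, p_old, time, status, weights = NULL, tau = 10,
                ipcw = NULL) {
  if (length(p_new) != length(p_old) || length(p_new) != length(time))
    stop("prediction vectors must align with the sample")
  hw <- horizon_weights(time, status, weights, tau, ipcw)
  u <- hw$u
  wmean <- function(x, sel) sum(u[sel] * x[sel]) / sum(u[sel])
  slope_new <- wmean(p_new, hw$case) - wmean(p_new, hw$ctrl)
  slope_old <- wmean(p_old, hw$case) - wmean(p_old, hw$ctrl)
  out <- slope_new - slope_old
  attr(out, "slopes") <- c(new = slope_new, old = slope_old)
  out
}

#' Risk category grid for the NRI
#'
#' Interior cut points; intervals are right-closed so that a risk of
#' exactly 3.0% falls in the lowest category of the default grid
#' 0-3.0%, 3.1-8.0%, 8.1-15.0%, >15%. Alternate grids (0.02, 0.05, 0.10)
#' and (0.05, 0.10, 0.20) are used in sensitivity analyses.
#'
#' @param cuts strictly increasing cut points in (0, 1).
#' @return validated numeric vector of class `nri_categories`.
#' @export
nri_categories <- function(cuts = c(0.03, 0.08, 0.15)) {
  if (any(diff(cuts) <= 0) || any(cuts <= 0) || any(cuts >= 1))
    stop("cut points must be strictly increasing and inside (0, 1)")
  structure(cuts, class = "nri_categories")
}

risk_category <- function(p, cuts) {
  findInterval(p, cuts, left.open = TRUE) + 1L   # right-closed intervals
}

#' Category-based net reclassification index
#'
#' Subjects are cross-classified by old and new risk category;
#' `NRI = [P_u(up|case) - P_u(down|case)] + [P_u(down|control) -
#' P_u(up|control)]` with u-weighted proportions (design x IPCW weights).
#'
#' @inheritParams delta_auc
#' @param cats a [nri_categories()] grid (default cuts 3/8/15%).
#' @return list of class `nri_result`: `nri`, `nri_case`, `nri_control`,
#'   and weighted reclassification tables `table_case`, `table_control`
#'   (old category in rows, new in columns).
#' @export
nri <- function(p_new, p_old, time, status, weights = NULL, tau = 10,
                cats = nri_categories(), ipcw = NULL) {
  if (length(p_new) != length(p_old) || length(p_new) != length(time))
    stop("prediction vectors must align with the sample")
  if (!inherits(cats, "nri_categories")) cats <- nri_categories(cats)
  hw <- horizon_weights(time, status, weights, tau, ipcw)
  u <- hw$u
  k <- length(cats) + 1L
  old_cat <- risk_category(p_old, cats)
  new_cat <- risk_category(p_new, cats)
  cross_tab <- function(sel) {
    tab <- matrix(0, k, k,
                  dimnames = list(old = paste0("cat", 1:k),
                                  new = paste0("cat", 1:k)))
    if (any(sel)) {
      agg <- rowsum(u[sel], interaction(old_cat[sel], new_cat[sel], drop = TRUE))
      ij <- do.call(rbind, strsplit(rownames(agg), ".", fixed = TRUE))
      tab[cbind(as.integer(ij[, 1]), as.integer(ij[, 2]))] <- agg[, 1]
    }
    tab
  }
  tc <- cross_tab(hw$case)
  tk <- cross_tab(hw$ctrl)
  prop <- function(tab, which) {
    tot <- sum(tab)
    if (tot <= 0) return(0)
    sel <- if (which == "up") upper.tri(tab) else lower.tri(tab)
    sum(tab[sel]) / tot
  }
  nri_case <- prop(tc, "up") - prop(tc, "down")
  nri_ctrl <- prop(tk, "down") - prop(tk, "up")
  structure(list(nri = nri_case + nri_ctrl,
                 nri_case = nri_case, nri_control = nri_ctrl,
                 table_case = tc, table_control = tk,
                 cuts = as.numeric(cats)),
            class = "nri_result")
}

#' @export
print.nri_result <- function(x, ...) {
  cat("NRI =", format(x$nri, digits = 4),
      "(cases", format(x$nri_case, digits = 4),
      "+ controls", format(x$nri_control, digits = 4), ")\n")
  cat("cut points:", paste(x$cuts, collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate a set of fitted models on one sample
#'
#' Computes 10-year risk predictions for every fit, then the four accuracy
#' measures of each model against a declared baseline model: AUC(tau),
#' delta-AUC, IDI, NRI (with reclassification tables) and delta-AIC. The
#' same design-weight x IPCW weighting is used throughout. Deterministic
#' given its inputs.
#'
#' @param sample a weighted `cch_sample`.
#' @param fits named list of `cch_cox` fits on this sample.
#' @param baseline name of the reference model (default: first fit).
#' @param tau horizon in years.
#' @param cats NRI category grid.
#' @return object of class `discrimination_result`: `summary` data.frame
#'   (one row per model: auc, delta_auc, idi, nri, delta_aic), the
#'   prediction matrix, NRI details, tau, and the baseline name.
#' @export
evaluate_models <- function(sample, fits, baseline = names(fits)[1], tau = 10,
                            cats = nri_categories()) {
  if (is.null(names(fits)) || any(names(fits) == ""))
    stop("fits must be a named list")
  if (!baseline %in% names(fits)) stop("unknown baseline model: ", baseline)
  w <- sample$weight
  ipcw <- ipcw_weights(sample$time, sample$status, tau, weights = w)
  preds <- vapply(fits, function(f) predict(f, sample, tau = tau),
                  numeric(nrow(sample)))
  p0 <- preds[, baseline]
  rows <- list(); nris <- list()
  for (nm in names(fits)) {
    p1 <- preds[, nm]
    a <- auc_tau(p1, sample$time, sample$status, w, tau, ipcw)
    if (nm == baseline) {
      rows[[nm]] <- data.frame(model = nm, auc = a, delta_auc = NA_real_,
                               idi = NA_real_, nri = NA_real_,
                               delta_aic = NA_real_, stringsAsFactors = FALSE)
    } else {
      nr <- nri(p1, p0, sample$time, sample$status, w, tau, cats, ipcw)
      nris[[nm]] <- nr
      rows[[nm]] <- data.frame(
        model = nm, auc = a,
        delta_auc = a - auc_tau(p0, sample$time, sample$status, w, tau, ipcw),
        idi = as.numeric(idi(p1, p0, sample$time, sample$status, w, tau, ipcw)),
        nri = nr$nri,
        delta_aic = as.numeric(delta_aic(fits[[nm]], fits[[baseline]])),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(summary = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 predictions = preds, nri = nris, tau = tau,
                 baseline = baseline),
            class = "discrimination_result")
}

#' @export
print.discrimination_result <- function(x, ...) {
  cat("Discrimination at tau =", x$tau, "years (baseline:", x$baseline, ")\n")
  print(x$summary, digits = 4, row.names = FALSE)
  invisible(x)
}
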