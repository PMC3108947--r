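# Weighted Cox proportional-hazards fitting for stratified case-cohort
# samples: Newton-Raphson on the weighted log partial likelihood with
# Breslow tie handling, counting-process risk sets implementing the
# Prentice / Barlow schemes, robust sandwich variance from weighted score
# residuals, and the weighted Breslow baseline cumulative hazard.

#' z-transformation
#'
#' Standardize a concentration vector: `(x - mean) / sd`. Makes hazard
#' ratios unit-free (per 1 SD).
#'
#' @param values numeric vector.
#' @param mean,sd centering and scaling constants; `sd` must be positive.
#' @return standardized values.
#' @export
z_transform <- function(values, mean, sd) {
  if (sd <= 0) stop("sd must be positive (constant biomarker?)")
  (values - mean) / sd
}

#' Define a prediction model
#'
#' A named, ordered covariate list. Continuous terms listed in `z_terms`
#' are z-transformed on the weighted subcohort (design-representative
#' moments, n-1 denominator); other continuous terms are centered at their
#' weighted subcohort mean so the baseline hazard refers to a mean-profile,
#' reference-category subject. Factor terms are dummy-coded with the first
#' level as reference.
#'
#' @param name model label (e.g. "model_a", "model1_crp").
#' @param terms character vector of cohort column names.
#' @param z_terms subset of `terms` to z-transform (typically biomarkers).
#' @param endpoint endpoint label the model targets.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(name, terms, z_terms = character(0), endpoint = NULL) {
  if (anyDuplicated(terms)) stop("duplicate terms in model spec: ", name)
  if (length(setdiff(z_terms, terms))) stop("z_terms must be a subset of terms")
  structure(list(name = name, terms = terms, z_terms = z_terms,
                 endpoint = endpoint), class = "model_spec")
}

# weighted mean and SD (n-1 style) on the subcohort rows
subcohort_moments <- function(x, w) {
  m <- sum(w * x) / sum(w)
  v <- sum(w * (x - m)^2) / (sum(w) - 1)
  c(mean = m, sd = sqrt(v))
}

# Build the centered/standardized design matrix and remember the scaling so
# predictions can reproduce it on new data.
build_design <- function(data, spec, weights = NULL, subcohort = NULL) {
  n <- nrow(data)
  if (is.null(weights)) weights <- rep(1, n)
  if (is.null(subcohort)) {
    subcohort <- if ("in_subcohort" %in% names(data)) data$in_subcohort == 1 else rep(TRUE, n)
  }
  cols <- list(); scaling <- list()
  for (term in spec$terms) {
    x <- data[[term]]
    if (is.null(x)) stop("covariate not found: ", term)
    if (is.numeric(x)) {
      mom <- subcohort_moments(x[subcohort], weights[subcohort])
      if (!is.finite(mom["sd"]) || mom["sd"] <= 0)
        stop("constant covariate: ", term)
      if (term %in% spec$z_terms) {
        cols[[term]] <- z_transform(x, mom["mean"], mom["sd"])
        scaling[[term]] <- list(type = "z", center = unname(mom["mean"]),
                                scale = unname(mom["sd"]))
      } else {
        cols[[term]] <- x - mom["mean"]
        scaling[[term]] <- list(type = "center", center = unname(mom["mean"]),
                                scale = 1)
      }
    } else {
      f <- if (is.factor(x)) x else factor(x)
      levs <- levels(f)
      if (length(levs) < 2) stop("constant covariate: ", term)
      for (lv in levs[-1]) {
        nm <- paste0(term, "_", lv)
        cols[[nm]] <- as.numeric(f == lv)
      }
      scaling[[term]] <- list(type = "factor", levels = levs)
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  list(X = X, scaling = scaling)
}

# Expand a case-cohort sample into counting-process rows (start, stop]
# according to the weighting scheme. eps separates an outside case's entry
# from its own failure time.
expand_risk_rows <- function(sample, scheme, eps = 1e-8) {
  n <- nrow(sample)
  t <- sample$time; d <- sample$status
  insub <- sample$in_subcohort == 1
  alphas <- attr(sample, "alphas")
  a <- if (is.null(alphas)) rep(1, n) else unname(alphas[sample$stratum])

  if (scheme == "prentice") {
    start <- ifelse(insub, 0, pmax(t - eps, 0))
    list(start = start, stop = t, status = d, w = rep(1, n), id = seq_len(n))
  } else if (scheme == "barlow") {
    start <- numeric(0); stop <- numeric(0); status <- integer(0)
    w <- numeric(0); id <- integer(0)
    add <- function(s, e, st, wt, i) {
      start <<- c(start, s); stop <<- c(stop, e); status <<- c(status, st)
      w <<- c(w, wt); id <<- c(id, i)
    }
    for (i in seq_len(n)) {
      if (insub[i] && d[i] == 0) {
        add(0, t[i], 0L, 1 / a[i], i)
      } else if (insub[i] && d[i] == 1) {
        if (t[i] > eps) add(0, t[i] - eps, 0L, 1 / a[i], i)
        add(max(t[i] - eps, 0), t[i], 1L, 1, i)
      } else {                         # case outside the subcohort
        add(max(t[i] - eps, 0), t[i], 1L, 1, i)
      }
    }
    list(start = start, stop = stop, status = status, w = w, id = id)
  } else stop("unknown weight scheme: ", scheme)
}

# column-wise cumulative sums via one cumsum over the stacked columns
colcumsum <- function(M) {
  n <- nrow(M); p <- ncol(M)
  cs <- cumsum(as.vector(M))
  out <- matrix(cs, n, p)
  if (p > 1) out <- out - matrix(rep(c(0, cs[n * seq_len(p - 1)]), each = n), n, p)
  out
}

# cumulative "sum over rows with key >= t" machinery: precompute an order
# once, then reuse for any value matrix. Rows whose key precedes the first
# event time can never be counted and are dropped up front (e.g. all the
# start = 0 entries of subcohort members).
make_ge_summer <- function(key, et) {
  keep <- which(key >= et[1])
  o <- keep[order(key[keep], decreasing = TRUE)]   # descending: cumsum = tail sums
  m <- length(o)
  K <- length(et)
  asc <- sort(key[o])
  nge <- m - findInterval(et, asc, left.open = TRUE) # count of kept key >= t
  idx <- pmax(nge, 1)
  zero <- nge == 0
  function(V) {
    if (!is.matrix(V)) V <- matrix(V, ncol = 1)
    if (m == 0) return(matrix(0, K, ncol(V)))
    cs <- colcumsum(V[o, , drop = FALSE])
    res <- cs[idx, , drop = FALSE]
    if (any(zero)) res[zero, ] <- 0
    res
  }
}

# Core Newton-Raphson solver for the weighted Cox partial likelihood with
# Breslow ties on counting-process data.
cox_fit_engine <- function(start, stop, status, X, w, id,
                           max_iter = 100, score_tol = 1e-8, rel_tol = 1e-10) {
  X <- as.matrix(X)
  p <- ncol(X)
  ev <- status == 1
  if (sum(ev) < 2) stop("need at least 2 events")
  et <- sort(unique(stop[ev]))
  K <- length(et)
  # weighted event count and weighted covariate sum per distinct event time
  gie <- match(stop[ev], et)      # event-time group of each event row
  wd <- numeric(K)
  agg <- rowsum(w[ev], gie, reorder = TRUE)
  wd[as.integer(rownames(agg))] <- agg[, 1]
  ev_lp_const <- colSums(w[ev] * X[ev, , drop = FALSE])

  # Risk-set sums. Rows entering at time 0 are handled by prefix sums over
  # descending stop times. Delayed-entry rows (a case joining just before
  # its own failure) have epsilon-width intervals and contribute to exactly
  # one risk set, so they are added by direct lookup — never by subtracting
  # two prefix sums, which loses all precision when one subject dominates
  # the exponentiated linear predictor.
  from0 <- start == 0
  if (any(!from0 & (stop - start) > 1e-6))
    stop("internal: delayed entry supported only for epsilon-width rows")
  sum_stop0 <- make_ge_summer(stop[from0], et)
  spot_k <- match(stop[!from0], et)      # own event time of each entry row
  risk_sum <- function(V) {
    if (!is.matrix(V)) V <- matrix(V, ncol = 1)
    out <- sum_stop0(V[from0, , drop = FALSE])
    if (length(spot_k)) {
      agg <- rowsum(V[!from0, , drop = FALSE], spot_k, reorder = TRUE)
      rows <- as.integer(rownames(agg))
      out[rows, ] <- out[rows, , drop = FALSE] + agg
    }
    out
  }

  # pairwise products for the information matrix
  pair_i <- rep(seq_len(p), times = seq(p, 1))
  pair_j <- unlist(lapply(seq_len(p), function(i) i:p))
  Xpair <- X[, pair_i, drop = FALSE] * X[, pair_j, drop = FALSE]

  unpack <- function(v) {
    M <- matrix(0, p, p)
    M[cbind(pair_i, pair_j)] <- v
    M[cbind(pair_j, pair_i)] <- v
    M
  }

  Xall <- cbind(1, X, Xpair)                 # fused S0 | S1 | S2 value matrix
  i_s1 <- 1 + seq_len(p)
  i_s2 <- 1 + p + seq_along(pair_i)

  # the linear predictor is recentred before exponentiating so extreme
  # leverage points cannot wash out the risk-set sums; the shift cancels
  # in every ratio and is added back to log S0 for the likelihood
  loglik_at <- function(eta) {
    cshift <- max(eta)
    v <- w * exp(eta - cshift)
    S0 <- as.vector(risk_sum(v))
    list(loglik = sum(w[ev] * eta[ev]) - sum(wd * (log(S0) + cshift)),
         S0 = S0, v = v, cshift = cshift)
  }

  beta <- rep(0, p)
  eta <- as.vector(X %*% beta)
  cur <- loglik_at(eta)
  ll <- cur$loglik
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    v <- cur$v
    R <- risk_sum(v * Xall)
    S0 <- R[, 1]
    S1 <- R[, i_s1, drop = FALSE]
    S2 <- R[, i_s2, drop = FALSE]
    xbar <- S1 / S0
    grad <- ev_lp_const - colSums(wd * xbar)
    info <- unpack(colSums(wd * S2 / S0)) - crossprod(sqrt(wd) * xbar)
    if (max(abs(grad)) < score_tol) { converged <- TRUE; break }
    step <- tryCatch(solve(info, grad), error = function(e)
      stop("singular information matrix (collinear covariates?)"))
    halve <- 0
    repeat {
      beta_new <- beta + step
      if (max(abs(beta_new)) > 50)
        stop("monotone likelihood: coefficient diverging (complete separation)")
      eta_new <- as.vector(X %*% beta_new)
      cand <- loglik_at(eta_new)
      if (is.finite(cand$loglik) && cand$loglik >= ll - 1e-12) break
      halve <- halve + 1
      if (halve > 25) {
        if (max(abs(beta)) > 5)
          stop("monotone likelihood: coefficient diverging (complete separation)")
        stop("step halving failed; last |score| = ", format(max(abs(grad))))
      }
      step <- step / 2
    }
    rel_change <- abs(cand$loglik - ll) / (abs(ll) + rel_tol)
    beta <- beta_new; eta <- eta_new; cur <- cand; ll <- cand$loglik
    if (rel_change < rel_tol) { converged <- TRUE; break }
  }
  if (!converged && iter == max_iter) {
    v <- cur$v; S0 <- cur$S0
    grad <- ev_lp_const - colSums(wd * (risk_sum(v * X) / S0))
    if (max(abs(grad)) >= score_tol)
      stop("no convergence in ", max_iter, " Newton steps; |score| = ",
           format(max(abs(grad))))
  }

  if (max(abs(beta)) > 20)
    stop("monotone likelihood: coefficient diverging (complete separation)")

  # final quantities at the optimum
  v <- cur$v
  R <- risk_sum(v * Xall)
  S0 <- R[, 1]
  S1 <- R[, i_s1, drop = FALSE]
  S2 <- R[, i_s2, drop = FALSE]
  xbar <- S1 / S0
  grad <- ev_lp_const - colSums(wd * xbar)
  info <- unpack(colSums(wd * S2 / S0)) - crossprod(sqrt(wd) * xbar)
  iinv <- solve(info)

  # Breslow baseline cumulative hazard increments (back on the true scale)
  h <- wd / S0 * exp(-cur$cshift)
  cumhaz <- cumsum(h)

  # weighted score residuals per counting-process row, then per subject;
  # the cshift factor cancels between v and the cumulative hazard terms
  Bc <- cumsum(wd / S0)                 # Sum_{t_k <= t} wd/S0 (scaled)
  Ac <- apply(wd * S1 / S0^2, 2, cumsum)
  at <- function(tt) {                  # index of last event time <= tt
    findInterval(tt, et)
  }
  i_stop <- at(stop); i_start <- at(start)
  B_stop <- c(0, Bc)[i_stop + 1]; B_start <- c(0, Bc)[i_start + 1]
  A_stop <- rbind(0, Ac)[i_stop + 1, , drop = FALSE]
  A_start <- rbind(0, Ac)[i_start + 1, , drop = FALSE]
  U <- matrix(0, length(stop), p)
  if (any(ev)) U[ev, ] <- w[ev] * (X[ev, , drop = FALSE] - xbar[gie, , drop = FALSE])
  U <- U - v * (X * (B_stop - B_start) - (A_stop - A_start))
  Uagg <- rowsum(U, id)
  robust <- iinv %*% crossprod(Uagg) %*% iinv

  list(beta = beta, loglik = ll, info = info, naive_var = iinv,
       robust_var = robust, baseline = list(time = et, cumhaz = cumhaz),
       n_events = sum(ev), iter = iter, score_norm = max(abs(grad)),
       converged = TRUE)
}

#' Fit a weighted Cox model to a case-cohort sample
#'
#' Maximizes the weighted log partial likelihood with Breslow tie handling
#' over risk sets built per the sample's weighting scheme: under
#' "prentice" cases outside the subcohort enter the risk set only just
#' before their own failure time; under "barlow" subcohort members carry
#' the inverse sampling fraction until a case's weight drops to 1 at its
#' event (via internal time splitting). Variance is the robust sandwich
#' estimator from weighted, per-subject score residuals — required for
#' validity under case-cohort weighting. Convergence: max |score| < 1e-8
#' or relative log-likelihood change < 1e-10 within 100 Newton steps.
#'
#' Also works on a full cohort (every weight 1), where it agrees with a
#' standard Cox implementation.
#'
#' @param sample a weighted `cch_sample`, or any data.frame with `time`,
#'   `status` columns (treated as a census: all weights 1).
#' @param spec a [model_spec()] (or a character vector of terms).
#' @param z_terms used only when `spec` is a character vector.
#' @param scheme override the sample's stored weighting scheme.
#' @return object of class `cch_cox`: coefficients, robust and model-based
#'   covariance, weighted log partial likelihood, pseudo-AIC
#'   (`-2 loglik + 2k`), Breslow baseline cumulative hazard at the
#'   mean-covariate/reference profile, the covariate scaling used, and fit
#'   metadata.
#' @export
cch_cox <- function(sample, spec, z_terms = character(0), scheme = NULL) {
  if (is.character(spec)) spec <- model_spec("model", spec, z_terms = z_terms)
  stopifnot(inherits(spec, "model_spec"))
  if (!all(c("time", "status") %in% names(sample))) {
    ep <- spec$endpoint
    if (!is.null(ep) && paste0("time_", ep) %in% names(sample)) {
      sample$time <- sample[[paste0("time_", ep)]]
      sample$status <- sample[[paste0("status_", ep)]]
    } else stop("sample must have time and status columns")
  }
  is_cch <- inherits(sample, "cch_sample") && !is.null(attr(sample, "alphas"))
  if (is.null(scheme)) scheme <- attr(sample, "scheme")
  if (is.null(scheme)) scheme <- "prentice"
  if (!"in_subcohort" %in% names(sample)) sample$in_subcohort <- 1L
  if (!"weight" %in% names(sample)) sample$weight <- 1

  # z-transform moments use the pure design weights (1/alpha) on the
  # subcohort, which is design-representative of the cohort
  mw <- if (is_cch) 1 / unname(attr(sample, "alphas")[sample$stratum])
        else rep(1, nrow(sample))
  des <- build_design(sample, spec, weights = mw)
  rows <- if (is_cch) expand_risk_rows(sample, scheme)
          else list(start = rep(0, nrow(sample)), stop = sample$time,
                    status = sample$status, w = rep(1, nrow(sample)),
                    id = seq_len(nrow(sample)))
  fit <- cox_fit_engine(rows$start, rows$stop, rows$status,
                        des$X[rows$id, , drop = FALSE], rows$w, rows$id)
  k <- length(fit$beta)
  beta <- stats::setNames(fit$beta, colnames(des$X))
  structure(list(
    coefficients = beta,
    var = fit$robust_var,
    naive_var = fit$naive_var,
    loglik = fit$loglik,
    k = k,
    aic = -2 * fit$loglik + 2 * k,
    baseline = fit$baseline,
    scaling = des$scaling,
    spec = spec,
    scheme = scheme,
    endpoint = if (!is.null(spec$endpoint)) spec$endpoint else attr(sample, "endpoint"),
    n = nrow(sample), n_events = fit$n_events,
    n_at_risk = nrow(sample),
    iter = fit$iter, score_norm = fit$score_norm
  ), class = "cch_cox")
}

#' @export
coef.cch_cox <- function(object, ...) object$coefficients

#' @export
vcov.cch_cox <- function(object, ...) {
  v <- object$var
  dimnames(v) <- list(names(object$coefficients), names(object$coefficients))
  v
}

#' Pseudo-AIC of a weighted Cox fit
#'
#' `-2 * loglik_w + 2k` on the weighted partial likelihood. Not a true
#' AIC under weighting; meaningful only comparatively between models
#' fitted to the same sample (see [delta_aic()]).
#'
#' @param fit a `cch_cox` fit.
#' @return numeric AIC value.
#' @export
model_aic <- function(fit) fit$aic

#' @export
AIC.cch_cox <- function(object, ..., k = 2) -2 * object$loglik + k * object$k

#' AIC difference between two models on the same sample
#'
#' `delta = AIC(old) - AIC(new)`, so positive values favour the new model.
#' An absolute difference above 10 is flagged "essential" (models
#' essentially different).
#'
#' @param fit_new,fit_old `cch_cox` fits on the same sample and endpoint.
#' @return numeric delta with attribute `essential`.
#' @export
delta_aic <- function(fit_new, fit_old) {
  if (!identical(fit_new$endpoint, fit_old$endpoint) ||
      fit_new$n != fit_old$n || fit_new$n_events != fit_old$n_events)
    stop("models were not fitted to the same sample/endpoint")
  d <- fit_old$aic - fit_new$aic
  attr(d, "essential") <- abs(d) > 10
  d
}

#' Hazard-ratio table
#'
#' Per covariate: HR = exp(beta), 95% Wald CI from the robust SE, and the
#' two-sided Wald p value; significance is flagged at p < 0.05.
#'
#' @param fit a `cch_cox` fit.
#' @param level confidence level (default 0.95).
#' @return data.frame with columns `term`, `hr`, `ci_low`, `ci_high`,
#'   `se`, `p`, `significant`.
#' @export
hazard_ratios <- function(fit, level = 0.95) {
  b <- fit$coefficients
  se <- sqrt(diag(fit$var))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  z <- b / se
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(term = names(b), hr = unname(exp(b)),
             ci_low = unname(exp(b - zq * se)), ci_high = unname(exp(b + zq * se)),
             se = unname(se), p = unname(p), significant = unname(p < 0.05),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Breslow baseline cumulative hazard
#'
#' Step function `H0(t) = sum_{t_i <= t} w_i d_i / sum_{R(t_i)} w_j
#' exp(x_j'beta)` at the mean-covariate, reference-category profile.
#'
#' @param fit a `cch_cox` fit.
#' @return a step function of time (years); `environment(f)$table` holds
#'   the (time, cumhaz) table.
#' @export
breslow_baseline <- function(fit) {
  tab <- data.frame(time = fit$baseline$time, cumhaz = fit$baseline$cumhaz)
  f <- stats::stepfun(tab$time, c(0, tab$cumhaz), right = FALSE)
  attr(f, "table") <- tab
  f
}

# design row(s) for new data on the fit's stored scaling
design_newdata <- function(fit, newdata) {
  cols <- list()
  for (term in names(fit$scaling)) {
    sc <- fit$scaling[[term]]
    x <- newdata[[term]]
    if (is.null(x)) stop("covariate missing from new data: ", term)
    if (sc$type == "factor") {
      f <- factor(as.character(x), levels = sc$levels)
      if (anyNA(f)) stop("unknown level in covariate ", term)
      for (lv in sc$levels[-1]) cols[[paste0(term, "_", lv)]] <- as.numeric(f == lv)
    } else {
      cols[[term]] <- (x - sc$center) / sc$scale
    }
  }
  X <- do.call(cbind, cols)
  X[, names(fit$coefficients), drop = FALSE]
}

#' Predict absolute event risk at a time horizon
#'
#' `risk = 1 - exp(-H0(tau) * exp(x'beta))` with `x` mapped onto the fit's
#' stored centering/standardization.
#'
#' @param object a `cch_cox` fit.
#' @param newdata data.frame of covariates (defaults to refitting data not
#'   being stored, so it must be supplied).
#' @param tau horizon in years (default 10).
#' @param type "risk" (default) or "lp" (linear predictor).
#' @param ... unused.
#' @return numeric vector.
#' @export
predict.cch_cox <- function(object, newdata, tau = 10, type = c("risk", "lp"), ...) {
  type <- match.arg(type)
  if (tau <= 0) stop("tau must be positive")
  X <- design_newdata(object, newdata)
  lp <- as.vector(X %*% object$coefficients)
  if (type == "lp") return(lp)
  H0 <- breslow_baseline(object)(tau)
  1 - exp(-H0 * exp(lp))
}

#' @export
print.cch_cox <- function(x, ...) {
  cat("Weighted case-cohort Cox model:", x$spec$name, "\n")
  cat("  scheme:", x$scheme,
      " n =", x$n, " events =", x$n_events,
      " iterations =", x$iter, "\n")
  cat("  loglik =", format(x$loglik), "  pseudo-AIC =", format(x$aic), "\n")
  print(hazard_ratios(x)[, c("term", "hr", "ci_low", "ci_high", "p")],
        digits = 3)
  invisible(x)
}

#' @export
summary.cch_cox <- function(object, ...) {
  out <- list(name = object$spec$name, table = hazard_ratios(object),
              loglik = object$loglik, aic = object$aic,
              n = object$n, n_events = object$n_events)
  class(out) <- "summary.cch_cox"
  out
}

#' @export
print.summary.cch_cox <- function(x, ...) {
  cat("Model", x$name, "- n =", x$n, ", events =", x$n_events, "\n")
  print(x$table, digits = 3)
  cat("loglik =", format(x$loglik), ", pseudo-AIC =", format(x$aic), "\n")
  invisible(x)
}
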